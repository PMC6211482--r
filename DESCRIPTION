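Package: BayesHLA
Title: Bayesian HLA Genotyping and Somatic Mutation Detection from
    Sequencing Reads
Version: 0.1.0
Authors@R:
    person("BayesHLA", "Developers", email = "bayeshla@example.org",
           role = c("aut", "cre"))
Description: Collects sequencing reads likely to originate from a target
    HLA gene, infers the pair of HLA types and the personal HLA sequences
    of a sample with a Bayesian hierarchical model sampled by Gibbs and
    Metropolis-Hastings moves under parallel tempering, and derives
    germline variants, somatic mutations and loss-of-heterozygosity
    evidence from paired normal/tumor runs.  Ships an integrated
    multiple-sequence-alignment builder for genomic plus exonic HLA
    reference alignments, an HLA-read scoring and filtering stage, a
    read/reference simulator for fully offline testing, and a
    command-line pipeline front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    Biostrings,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools
Config/testthat/edition: 3
RoxygenNote: 7.3.3
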