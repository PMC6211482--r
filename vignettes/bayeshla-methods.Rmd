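---
title: "BayesHLA: model, sampler, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{BayesHLA: model, sampler, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BayesHLA)
```

# The problem

HLA genes are extremely polymorphic: each person carries two alleles per
gene out of thousands of catalogued types, and short-read data from the
MHC region maps ambiguously both across alleles and across homologous
genes.  BayesHLA infers, for one target gene at a time, the pair of HLA
types of a sample, the sample's personal HLA sequences (which may not be
in any database), and — from paired normal/tumor runs — germline
variants, somatic mutations, and loss-of-heterozygosity (LOH) evidence.

The pipeline has two stages: (1) read collection, scoring every candidate
read against every reference allele and keeping those that look like
target-gene reads; (2) Bayesian inference over types, sequences and
per-read origin assignments by MCMC.

# Reference panel: the integrated MSA

HLA databases hold a full *genomic* alignment for some alleles and an
*exonic* (coding-only) alignment for most.  `build_integrated_msa()`
reconciles the exon blocks of the two alignments into one column space
(inserting gap columns where block widths differ, using a
Needleman–Wunsch merge of the block consensuses) and fills the
non-coding columns of exonic-only alleles from the most similar genomic
allele (`impute_noncoding()`).

Design choices here were genuinely open:

* **Similarity for donor choice** is the count of exact matches over the
  columns where the target is defined (its exons), with ties broken by
  lexicographic allele name so builds are reproducible.
* Imputed positions are recorded in a per-allele mask; the model treats
  them with inflated variant rates (below).
* Read insertions that cannot be represented inside the fixed column
  space are dropped (and counted) rather than widening the MSA, which
  would invalidate all existing coordinates mid-run.

# Read collection: the HR score

A read $x$ aligned to an allele $t$ receives the score
$\sum_n (\tilde\alpha_n + \tilde\beta_n)$ over alignment columns: a
mismatch of two concrete bases contributes $\log(\tilde p_n/3)$ with
$\tilde p_n = 10^{-q_n/10}$ the quality-implied error probability;
read-gaps and allele-gaps pay affine open/extend penalties
($\alpha^{d,o},\alpha^{d,e},\alpha^{i,o},\alpha^{i,e}$); an N opposite a
concrete symbol pays $\alpha^N$; and every column where the read carries
a symbol earns the length reward $\beta>0$.  Logs are natural.

A read is kept for gene $G$ when its best score within $G$ exceeds an
absolute threshold and beats the best score in any other gene by a
margin; for pairs, both conditions are applied to the mate sums with
(necessarily looser) thresholds.  All inequalities are strict, and an
unalignable read ($-\infty$) never passes.

The built-in aligner is an affine-gap semi-global DP whose objective *is*
the HR score (free entry/exit along the allele, full read consumed, and
the first consumed read base must anchor on an allele base).  There are no canonical values for the
$\alpha, \beta, \theta$ constants; the defaults in
`score_params()` — $\beta = 0.25$, $\alpha = (-6,-1,-6,-1,-2)$,
$\theta^{u,m} = -20$, $\theta^{u,d} = 2$, $\theta^{p,m} = -40$,
$\theta^{p,d} = 0$ — are tuning choices, exposed in configuration, chosen
so a 100 bp Q30 read tolerates a handful of mismatches but a 5%-diverged
homolog fails the margin test.

# The Bayesian model

For one gene the unknowns are $\mathcal R$ (HLA types: two sample slots
plus decoys), $\mathcal S$ (the corresponding sequences in MSA columns)
and $\mathcal I$ (per-read component assignments).  The posterior is

$$p(\mathcal R,\mathcal S,\mathcal I \mid \hat X) \propto
  p(\hat X\mid \mathcal S,\mathcal I)\,
  p(\mathcal R,\mathcal S)\, p(\mathcal I).$$

*Read likelihood.* Each covered column emits independently; with
sequence base $S$, the read reproduces it w.p.
$(1-\gamma^d)(1-\gamma^N)(1-\hat p)$, substitutes w.p.
$(1-\gamma^d)(1-\gamma^N)\hat p/3$, reads N w.p. $(1-\gamma^d)\gamma^N$,
or drops it w.p. $\gamma^d$; a sequence N emits bases uniformly; a
sequence gap stays a gap w.p. $1-\gamma^i$.  Every conditional
distribution sums to one (tested to $10^{-12}$).  Columns not covered by
a read — including the gap between mates — contribute nothing.

*Sequence prior.* $p(S_{k,n}\mid R_{k,n})$ has the same piecewise shape
with germline-variant rates $\delta^s,\delta^d,\delta^i,\delta^N$, and a
second, larger rate set at positions whose reference base was imputed.
No field-standard values exist for these rates. Package defaults:
$\gamma^d=\gamma^i=10^{-3}$, $\gamma^N=10^{-4}$;
$\delta = (5\cdot10^{-3},10^{-3},10^{-3},10^{-4})$;
imputed $\delta = (0.02, 0.005, 0.005, 2\cdot10^{-4})$.
The imputed set is one order of magnitude above the normal set rather
than the 40-fold inflation we first tried: because *every* imputed column
pays $\log(1-\delta^d)(1-\delta^N)(1-\delta^s)$ even when sequence and
reference agree, very large imputed rates levy a constant per-column tax
on exonic-only alleles (~0.27 nats/column, i.e. hundreds of nats per
gene) that structurally excludes them from genotype calls regardless of
the data.  The chosen defaults keep the intended effect — data override
the reference cheaply at imputed positions — without that pathology.

*Type prior.* Sample slots use population frequencies when a table is
supplied, smoothed as $(f+\lambda)/(1+\lambda n)$ with
$\lambda=10^{-3}$ (uniform otherwise); decoy slots use the constant
$1/n$.

*Indicator prior.* $p(I_i)\propto 1$ for the two sample slots and
$\epsilon$ for each decoy ($\epsilon = 0.01$, 2 decoys by default).
Decoys absorb reads from homologous regions that slip past the filter.

# Sampling

Gibbs sweeps update every $S_{k,n}$ (six-way conditional), every $R_k$
(over the whole panel) and every $I_i$.  Two Metropolis–Hastings
proposals run every `mh_period` sweeps:

* **Masked-sequence type jump.** $S^N_k$ masks to N every column not
  covered by the reads of component $k$; a candidate type is drawn from
  $p(R^*\mid S^N_k)$ and a candidate sequence from its full conditional.
  This lets the chain hop between types that differ only at unread
  positions.  We accept with the *exact* ratio, in which the marginals
  over sequences factorize per column and are computed exactly (never by
  nested sampling).  The textbook ratio assumes the proposed sequence
  equals the current one at covered columns; our ratio carries the
  correction terms (reverse-move mask and its type normalizer), reduces
  to the textbook form when the assumption holds, and keeps detailed
  balance exactly — which is what makes the enumeration test below
  possible.
* **Decoy swap.** One sample slot and one decoy exchange their
  (type, sequence) pair and all indicators are redrawn from their
  conditional; the acceptance ratio marginalizes the indicators exactly
  (a per-read factorized sum).

Parallel tempering runs a short ladder of chains with replica-exchange
between adjacent temperatures; only the cold chain is summarized.  At
the problem sizes this package targets (kilobase columns) the cold-chain
log-posterior fluctuates with s.d. ≈ 20, so ladders with spacings of
0.3–1.0 never exchange; the default ladder (1, 1.05, 1.11, 1.18) is
spaced for ~10% swap acceptance and is configurable.

Two burn-in-only heuristics guard against the crossover-type local
optima: a multi-start phase seeds the ladder from the best of several
short exploratory chains, and reference sequences are periodically
copied over the sampled sequences.  Both stop at the end of burn-in, so
kept samples follow the posterior; on instances small enough to
enumerate, genotype marginals from 50 000 sweeps match exhaustive
enumeration within total-variation distance 0.05 (typically < 0.02).

Genotypes are called by counting unordered sampled type pairs; consensus
sequences by per-column modal symbols, with label switching between the
two sample components resolved by greedy matching against the running
consensus, and columns below the support threshold (default 0.9)
reported as N.

# Variant, somatic and LOH calling

Germline variants are columns where the consensus differs from the
called type's reference with sufficient support (imputed columns
flagged).  Somatic calls compare normal and tumor consensus pairs after
minimal-mismatch haplotype matching; a tumor gap opposite a normal base
is a deletion, and N on either side suppresses the call.  LOH screening
flags genes whose genotype is uniquely determined in the normal but not
the tumor, or uniquely but differently in both; at heterozygous SNP
columns the allele-supporting depths give a log odds ratio with a Woolf
(log-scale normal) 95% CI using the Haldane–Anscombe 0.5 pseudocount —
no single CI construction is canonical for such depth data, so this
one is flagged as a reconstruction in the report header.

# The synthetic world

`generate_mock_db()` / `simulate_reads()` build the world the tests run
in: 20 alleles of one gene over 1 kb (10% UTR, 20% exon, 20% intron,
20% exon, 20% intron, 10% UTR), pairwise divergence 2% by independent
substitution mutants of one ancestor, half the alleles exported at
exonic level only, a homolog gene at 5% divergence, and 100 bp Q30
paired reads (Q15 over the last 5 bases) at 10× with insert
300 ± 30 bp, quality-implied substitution errors and $10^{-4}$
single-base indel errors.  Planted scenarios cover a clonal single-base
somatic indel (all reads of one haplotype, i.e. half the locus reads,
carry it — the depth pattern of a clonal heterozygous event), a 4:1
allelic imbalance, and a reference misimputation (one base of one
allele's emitted reference flipped to another allele's variant at a
polymorphic column, truth manifest unchanged).

What the generator does **not** emulate: platform-specific error
profiles, GC/coverage bias, paralog mosaic (gene-conversion) alleles,
population linkage between alleles, and full-genome background reads.
A green test therefore establishes correctness of the inference
machinery in its own model world, not clinical-grade accuracy on real
WGS data.

Two limits of this world worth knowing about: with few, short, closely
related alleles, an exonic-only allele whose imputed introns come from a
dissimilar donor can be *legitimately* out-scored by a nearby genomic
allele when the distinguishing exon columns happen to be uncovered —
the sequence consensus stays correct, and this is exactly the
misimputation regime the robustness test probes; and a subclonal
(cell fraction ≈ 0.5 *of one haplotype's reads*) indel is not called,
because with symmetric $\gamma$ rates a half-deleted column is best
explained by the base, not the gap.

# Numerical notes

* All scoring and densities in natural-log space; six-way conditionals
  sampled by max-shifted exponentiation.
* Tempered conditionals raise the *target* to $1/T$; proposals are drawn
  from tempered conditionals so the MH ratios stay exact at every
  temperature.
* Ties: best-type and donor choices break lexicographically; genotype
  ranking breaks count ties lexicographically.
* Determinism: a single seeded RNG (R's generator, shared by the C++
  core) drives every stage; identical config + seed gives byte-identical
  outputs.
* Degenerate inputs: zero accepted reads aborts with a pointer to the
  filter log; an empty panel or malformed config errors before any
  compute.
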