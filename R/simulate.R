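#' Configuration of the mock HLA reference and read simulator
#'
#' The generator emulates the statistical world the model assumes: a panel
#' of alleles of one target gene diverging by point substitutions, a
#' homologous non-target gene at larger divergence, a fraction of alleles
#' known only at exonic level, and paired short reads with quality-implied
#' substitution errors and rare indel errors.
#'
#' @param n_alleles number of target-gene alleles.
#' @param length gene length in bases.
#' @param divergence expected pairwise allele divergence (substitutions per
#'   site), in (0,1).
#' @param exonic_only_frac fraction of alleles emitted at exonic level only.
#' @param n_homolog,homolog_divergence size and divergence of the
#'   non-target homolog gene.
#' @param read_length,insert_mean,insert_sd,coverage paired-read geometry
#'   and mean depth per haplotype pair.
#' @param q_high,q_tail,tail_len base quality profile: constant
#'   \code{q_high} with a \code{q_tail} tail over the last \code{tail_len}
#'   bases.
#' @param indel_rate per-base sequencing indel error rate.
#' @param contam_frac fraction of read pairs drawn from the homolog gene.
#' @param seed mandatory RNG seed.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_alleles = 20L, length = 1000L, divergence = 0.02,
                       exonic_only_frac = 0.5, n_homolog = 5L,
                       homolog_divergence = 0.05,
                       read_length = 100L, insert_mean = 300L,
                       insert_sd = 30L, coverage = 10,
                       q_high = 30L, q_tail = 15L, tail_len = 5L,
                       indel_rate = 1e-4, contam_frac = 0, seed = 1L) {
  stopifnot(divergence > 0, divergence < 1, homolog_divergence > 0,
            homolog_divergence < 1, coverage > 0, n_alleles >= 2,
            read_length >= 10, !is.null(seed))
  structure(as.list(environment()), class = "sim_config")
}

.random_bases <- function(n) sample(4L, n, replace = TRUE)

.mutate <- function(codes, rate) {
  hit <- which(stats::runif(length(codes)) < rate)
  if (length(hit))
    codes[hit] <- 1L + (codes[hit] - 1L + sample(3L, length(hit),
                                                 replace = TRUE)) %% 4L
  codes
}

.default_feature_map <- function(L) {
  fr <- c(UTR5 = 0.1, exon1 = 0.2, intron1 = 0.2, exon2 = 0.2,
          intron2 = 0.2, UTR3 = 0.1)
  widths <- diff(round(cumsum(c(0, fr)) * L))
  rep(names(fr), widths)
}

#' Generate a mock HLA reference bundle with known truth
#'
#' Alleles of the target gene are independent substitution mutants of one
#' ancestral sequence at rate \code{divergence/2} per site (expected
#' pairwise divergence \code{divergence}); a homolog gene descends from the
#' same ancestor at \code{homolog_divergence}.  A configurable fraction of
#' target alleles is exported at exonic level only.  Optionally one base of
#' a designated allele is misimputed in the emitted reference (replaced by
#' another allele's variant at a polymorphic column) while the truth
#' manifest keeps the real sequence.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param misimpute_allele optional allele name whose reference copy gets
#'   one planted misimputation.
#' @param seed RNG seed (default \code{cfg$seed}).
#' @return an object of class \code{mock_db}: \code{gene},
#'   \code{genomic}/\code{exonic} (lists of \code{\link{hla_allele}}),
#'   \code{feature_map}, \code{homolog} (all-genomic bundle), and
#'   \code{truth} (true sequences and the planted misimputation, if any).
#' @export
generate_mock_db <- function(cfg, misimpute_allele = NULL,
                             seed = cfg$seed) {
  set.seed(seed)
  L <- cfg$length
  fmap <- .default_feature_map(L)
  anc <- .random_bases(L)
  truth_seq <- list()
  alleles <- list()
  names_t <- sprintf("A*%02d:01", seq_len(cfg$n_alleles))
  for (i in seq_len(cfg$n_alleles)) {
    codes <- .mutate(anc, cfg$divergence / 2)
    truth_seq[[names_t[i]]] <- codes
  }

  mis <- NULL
  if (!is.null(misimpute_allele)) {
    if (!misimpute_allele %in% names_t) stop("unknown allele to misimpute")
    target <- truth_seq[[misimpute_allele]]
    others <- do.call(rbind, truth_seq[setdiff(names_t, misimpute_allele)])
    # polymorphic columns where some other allele differs from the target
    snp_cols <- which(vapply(seq_len(L), function(n)
      any(others[, n] != target[n]), logical(1)))
    if (!length(snp_cols)) stop("no polymorphic column to misimpute")
    col <- snp_cols[sample.int(length(snp_cols), 1L)]
    donor_vals <- others[others[, col] != target[col], col]
    newbase <- donor_vals[1L]
    mis <- list(allele = misimpute_allele, column = col,
                true_base = HLA_SYMBOLS[target[col]],
                planted_base = HLA_SYMBOLS[newbase])
  }

  n_exonic <- round(cfg$exonic_only_frac * cfg$n_alleles)
  exonic_idx <- if (n_exonic > 0)
    seq(cfg$n_alleles - n_exonic + 1L, cfg$n_alleles) else integer(0)
  is_exon <- grepl("^exon", fmap)
  genomic <- list(); exonic <- list()
  for (i in seq_len(cfg$n_alleles)) {
    codes <- truth_seq[[names_t[i]]]
    if (!is.null(mis) && names_t[i] == mis$allele)
      codes[mis$column] <- match(mis$planted_base, HLA_SYMBOLS)
    if (i %in% exonic_idx) {
      exonic[[length(exonic) + 1L]] <-
        hla_allele("A", names_t[i], "exonic",
                   decode_seq(codes[is_exon]))
    } else {
      genomic[[length(genomic) + 1L]] <-
        hla_allele("A", names_t[i], "genomic", decode_seq(codes))
    }
  }

  hom_anc <- .mutate(anc, cfg$homolog_divergence)
  hom_names <- sprintf("B*%02d:01", seq_len(cfg$n_homolog))
  homolog <- list(); hom_truth <- list()
  for (i in seq_len(cfg$n_homolog)) {
    codes <- .mutate(hom_anc, cfg$divergence / 2)
    hom_truth[[hom_names[i]]] <- codes
    homolog[[length(homolog) + 1L]] <-
      hla_allele("B", hom_names[i], "genomic", decode_seq(codes))
  }

  structure(list(gene = "A", genomic = genomic, exonic = exonic,
                 feature_map = fmap,
                 homolog = list(gene = "B", genomic = homolog,
                                feature_map = fmap),
                 truth = list(sequences = lapply(truth_seq, decode_seq),
                              homolog_sequences = lapply(hom_truth,
                                                         decode_seq),
                              misimputation = mis),
                 cfg = cfg, seed = seed),
            class = "mock_db")
}

#' Build the per-gene integrated MSA panels of a mock reference bundle
#'
#' @param db a \code{\link{generate_mock_db}} bundle.
#' @return named list of \code{\link{hla_msa}} (target gene and homolog).
#' @export
mock_db_msa <- function(db) {
  out <- list(build_integrated_msa(db$genomic, db$exonic, db$feature_map))
  names(out) <- db$gene
  if (length(db$homolog$genomic)) {
    out[[db$homolog$gene]] <-
      build_integrated_msa(db$homolog$genomic, list(),
                           db$homolog$feature_map)
  }
  out
}

.qual_profile <- function(cfg) {
  q <- rep(cfg$q_high, cfg$read_length)
  if (cfg$tail_len > 0)
    q[seq(cfg$read_length - cfg$tail_len + 1L, cfg$read_length)] <- cfg$q_tail
  as.integer(q)
}

# sequencing errors on one read: quality-implied substitutions plus rare
# 1-base indels (deletion shifts the template; both keep read length by
# re-trimming against the template tail)
.seq_errors <- function(codes, quals, indel_rate) {
  p <- mismatch_prob(quals)
  sub <- which(stats::runif(length(codes)) < p)
  if (length(sub))
    codes[sub] <- 1L + (codes[sub] - 1L + sample(3L, length(sub),
                                                 replace = TRUE)) %% 4L
  if (indel_rate > 0) {
    u <- stats::runif(length(codes))
    del <- u < indel_rate / 2
    if (any(del)) codes <- codes[!del]
    ins <- which(u >= indel_rate / 2 & u < indel_rate)
    for (i in rev(ins))
      codes <- append(codes, sample(4L, 1L), after = min(i, length(codes)))
  }
  codes
}

#' Simulate paired reads from a genotype of the mock reference
#'
#' Fragments are placed uniformly along each haplotype with
#' normally-distributed insert sizes; both mates are emitted in gene
#' orientation with the configured quality profile, quality-implied
#' substitution errors and rare single-base indel errors.  Options plant a
#' somatic single-base event at a cell fraction, an allelic imbalance
#' between the two haplotypes, and contaminating pairs from the homolog
#' gene.
#'
#' @param db a \code{\link{generate_mock_db}} bundle.
#' @param genotype character vector of two target-gene allele names (truth
#'   haplotypes).
#' @param cfg a \code{\link{sim_config}} (geometry and error rates).
#' @param seed RNG seed (default \code{cfg$seed}).
#' @param somatic optional list(column, kind = "deletion" or "insertion",
#'   cell_fraction): haplotype-1 fragments carry a single-base event at the
#'   given truth coordinate with the given probability.
#' @param imbalance haplotype-1 : haplotype-2 read ratio (4 means 4:1).
#' @param contam_frac overrides \code{cfg$contam_frac}.
#' @return an object of class \code{sim_reads}: \code{reads} (list of
#'   \code{\link{raw_read}}) and \code{truth} (data.frame: id, haplotype,
#'   source, contaminant, has_somatic).
#' @export
simulate_reads <- function(db, genotype, cfg = db$cfg, seed = cfg$seed,
                           somatic = NULL, imbalance = 1,
                           contam_frac = cfg$contam_frac) {
  stopifnot(length(genotype) == 2L,
            all(genotype %in% names(db$truth$sequences)))
  set.seed(seed)
  haps <- lapply(db$truth$sequences[genotype], encode_seq)
  mut_hap <- NULL
  if (!is.null(somatic)) {
    h <- haps[[1L]]
    if (somatic$kind == "deletion") mut_hap <- h[-somatic$column]
    else if (somatic$kind == "insertion")
      mut_hap <- append(h, sample(4L, 1L), after = somatic$column)
    else stop("somatic kind must be deletion or insertion")
  }
  L <- cfg$length; rl <- cfg$read_length
  n_pairs <- max(1L, round(cfg$coverage * L / (2 * rl)))
  quals <- .qual_profile(cfg)
  p_h1 <- imbalance / (imbalance + 1)
  reads <- vector("list", n_pairs)
  truth <- data.frame(id = character(n_pairs), haplotype = integer(n_pairs),
                      source = character(n_pairs),
                      contaminant = logical(n_pairs),
                      has_somatic = logical(n_pairs))
  hom_seqs <- lapply(db$truth$homolog_sequences, encode_seq)
  for (j in seq_len(n_pairs)) {
    contaminant <- length(hom_seqs) > 0 && stats::runif(1) < contam_frac
    has_som <- FALSE
    if (contaminant) {
      src <- sample(length(hom_seqs), 1L)
      tmpl <- hom_seqs[[src]]
      srcname <- names(hom_seqs)[src]
      hap <- NA_integer_
    } else {
      hap <- if (stats::runif(1) < p_h1) 1L else 2L
      tmpl <- haps[[hap]]
      srcname <- genotype[hap]
      if (hap == 1L && !is.null(mut_hap) &&
          stats::runif(1) < somatic$cell_fraction) {
        tmpl <- mut_hap
        has_som <- TRUE
      }
    }
    Lt <- length(tmpl)
    insert <- round(stats::rnorm(1, cfg$insert_mean, cfg$insert_sd))
    insert <- max(rl, min(insert, Lt))
    start <- sample.int(Lt - insert + 1L, 1L)
    frag <- tmpl[start:(start + insert - 1L)]
    m1 <- .seq_errors(frag[seq_len(min(rl, insert))], quals,
                      cfg$indel_rate)
    m2 <- .seq_errors(frag[seq(max(1L, insert - rl + 1L), insert)], quals,
                      cfg$indel_rate)
    id <- sprintf("sim_%05d", j)
    q1 <- quals[pmin(seq_along(m1), length(quals))]
    q2 <- quals[pmin(seq_along(m2), length(quals))]
    reads[[j]] <- raw_read(id, decode_seq(m1), q1, decode_seq(m2), q2)
    truth$id[j] <- id; truth$haplotype[j] <- hap
    truth$source[j] <- srcname; truth$contaminant[j] <- contaminant
    truth$has_somatic[j] <- has_som
  }
  structure(list(reads = reads, truth = truth, genotype = genotype,
                 seed = seed), class = "sim_reads")
}
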