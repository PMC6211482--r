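#' Call germline variants against the reference of the called type
#'
#' One call per MSA column where the consensus differs from the reference,
#' the consensus is not N, and its support clears \code{min_support};
#' columns whose reference base was imputed are flagged.
#'
#' @param consensus data.frame (column, symbol, support) for one sequence
#'   (\code{\link{call_sequences}}).
#' @param reference integer symbol codes of the called type's reference
#'   row.
#' @param imputed_mask logical vector of imputed reference positions.
#' @param gene gene symbol for the report.
#' @param min_support minimum consensus support (default 0.9).
#' @return data.frame (gene, column, kind, ref_symbol, obs_symbol, support,
#'   imputed).
#' @export
call_germline_variants <- function(consensus, reference, imputed_mask,
                                   gene = "A", min_support = 0.9) {
  stopifnot(nrow(consensus) == length(reference))
  obs <- match(consensus$symbol, HLA_SYMBOLS)
  keep <- obs != reference & obs != SYM_N &
    consensus$support >= min_support
  idx <- which(keep)
  kind <- ifelse(obs[idx] == SYM_GAP, "deletion",
                 ifelse(reference[idx] == SYM_GAP, "insertion",
                        "substitution"))
  data.frame(gene = rep(gene, length(idx)), column = idx, kind = kind,
             ref_symbol = HLA_SYMBOLS[reference[idx]],
             obs_symbol = HLA_SYMBOLS[obs[idx]],
             support = consensus$support[idx],
             imputed = imputed_mask[idx])
}

# pair tumor consensus sequences to normal ones by minimal total mismatch
.match_pairs <- function(n1, n2, t1, t2) {
  mm <- function(a, b) sum(a$symbol != b$symbol)
  if (mm(n1, t1) + mm(n2, t2) <= mm(n1, t2) + mm(n2, t1))
    list(t1, t2) else list(t2, t1)
}

#' Call somatic mutations from paired normal/tumor consensus sequences
#'
#' Tumor sequences are paired to normal sequences by minimal-mismatch
#' matching; a call is made at every column where the paired sequences
#' differ, both supports clear \code{min_support}, and neither symbol is N.
#' A gap in tumor opposite a base in normal is a deletion, the converse an
#' insertion.
#'
#' @param normal,tumor lists of two consensus data.frames (column, symbol,
#'   support) from \code{\link{call_sequences}} for the same gene and
#'   column space.
#' @param gene gene symbol for the report.
#' @param min_support minimum support in both samples (default 0.9).
#' @return data.frame (gene, haplotype, column, kind, normal_symbol,
#'   tumor_symbol, normal_support, tumor_support).
#' @export
call_somatic_mutations <- function(normal, tumor, gene = "A",
                                   min_support = 0.9) {
  stopifnot(length(normal) == 2L, length(tumor) == 2L)
  tm <- .match_pairs(normal[[1]], normal[[2]], tumor[[1]], tumor[[2]])
  out <- list()
  for (h in 1:2) {
    n <- normal[[h]]; t <- tm[[h]]
    keep <- n$symbol != t$symbol & n$symbol != "N" & t$symbol != "N" &
      n$support >= min_support & t$support >= min_support
    idx <- which(keep)
    if (!length(idx)) next
    kind <- ifelse(t$symbol[idx] == "-", "deletion",
                   ifelse(n$symbol[idx] == "-", "insertion",
                          "substitution"))
    out[[h]] <- data.frame(gene = gene, haplotype = h, column = idx,
                           kind = kind,
                           normal_symbol = n$symbol[idx],
                           tumor_symbol = t$symbol[idx],
                           normal_support = n$support[idx],
                           tumor_support = t$support[idx])
  }
  if (!length(out))
    return(data.frame(gene = character(0), haplotype = integer(0),
                      column = integer(0), kind = character(0),
                      normal_symbol = character(0),
                      tumor_symbol = character(0),
                      normal_support = numeric(0),
                      tumor_support = numeric(0)))
  do.call(rbind, out)
}

#' Depth log odds ratio at a heterozygous SNP column
#'
#' With pseudocount \code{c}, the log odds ratio of allele-supporting read
#' depths between tumor and normal is
#' \code{ln(((b1+c)/(b2+c)) / ((a1+c)/(a2+c)))} and the 95\% confidence
#' interval uses the Woolf normal approximation on the log scale,
#' \code{logOR +/- 1.96 sqrt(1/(a1+c)+1/(a2+c)+1/(b1+c)+1/(b2+c))}.
#' Negative values mean allele 1 is depleted in the tumor.
#'
#' @param normal_counts,tumor_counts length-2 non-negative counts of reads
#'   supporting allele 1 and allele 2.
#' @param pseudocount Haldane-Anscombe continuity correction (default 0.5).
#' @return named numeric: \code{log_or}, \code{ci_low}, \code{ci_high}.
#' @export
loh_log_odds <- function(normal_counts, tumor_counts, pseudocount = 0.5) {
  a <- normal_counts + pseudocount; b <- tumor_counts + pseudocount
  if (any(normal_counts < 0) || any(tumor_counts < 0))
    stop("read counts must be non-negative")
  if (any(a == 0) || any(b == 0))
    stop("zero counts with no pseudocount: log odds ratio undefined")
  lor <- (log(b[1]) - log(b[2])) - (log(a[1]) - log(a[2]))
  se <- sqrt(sum(1 / c(a, b)))
  c(log_or = lor, ci_low = lor - 1.96 * se, ci_high = lor + 1.96 * se)
}

# reads supporting each of two symbols at one column
.allele_depths <- function(reads, column, sym1, sym2) {
  col <- reads$sym[, column]
  c(sum(col == sym1), sum(col == sym2))
}

#' Screen genes for loss-of-heterozygosity candidates
#'
#' A gene is flagged when (i) the normal genotype is uniquely determined
#' (top posterior fraction >= \code{uniqueness}) but the tumor genotype is
#' not, or (ii) both are unique but differ.  For flagged genes (and, with
#' \code{always_report}, any heterozygous gene) the per-column
#' allele-supporting depths at heterozygous SNP columns are tabulated from
#' the realigned normal and tumor reads, feeding
#' \code{\link{loh_log_odds}}.
#'
#' @param normal_genotype,tumor_genotype genotype tables from
#'   \code{\link{call_genotype}}.
#' @param normal_reads,tumor_reads \code{hla_reads} used in the two runs.
#' @param msa the gene's \code{\link{hla_msa}}.
#' @param uniqueness posterior fraction above which a genotype counts as
#'   uniquely determined (default 0.9).
#' @param always_report tabulate depths even for unflagged genes.
#' @return list with \code{flagged} (FALSE or "ambiguous_tumor" /
#'   "genotype_change"), and \code{snp_table}: data.frame (column,
#'   allele1_symbol, allele2_symbol, normal_a1, normal_a2, tumor_a1,
#'   tumor_a2, log_or, ci_low, ci_high) over heterozygous SNP columns.
#' @export
screen_loh <- function(normal_genotype, tumor_genotype, normal_reads,
                       tumor_reads, msa, uniqueness = 0.9,
                       always_report = FALSE) {
  n_unique <- normal_genotype$fraction[1] >= uniqueness
  t_unique <- tumor_genotype$fraction[1] >= uniqueness
  same <- identical(sort(c(normal_genotype$allele1[1],
                           normal_genotype$allele2[1])),
                    sort(c(tumor_genotype$allele1[1],
                           tumor_genotype$allele2[1])))
  flagged <- FALSE
  if (n_unique && !t_unique) flagged <- "ambiguous_tumor"
  else if (n_unique && t_unique && !same) flagged <- "genotype_change"

  snp_table <- NULL
  if (!identical(flagged, FALSE) || always_report) {
    a1 <- normal_genotype$allele1[1]; a2 <- normal_genotype$allele2[1]
    r1 <- msa$alleles[a1, ]; r2 <- msa$alleles[a2, ]
    het <- which(r1 != r2 & r1 != SYM_GAP & r2 != SYM_GAP &
                   r1 != SYM_N & r2 != SYM_N)
    rows <- lapply(het, function(n) {
      nc <- .allele_depths(normal_reads, n, r1[n], r2[n])
      tc <- .allele_depths(tumor_reads, n, r1[n], r2[n])
      lor <- loh_log_odds(nc, tc)
      data.frame(column = n,
                 allele1_symbol = HLA_SYMBOLS[r1[n]],
                 allele2_symbol = HLA_SYMBOLS[r2[n]],
                 normal_a1 = nc[1], normal_a2 = nc[2],
                 tumor_a1 = tc[1], tumor_a2 = tc[2],
                 log_or = lor[["log_or"]], ci_low = lor[["ci_low"]],
                 ci_high = lor[["ci_high"]])
    })
    snp_table <- if (length(rows)) do.call(rbind, rows) else
      data.frame()
  }
  list(flagged = flagged, snp_table = snp_table,
       normal_alleles = c(normal_genotype$allele1[1],
                          normal_genotype$allele2[1]))
}
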