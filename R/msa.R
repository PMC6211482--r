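#' Construct an HLA allele record
#'
#' @param gene HLA gene symbol (e.g. "A", "B", "DRB1").
#' @param name colon-delimited allele name (e.g. "A*31:01:02").
#' @param level "genomic" (full gene) or "exonic" (coding sequence only).
#' @param seq aligned sequence over A,C,G,T,N,- as it appears in the source
#'   alignment.
#' @return an object of class \code{hla_allele}.
#' @export
hla_allele <- function(gene, name, level = c("genomic", "exonic"), seq) {
  level <- match.arg(level)
  if (!nzchar(seq)) stop("allele sequence must be non-empty")
  fields <- strsplit(sub("^[^*]*\\*", "", name), ":", fixed = TRUE)[[1L]]
  if (length(fields) < 1L || !grepl("^[0-9]+[A-Z]?$", fields[1L]))
    stop("allele name must contain >= 1 numeric field after the gene: ", name)
  codes <- encode_seq(seq)   # validates the alphabet
  structure(list(gene = gene, name = name, level = level,
                 seq = seq, codes = codes),
            class = "hla_allele")
}

# Needleman-Wunsch on two integer consensus vectors; returns the merged
# column list as a 2-column matrix of source indices (NA = inserted gap
# column on that side).  Deterministic: diagonal preferred, then up (gap in
# second sequence), then left.
.nw_merge <- function(a, b, match = 1, mismatch = -0.5, gap = -1) {
  n <- length(a); m <- length(b)
  sc <- matrix(0, n + 1, m + 1)
  sc[, 1] <- gap * (0:n); sc[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    sub <- ifelse(a[i] == b, match, mismatch)
    for (j in seq_len(m))
      sc[i + 1, j + 1] <- max(sc[i, j] + sub[j], sc[i, j + 1] + gap,
                              sc[i + 1, j] + gap)
  }
  path <- matrix(NA_integer_, 0, 2)
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        sc[i + 1, j + 1] == sc[i, j] + (if (a[i] == b[j]) match else mismatch)) {
      path <- rbind(c(i, j), path); i <- i - 1; j <- j - 1
    } else if (i > 0 && sc[i + 1, j + 1] == sc[i, j + 1] + gap) {
      path <- rbind(c(i, NA), path); i <- i - 1
    } else {
      path <- rbind(c(NA, j), path); j <- j - 1
    }
  }
  path
}

.consensus <- function(mat) {
  # modal symbol per column, ignoring NA; gap-only columns stay gap
  apply(mat, 2L, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(SYM_GAP)
    tab <- tabulate(col, nbins = 6L)
    which.max(tab)
  })
}

#' Impute the non-coding columns of a partially defined allele
#'
#' The donor with the largest number of matching non-gap symbols over the
#' columns where the target is defined (its exon columns) supplies every
#' undefined column; ties are broken by lexicographic donor name so builds
#' are deterministic.
#'
#' @param target integer vector of symbol codes with \code{NA} at undefined
#'   (non-coding) columns.
#' @param donors integer matrix of fully defined donor alleles (rows named
#'   by allele) in the same column space.
#' @return list with \code{seq} (complete integer vector), \code{mask}
#'   (logical, TRUE exactly at filled columns) and \code{donor} (name used,
#'   or NA if nothing was imputed).
#' @export
impute_noncoding <- function(target, donors) {
  if (is.null(dim(donors)) || nrow(donors) == 0L)
    stop("at least one genomic donor allele is required for imputation")
  undef <- is.na(target)
  if (!any(undef))
    return(list(seq = target, mask = rep(FALSE, length(target)), donor = NA))
  def <- which(!undef & target != SYM_GAP)
  sims <- vapply(seq_len(nrow(donors)), function(d)
    sum(donors[d, def] == target[def]), numeric(1))
  ord <- order(-sims, rownames(donors))
  best <- ord[1L]
  out <- target
  out[undef] <- donors[best, undef]
  list(seq = out, mask = undef, donor = rownames(donors)[best])
}

#' Build the integrated MSA of a gene from genomic and exonic alignments
#'
#' Exon blocks of the genomic alignment are reconciled column-by-column with
#' the exonic alignment (gap columns are inserted on either side where the
#' block widths or gap structures differ), every allele is projected into
#' the common column space, and the non-coding columns of exonic-only
#' alleles are filled from the most similar genomic allele
#' (\code{\link{impute_noncoding}}) with the filled positions recorded in a
#' per-allele imputation mask.
#'
#' @param genomic_alleles list of \code{\link{hla_allele}} records at
#'   genomic level, all with aligned sequences of equal length.
#' @param exonic_alleles list of \code{\link{hla_allele}} records at exonic
#'   level (may be empty).
#' @param feature_map character vector labelling each genomic-alignment
#'   column, e.g. "UTR5", "exon1", "intron1", ...; labels starting with
#'   "exon" mark coding columns.
#' @param exonic_feature_map optional labels for the exonic-alignment
#'   columns; when omitted the exonic columns are assumed to be the exon
#'   blocks of \code{feature_map} concatenated in order, which requires
#'   equal total width.
#' @return an object of class \code{hla_msa}: fields \code{gene},
#'   \code{n_col}, \code{alleles} (integer matrix, rows named by allele),
#'   \code{imputed} (logical matrix), \code{feature_map}, \code{level}
#'   (named character) and \code{imputation_donor}.
#' @export
build_integrated_msa <- function(genomic_alleles, exonic_alleles = list(),
                                 feature_map, exonic_feature_map = NULL) {
  stopifnot(length(genomic_alleles) >= 1L)
  genes <- unique(vapply(c(genomic_alleles, exonic_alleles),
                         function(a) a$gene, character(1)))
  if (length(genes) != 1L)
    stop("genomic and exonic alignments mix genes: ",
         paste(genes, collapse = ", "))
  gmat <- do.call(rbind, lapply(genomic_alleles, function(a) a$codes))
  rownames(gmat) <- vapply(genomic_alleles, function(a) a$name, character(1))
  if (length(feature_map) != ncol(gmat))
    stop("feature_map length must equal the genomic alignment width")
  is_exon <- grepl("^exon", feature_map)

  emat <- NULL
  if (length(exonic_alleles)) {
    emat <- do.call(rbind, lapply(exonic_alleles, function(a) a$codes))
    rownames(emat) <- vapply(exonic_alleles, function(a) a$name, character(1))
    exon_labels <- unique(feature_map[is_exon])
    if (is.null(exonic_feature_map)) {
      if (ncol(emat) != sum(is_exon))
        stop("alignment inconsistency: exonic width ", ncol(emat),
             " != genomic exon width ", sum(is_exon),
             " and no exonic_feature_map given")
      exonic_feature_map <- feature_map[is_exon]
    }
    if (length(exonic_feature_map) != ncol(emat))
      stop("exonic_feature_map length must equal the exonic alignment width")
    if (!all(exonic_feature_map %in% exon_labels))
      stop("alignment inconsistency: exonic feature labels not present in ",
           "the genomic feature_map")
  }

  # Merge column spaces block by block.  Each output row: genomic source
  # column (NA = inserted), exonic source column (NA = absent), label.
  out_g <- integer(0); out_e <- integer(0); out_lab <- character(0)
  gcol <- 1L
  while (gcol <= ncol(gmat)) {
    lab <- feature_map[gcol]
    block_end <- gcol
    while (block_end < ncol(gmat) && feature_map[block_end + 1L] == lab)
      block_end <- block_end + 1L
    gcols <- gcol:block_end
    if (grepl("^exon", lab) && !is.null(emat) &&
        any(exonic_feature_map == lab)) {
      ecols <- which(exonic_feature_map == lab)
      path <- .nw_merge(.consensus(gmat[, gcols, drop = FALSE]),
                        .consensus(emat[, ecols, drop = FALSE]))
      out_g <- c(out_g, ifelse(is.na(path[, 1]), NA, gcols[path[, 1]]))
      out_e <- c(out_e, ifelse(is.na(path[, 2]), NA, ecols[path[, 2]]))
      out_lab <- c(out_lab, rep(lab, nrow(path)))
    } else {
      out_g <- c(out_g, gcols)
      out_e <- c(out_e, rep(NA_integer_, length(gcols)))
      out_lab <- c(out_lab, rep(lab, length(gcols)))
    }
    gcol <- block_end + 1L
  }
  n_col <- length(out_g)

  gnames <- rownames(gmat)
  enames <- if (is.null(emat)) character(0) else
    setdiff(rownames(emat), gnames)   # genomic record wins for dual-level
  all_names <- c(gnames, enames)
  alleles <- matrix(NA_integer_, length(all_names), n_col,
                    dimnames = list(all_names, NULL))
  imputed <- matrix(FALSE, length(all_names), n_col,
                    dimnames = list(all_names, NULL))
  level <- c(rep("genomic", length(gnames)), rep("exonic", length(enames)))
  names(level) <- all_names

  gsrc <- !is.na(out_g)
  for (nm in gnames) {
    row <- rep(SYM_GAP, n_col)        # inserted columns are gaps
    row[gsrc] <- gmat[nm, out_g[gsrc]]
    alleles[nm, ] <- row
  }
  esrc <- !is.na(out_e)
  is_exon_out <- grepl("^exon", out_lab)
  donor_used <- setNames(rep(NA_character_, length(all_names)), all_names)
  for (nm in enames) {
    row <- rep(NA_integer_, n_col)
    row[is_exon_out] <- SYM_GAP       # exon columns absent from the exonic
    row[esrc] <- emat[nm, out_e[esrc]]  # alignment stay gaps, never imputed
    imp <- impute_noncoding(row, alleles[gnames, , drop = FALSE])
    alleles[nm, ] <- imp$seq
    imputed[nm, ] <- imp$mask
    donor_used[nm] <- imp$donor
  }

  structure(list(gene = genes, n_col = n_col, alleles = alleles,
                 imputed = imputed, feature_map = out_lab, level = level,
                 imputation_donor = donor_used),
            class = "hla_msa")
}

#' @export
print.hla_msa <- function(x, ...) {
  cat("Integrated HLA MSA: gene", x$gene, "-", nrow(x$alleles), "alleles x",
      x$n_col, "columns (", sum(x$level == "exonic"), "exonic-only )\n")
  invisible(x)
}

#' Project a pairwise read/allele alignment into MSA columns
#'
#' Given the gapped alignment of a read against the ungapped sequence of one
#' allele, assigns every read base (or deletion) the MSA column of the
#' corresponding allele base; read insertions are placed into columns that
#' are gaps in that allele, and a read whose insertion cannot be
#' accommodated raises a condition of class
#' \code{bayeshla_unrepresentable_insertion} (callers drop such reads).
#'
#' @param msa an \code{\link{hla_msa}}.
#' @param allele_name row of the MSA the alignment refers to.
#' @param aligned_read,aligned_allele gapped strings of equal length.
#' @param start_offset 1-based position of the first aligned allele base in
#'   the allele's ungapped sequence.
#' @return list with \code{start_col}, \code{end_col}, \code{sym} (integer
#'   codes over the spanned columns, gaps where the read asserts no
#'   material) and \code{read_pos} (index of the read base placed at each
#'   column, NA at gap columns).
#' @export
project_alignment <- function(msa, allele_name, aligned_read, aligned_allele,
                              start_offset) {
  stopifnot(inherits(msa, "hla_msa"))
  if (!allele_name %in% rownames(msa$alleles))
    stop("unknown allele: ", allele_name)
  row <- msa$alleles[allele_name, ]
  colmap <- which(row != SYM_GAP)     # MSA column of each ungapped base
  r <- encode_seq(aligned_read); t <- encode_seq(aligned_allele)
  if (length(r) != length(t))
    stop("aligned read and allele strings differ in length")
  t_deg <- t[t != SYM_GAP]
  if (start_offset < 1L || start_offset + length(t_deg) - 1L > length(colmap))
    stop("start_offset places the alignment outside the allele")
  if (!identical(unname(t_deg),
                 unname(row[colmap[start_offset + seq_along(t_deg) - 1L]])))
    stop("aligned_allele does not match the allele at start_offset")

  placed_col <- integer(length(r)); placed_col[] <- NA_integer_
  j <- start_offset                   # next allele base (ungapped index)
  last_col <- if (start_offset > 1L) colmap[start_offset - 1L] else 0L
  nbases <- 0L                        # read bases consumed so far
  read_base_idx <- cumsum(r != SYM_GAP)
  for (c in seq_along(r)) {
    if (t[c] != SYM_GAP) {
      placed_col[c] <- colmap[j]
      last_col <- colmap[j]
      j <- j + 1L
    } else {
      # insertion: next free gap column of this allele after last_col and
      # before the next base column
      nxt <- if (j <= length(colmap)) colmap[j] else msa$n_col + 1L
      cand <- last_col + 1L
      while (cand < nxt && (cand %in% placed_col)) cand <- cand + 1L
      if (cand >= nxt || row[cand] != SYM_GAP)
        stop(structure(class = c("bayeshla_unrepresentable_insertion",
                                 "error", "condition"),
                       list(message = paste0(
                         "read insertion cannot be represented in the MSA ",
                         "columns of allele ", allele_name),
                         call = NULL)))
      placed_col[c] <- cand
      last_col <- cand
    }
  }
  start_col <- min(placed_col); end_col <- max(placed_col)
  span <- start_col:end_col
  sym <- rep(SYM_GAP, length(span))
  read_pos <- rep(NA_integer_, length(span))
  for (c in seq_along(r)) {
    pos <- placed_col[c] - start_col + 1L
    sym[pos] <- r[c]
    if (r[c] != SYM_GAP) read_pos[pos] <- read_base_idx[c]
  }
  list(start_col = start_col, end_col = end_col, sym = sym,
       read_pos = read_pos)
}
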