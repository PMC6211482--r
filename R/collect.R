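#' Construct a raw sequencing read (optionally paired)
#'
#' @param id read identifier.
#' @param bases base string over A,C,G,T,N.
#' @param quals integer Phred qualities, one per base.
#' @param mate_bases,mate_quals optional second mate.
#' @return an object of class \code{raw_read}.
#' @export
raw_read <- function(id, bases, quals, mate_bases = NULL, mate_quals = NULL) {
  codes <- encode_seq(bases)
  if (any(codes == SYM_GAP)) stop("raw reads cannot contain gaps")
  if (length(quals) != length(codes))
    stop("bases and quals differ in length")
  if (any(quals < 0)) stop("Phred qualities must be non-negative")
  mate <- NULL
  if (!is.null(mate_bases)) {
    mcodes <- encode_seq(mate_bases)
    if (any(mcodes == SYM_GAP)) stop("raw reads cannot contain gaps")
    if (length(mate_quals) != length(mcodes))
      stop("mate bases and quals differ in length")
    mate <- list(bases = mate_bases, quals = as.integer(mate_quals),
                 codes = mcodes)
  }
  structure(list(id = id, bases = bases, quals = as.integer(quals),
                 codes = codes, mate = mate),
            class = "raw_read")
}

#' HR score of a read/allele alignment
#'
#' Scores a gapped pairwise alignment column by column: a mismatch of two
#' concrete bases adds \code{log(p/3)} with \code{p} the quality-implied
#' mismatch probability of the read base; a read gap adds the deletion
#' open/extend penalty according to whether the previous read column was
#' already a gap (likewise allele gaps with the insertion penalties); an N
#' opposite a concrete symbol adds \code{alpha_N}; and every column where
#' the read carries a symbol additionally earns the length reward
#' \code{beta}.  Natural logarithms throughout.
#'
#' @param aligned_read,aligned_type gapped strings of equal length, never
#'   both gap in one column.
#' @param quals Phred qualities of the read bases (length = number of
#'   non-gap read symbols).
#' @param params a \code{\link{score_params}} object.
#' @return scalar HR score.
#' @export
hr_score <- function(aligned_read, aligned_type, quals, params) {
  r <- encode_seq(aligned_read); t <- encode_seq(aligned_type)
  if (length(r) != length(t))
    stop("aligned read and type strings differ in length")
  if (any(r == SYM_GAP & t == SYM_GAP))
    stop("alignment column with gaps on both sides")
  nb <- sum(r != SYM_GAP)
  if (length(quals) != nb)
    stop("quals must have one entry per read base")
  p <- mismatch_prob(quals)
  pcol <- rep(NA_real_, length(r))
  pcol[r != SYM_GAP] <- p
  score <- 0
  prev_r_gap <- FALSE; prev_t_gap <- FALSE
  for (n in seq_along(r)) {
    rn <- r[n]; tn <- t[n]
    if (rn == SYM_GAP) {
      score <- score + if (prev_r_gap) params$alpha_del_ext else
        params$alpha_del_open
    } else if (tn == SYM_GAP) {
      score <- score + (if (prev_t_gap) params$alpha_ins_ext else
        params$alpha_ins_open) + params$beta
    } else if (rn == SYM_N || tn == SYM_N) {
      score <- score + params$alpha_N + params$beta
    } else if (rn != tn) {
      score <- score + log(pcol[n] / 3) + params$beta
    } else {
      score <- score + params$beta
    }
    prev_r_gap <- rn == SYM_GAP
    prev_t_gap <- tn == SYM_GAP
  }
  score
}

# degapped sequence of one MSA row
.msa_ungapped <- function(msa, name) {
  row <- msa$alleles[name, ]
  row[row != SYM_GAP]
}

#' Score a read against every allele of a reference panel
#'
#' Aligns the read to the ungapped sequence of each allele of each gene with
#' the built-in affine-gap semi-global aligner (whose objective is the HR
#' score itself) and records the per-type scores, the best score within the
#' target gene (\code{s_star}), the best score in any other gene
#' (\code{s_bar_star}, \code{-Inf} when the panel holds a single gene) and
#' the best target type (ties broken by lexicographic allele name).
#'
#' @param read a \code{\link{raw_read}} (single mate scored; see
#'   \code{\link{score_read_pair}} for pairs).
#' @param db named list of \code{\link{hla_msa}} panels, one per gene.
#' @param target_gene name of the target gene in \code{db}.
#' @param params a \code{\link{score_params}} object.
#' @return an object of class \code{hr_table}: fields \code{scores} (named
#'   list per gene of named numeric vectors), \code{s_star},
#'   \code{s_bar_star}, \code{best_type}.
#' @export
score_read_against_db <- function(read, db, target_gene,
                                  params = score_params()) {
  if (!length(db)) stop("reference panel is empty")
  if (!target_gene %in% names(db))
    stop("target gene not in reference panel: ", target_gene)
  phat <- mismatch_prob(read$quals)
  scores <- lapply(db, function(msa) {
    nms <- rownames(msa$alleles)
    sc <- cpp_score_db(read$codes, phat,
                       lapply(nms, function(nm) .msa_ungapped(msa, nm)),
                       params$alpha_del_open, params$alpha_del_ext,
                       params$alpha_ins_open, params$alpha_ins_ext,
                       params$alpha_N, params$beta)
    setNames(sc, nms)
  })
  tg <- scores[[target_gene]]
  ord <- order(-tg, names(tg))
  s_star <- tg[ord[1L]]
  others <- unlist(scores[setdiff(names(db), target_gene)], use.names = FALSE)
  s_bar_star <- if (length(others)) max(others) else -Inf
  structure(list(scores = scores, s_star = unname(s_star),
                 s_bar_star = s_bar_star,
                 best_type = names(tg)[ord[1L]],
                 target_gene = target_gene, id = read$id),
            class = "hr_table")
}

#' Score both mates of a read (pair-aware wrapper)
#'
#' @inheritParams score_read_against_db
#' @return for unpaired reads the \code{hr_table}; for pairs a list of class
#'   \code{hr_pair} with fields \code{mate1}, \code{mate2}.
#' @export
score_read_pair <- function(read, db, target_gene, params = score_params()) {
  t1 <- score_read_against_db(read, db, target_gene, params)
  if (is.null(read$mate)) return(t1)
  m <- raw_read(paste0(read$id, "/2"), read$mate$bases, read$mate$quals)
  t2 <- score_read_against_db(m, db, target_gene, params)
  structure(list(mate1 = t1, mate2 = t2, id = read$id), class = "hr_pair")
}

#' Decide which scored reads belong to the target gene
#'
#' An unpaired read is accepted iff \code{s_star > theta_u_m} and
#' \code{s_star - s_bar_star > theta_u_d} (strict); a pair is accepted iff
#' the mate sums clear \code{theta_p_m} and \code{theta_p_d}.  A score of
#' \code{-Inf} never passes.
#'
#' @param tables list of \code{hr_table} / \code{hr_pair} objects.
#' @param params a \code{\link{score_params}}.
#' @return logical vector of decisions, with attribute \code{"log"}: a
#'   data.frame (id, paired, s_star, s_bar_star, accepted).
#' @export
filter_reads <- function(tables, params = score_params()) {
  rows <- lapply(tables, function(tb) {
    if (inherits(tb, "hr_pair")) {
      s <- tb$mate1$s_star + tb$mate2$s_star
      sb <- tb$mate1$s_bar_star + tb$mate2$s_bar_star
      acc <- is.finite(s) && s > params$theta_p_m &&
        (s - sb) > params$theta_p_d
      data.frame(id = tb$id, paired = TRUE, s_star = s, s_bar_star = sb,
                 accepted = acc)
    } else {
      s <- tb$s_star; sb <- tb$s_bar_star
      acc <- is.finite(s) && s > params$theta_u_m &&
        (s - sb) > params$theta_u_d
      data.frame(id = tb$id, paired = FALSE, s_star = s, s_bar_star = sb,
                 accepted = acc)
    }
  })
  log <- do.call(rbind, rows)
  structure(log$accepted, log = log)
}

# best target-gene type for a read or pair (pair: argmax of summed scores);
# ties broken by lexicographic allele name
.best_type <- function(tb) {
  if (inherits(tb, "hr_pair")) {
    sc <- tb$mate1$scores[[tb$mate1$target_gene]] +
      tb$mate2$scores[[tb$mate2$target_gene]]
  } else {
    sc <- tb$scores[[tb$target_gene]]
  }
  names(sc)[order(-sc, names(sc))][1L]
}

# align one mate against one allele and project into MSA columns;
# returns NULL when the read does not align or an insertion is
# unrepresentable
.project_mate <- function(codes, quals, msa, type_name, params) {
  phat <- mismatch_prob(quals)
  aln <- cpp_align_read(codes, phat, .msa_ungapped(msa, type_name),
                        params$alpha_del_open, params$alpha_del_ext,
                        params$alpha_ins_open, params$alpha_ins_ext,
                        params$alpha_N, params$beta)
  if (!is.finite(aln$score)) return(NULL)
  rsym <- ifelse(aln$read_idx > 0, HLA_SYMBOLS[codes[pmax(aln$read_idx, 1L)]],
                 "-")
  tsym <- ifelse(aln$allele_idx > 0,
                 HLA_SYMBOLS[.msa_ungapped(msa, type_name)[
                   pmax(aln$allele_idx, 1L)]], "-")
  proj <- tryCatch(
    project_alignment(msa, type_name, paste(rsym, collapse = ""),
                      paste(tsym, collapse = ""), aln$start_offset),
    bayeshla_unrepresentable_insertion = function(e) NULL)
  if (is.null(proj)) return(NULL)
  qcol <- rep(NA_integer_, length(proj$sym))
  qcol[!is.na(proj$read_pos)] <- quals[proj$read_pos[!is.na(proj$read_pos)]]
  list(start = proj$start_col, sym = proj$sym, qual = qcol)
}

#' Realign accepted reads into the integrated MSA columns
#'
#' Each accepted read (or pair) is aligned against its best target type and
#' projected into MSA columns; mates are concatenated into one record whose
#' inter-mate columns stay uncovered.  Reads with unrepresentable
#' insertions are dropped and counted.
#'
#' @param reads list of \code{\link{raw_read}} objects.
#' @param tables matching list of score tables
#'   (\code{\link{score_read_pair}}).
#' @param msa the target gene's \code{\link{hla_msa}}.
#' @param accepted logical vector from \code{\link{filter_reads}}; only
#'   these reads are realigned.
#' @param params a \code{\link{score_params}}.
#' @return an object of class \code{hla_reads}: \code{ids}, \code{sym}
#'   (integer matrix reads x columns, 0 = uncovered), \code{phat} (matched
#'   mismatch probabilities), \code{best_type}, and attribute
#'   \code{"n_dropped"}.
#' @export
realign_accepted <- function(reads, tables, msa, accepted = NULL,
                             params = score_params()) {
  stopifnot(length(reads) == length(tables))
  if (is.null(accepted)) accepted <- rep(TRUE, length(reads))
  keep <- which(accepted)
  n_col <- msa$n_col
  ids <- character(0); best <- character(0)
  rows_sym <- list(); rows_phat <- list()
  dropped <- 0L
  for (j in keep) {
    rd <- reads[[j]]; tb <- tables[[j]]
    bt <- .best_type(tb)
    sym <- integer(n_col); phat <- numeric(n_col)
    p1 <- .project_mate(rd$codes, rd$quals, msa, bt, params)
    if (is.null(p1)) { dropped <- dropped + 1L; next }
    span <- p1$start + seq_along(p1$sym) - 1L
    sym[span] <- p1$sym
    phat[span] <- ifelse(is.na(p1$qual), 0, mismatch_prob(
      ifelse(is.na(p1$qual), 0L, p1$qual)))
    if (!is.null(rd$mate)) {
      p2 <- .project_mate(rd$mate$codes, rd$mate$quals, msa, bt, params)
      if (is.null(p2)) { dropped <- dropped + 1L; next }
      span2 <- p2$start + seq_along(p2$sym) - 1L
      fresh <- sym[span2] == 0L          # mate1 wins where mates overlap
      sym[span2[fresh]] <- p2$sym[fresh]
      phat[span2[fresh]] <- ifelse(is.na(p2$qual[fresh]), 0, mismatch_prob(
        ifelse(is.na(p2$qual[fresh]), 0L, p2$qual[fresh])))
    }
    ids <- c(ids, rd$id); best <- c(best, bt)
    rows_sym[[length(rows_sym) + 1L]] <- sym
    rows_phat[[length(rows_phat) + 1L]] <- phat
  }
  if (dropped > 0L)
    warning(dropped, " read(s) dropped (no alignment or unrepresentable ",
            "insertion)")
  out <- list(ids = ids,
              sym = if (length(rows_sym)) do.call(rbind, rows_sym) else
                matrix(integer(0), 0, n_col),
              phat = if (length(rows_phat)) do.call(rbind, rows_phat) else
                matrix(numeric(0), 0, n_col),
              best_type = best)
  attr(out, "n_dropped") <- dropped
  class(out) <- "hla_reads"
  out
}
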