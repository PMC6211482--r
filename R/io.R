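# File formats are documented in inst/FORMATS.md.  FASTA/FASTQ go through
# Biostrings; tables are plain TSV via base R.

.read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), names(x))
}

.write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
}

#' Write a mock (or converted) reference bundle to aligned-FASTA + TSV
#'
#' @param db a \code{\link{generate_mock_db}} bundle.
#' @param fasta,meta output paths.
#' @return invisibly, the two paths.
#' @export
write_reference_bundle <- function(db, fasta, meta) {
  seqs <- c(
    setNames(vapply(db$genomic, function(a) a$seq, character(1)),
             vapply(db$genomic, function(a) a$name, character(1))),
    setNames(vapply(db$exonic, function(a) a$seq, character(1)),
             vapply(db$exonic, function(a) a$name, character(1))),
    setNames(vapply(db$homolog$genomic, function(a) a$seq, character(1)),
             vapply(db$homolog$genomic, function(a) a$name, character(1))))
  .write_fasta(seqs, fasta)
  rows <- rbind(
    data.frame(record = "allele", gene = db$gene,
               name = vapply(db$genomic, function(a) a$name, character(1)),
               level = "genomic", start = NA, end = NA),
    if (length(db$exonic))
      data.frame(record = "allele", gene = db$gene,
                 name = vapply(db$exonic, function(a) a$name, character(1)),
                 level = "exonic", start = NA, end = NA),
    if (length(db$homolog$genomic))
      data.frame(record = "allele", gene = db$homolog$gene,
                 name = vapply(db$homolog$genomic, function(a) a$name,
                               character(1)),
                 level = "genomic", start = NA, end = NA))
  fm <- db$feature_map
  runs <- rle(fm)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  for (g in unique(rows$gene))
    rows <- rbind(rows, data.frame(record = "feature", gene = g,
                                   name = runs$values, level = "genomic",
                                   start = starts, end = ends))
  utils::write.table(rows, meta, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta, meta))
}

#' Read a reference bundle and build per-gene integrated MSAs
#'
#' @param fasta aligned-FASTA of allele sequences (genomic and exonic rows
#'   may have different widths).
#' @param meta TSV with allele rows (record=allele: gene, name, level) and
#'   feature rows (record=feature: gene, name=label, start, end in genomic
#'   alignment columns).
#' @return named list of \code{\link{hla_msa}}, one per gene.
#' @export
read_reference_bundle <- function(fasta, meta) {
  seqs <- .read_fasta(fasta)
  tab <- utils::read.delim(meta, stringsAsFactors = FALSE)
  out <- list()
  for (g in unique(tab$gene[tab$record == "allele"])) {
    al <- tab[tab$record == "allele" & tab$gene == g, ]
    fe <- tab[tab$record == "feature" & tab$gene == g, ]
    fe <- fe[order(fe$start), ]
    fmap <- rep(fe$name, fe$end - fe$start + 1L)
    genomic <- list(); exonic <- list()
    for (r in seq_len(nrow(al))) {
      a <- hla_allele(g, al$name[r], al$level[r], seqs[[al$name[r]]])
      if (al$level[r] == "genomic") genomic[[length(genomic) + 1L]] <- a
      else exonic[[length(exonic) + 1L]] <- a
    }
    out[[g]] <- build_integrated_msa(genomic, exonic, fmap)
  }
  out
}

#' Write an integrated MSA as aligned-FASTA plus an imputation-mask TSV
#'
#' @param msa an \code{\link{hla_msa}}.
#' @param fasta,mask_tsv output paths.
#' @return invisibly, the two paths.
#' @export
write_integrated_msa <- function(msa, fasta, mask_tsv) {
  seqs <- apply(msa$alleles, 1L, decode_seq)
  .write_fasta(seqs, fasta)
  idx <- which(msa$imputed, arr.ind = TRUE)
  tab <- data.frame(allele = rownames(msa$alleles)[idx[, 1]],
                    column = idx[, 2], imputed = 1L)
  utils::write.table(tab[order(tab$allele, tab$column), ], mask_tsv,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta, mask_tsv))
}

#' Write simulated reads as a FASTQ pair
#'
#' @param sim a \code{\link{simulate_reads}} result.
#' @param prefix path prefix; writes \code{<prefix>_1.fastq} and
#'   \code{<prefix>_2.fastq}.
#' @return invisibly, the two paths.
#' @export
write_fastq <- function(sim, prefix) {
  enc <- function(reads, mate) {
    s <- Biostrings::DNAStringSet(vapply(reads, function(r)
      if (mate == 1) r$bases else r$mate$bases, character(1)))
    names(s) <- vapply(reads, function(r) r$id, character(1))
    q <- Biostrings::PhredQuality(vapply(reads, function(r) {
      qq <- if (mate == 1) r$quals else r$mate$quals
      rawToChar(as.raw(qq + 33L))
    }, character(1)))
    list(s = s, q = q)
  }
  p1 <- paste0(prefix, "_1.fastq"); p2 <- paste0(prefix, "_2.fastq")
  e1 <- enc(sim$reads, 1)
  Biostrings::writeXStringSet(e1$s, p1, format = "fastq", qualities = e1$q)
  e2 <- enc(sim$reads, 2)
  Biostrings::writeXStringSet(e2$s, p2, format = "fastq", qualities = e2$q)
  invisible(c(p1, p2))
}

#' Read paired FASTQ files into raw reads
#'
#' @param path1,path2 FASTQ paths (\code{path2} optional for unpaired
#'   reads).
#' @return list of \code{\link{raw_read}}.
#' @export
read_fastq <- function(path1, path2 = NULL) {
  r1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path1))
  b1 <- as.character(r1)
  q1 <- lapply(as(Biostrings::quality(r1), "IntegerList"), as.integer)
  ids <- sub("\\s.*$", "", names(r1))
  if (is.null(path2))
    return(lapply(seq_along(b1), function(i)
      raw_read(ids[i], b1[[i]], q1[[i]])))
  r2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path2))
  b2 <- as.character(r2)
  q2 <- lapply(as(Biostrings::quality(r2), "IntegerList"), as.integer)
  lapply(seq_along(b1), function(i)
    raw_read(ids[i], b1[[i]], q1[[i]], b2[[i]], q2[[i]]))
}

#' Read / write the flat key=value configuration format
#'
#' Lines of the form \code{key = value}; blank lines and \code{#} comments
#' ignored; values parsed as numbers when possible, \code{true/false} as
#' logicals, comma-separated values as vectors.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(parts))
    parsed <- if (!anyNA(num)) num
    else if (all(tolower(parts) %in% c("true", "false")))
      tolower(parts) == "true"
    else parts
    out[[key]] <- parsed
  }
  out
}

#' @rdname read_config
#' @param config named list of scalar or vector values.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    paste0(k, " = ", paste(config[[k]], collapse = ",")), character(1))
  writeLines(lines, path)
  invisible(path)
}
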