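# Realigned-read archive: one row per accepted read with its full-width
# symbol string ('.' = uncovered) and comma-separated Phred-like error
# probabilities at covered columns.
write_reads_tsv <- function(reads, path) {
  n <- length(reads$ids)
  rows <- data.frame(
    id = reads$ids,
    best_type = reads$best_type,
    sym = vapply(seq_len(n), function(i) decode_seq(reads$sym[i, ]),
                 character(1)),
    phat = vapply(seq_len(n), function(i) {
      cov <- reads$sym[i, ] > 0L
      paste(signif(reads$phat[i, cov], 6), collapse = ",")
    }, character(1)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_reads_tsv <- function(path, n_col) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  n <- nrow(tab)
  sym <- matrix(0L, n, n_col); phat <- matrix(0, n, n_col)
  for (i in seq_len(n)) {
    chars <- strsplit(tab$sym[i], "", fixed = TRUE)[[1L]]
    codes <- match(chars, HLA_SYMBOLS)
    codes[is.na(codes)] <- 0L
    sym[i, ] <- codes
    cov <- codes > 0L
    if (nzchar(tab$phat[i]))
      phat[i, cov] <- as.numeric(strsplit(tab$phat[i], ",",
                                          fixed = TRUE)[[1L]])
  }
  structure(list(ids = tab$id, sym = sym, phat = phat,
                 best_type = tab$best_type), class = "hla_reads")
}

read_integrated_msa <- function(fasta, mask_tsv, gene = "A") {
  seqs <- .read_fasta(fasta)
  alleles <- do.call(rbind, lapply(seqs, encode_seq))
  rownames(alleles) <- names(seqs)
  imputed <- matrix(FALSE, nrow(alleles), ncol(alleles),
                    dimnames = list(rownames(alleles), NULL))
  if (file.exists(mask_tsv)) {
    tab <- utils::read.delim(mask_tsv, stringsAsFactors = FALSE)
    if (nrow(tab))
      imputed[cbind(match(tab$allele, rownames(alleles)), tab$column)] <- TRUE
  }
  structure(list(gene = gene, n_col = ncol(alleles), alleles = alleles,
                 imputed = imputed,
                 feature_map = rep(NA_character_, ncol(alleles)),
                 level = setNames(rep("genomic", nrow(alleles)),
                                  rownames(alleles)),
                 imputation_donor = NULL),
            class = "hla_msa")
}

.cfg_get <- function(config, key, default) {
  if (!is.null(config[[key]])) config[[key]] else default
}

.sampler_from_config <- function(config, seed) {
  sampler_config(
    temperatures = .cfg_get(config, "temperatures", c(1, 1.05, 1.11, 1.18)),
    n_burnin = .cfg_get(config, "n_burnin", 2000L),
    n_samples = .cfg_get(config, "n_samples", 8000L),
    thin = .cfg_get(config, "thin", 1L),
    mh_period = .cfg_get(config, "mh_period", 25L),
    multi_start = .cfg_get(config, "multi_start", 8L),
    multi_start_len = .cfg_get(config, "multi_start_len", 200L),
    copy_period = .cfg_get(config, "copy_period", 250L),
    seed = seed)
}

.hp_from_config <- function(config) {
  hp_args <- intersect(names(config), names(formals(hla_hyperparams)))
  do.call(hla_hyperparams, config[hp_args])
}

.sp_from_config <- function(config) {
  sp_args <- intersect(names(config), names(formals(score_params)))
  do.call(score_params, config[sp_args])
}

.stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full pipeline: collect, score, filter, sample, call
#'
#' Drives all stages for one target gene: load (or simulate) the reference
#' bundle and reads, score every read against every allele, filter, realign
#' into MSA columns, run the sampler and write the genotype table,
#' consensus sequences, trace, realigned-read archive and a JSON run
#' manifest into \code{out_dir}.  All randomness flows from the single
#' \code{seed}.
#'
#' @param config named list or path to a key=value config file.  Required:
#'   \code{out_dir}; either \code{simulate = TRUE} (with optional
#'   \code{sim_*} keys and \code{sim_genotype}) or \code{reference_fasta} +
#'   \code{reference_meta} + \code{reads_1} (+ \code{reads_2}).  Optional:
#'   \code{target_gene}, \code{seed}, sampler keys (\code{n_burnin},
#'   \code{n_samples}, ...), hyperparameter and score-threshold overrides.
#' @return invisibly, a list with the posterior summary, genotype table,
#'   consensus calls, realigned reads, the MSA panel and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config must set out_dir")
  seed <- as.integer(.cfg_get(config, "seed", 1L))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)

  input_files <- character(0)
  if (isTRUE(config$simulate)) {
    .stage_log("simulate", "generating mock reference and reads")
    scfg <- sim_config(
      n_alleles = .cfg_get(config, "sim_n_alleles", 20L),
      length = .cfg_get(config, "sim_length", 1000L),
      divergence = .cfg_get(config, "sim_divergence", 0.02),
      coverage = .cfg_get(config, "sim_coverage", 10),
      contam_frac = .cfg_get(config, "sim_contam_frac", 0),
      seed = seed)
    db <- generate_mock_db(scfg)
    panel <- mock_db_msa(db)
    gt <- .cfg_get(config, "sim_genotype",
                   names(db$truth$sequences)[1:2])
    sim <- simulate_reads(db, gt, scfg, seed = seed + 1L)
    reads <- sim$reads
    target_gene <- db$gene
  } else {
    for (key in c("reference_fasta", "reference_meta", "reads_1"))
      if (is.null(config[[key]]) || !file.exists(config[[key]]))
        stop("config error: missing input file for '", key, "'")
    if (!is.null(config$reads_2) && !file.exists(config$reads_2))
      stop("config error: missing input file for 'reads_2'")
    .stage_log("extract", "loading reference bundle and reads")
    panel <- read_reference_bundle(config$reference_fasta,
                                   config$reference_meta)
    reads <- read_fastq(config$reads_1, config$reads_2)
    target_gene <- .cfg_get(config, "target_gene", names(panel)[1L])
    input_files <- c(config$reference_fasta, config$reference_meta,
                     config$reads_1, config$reads_2)
  }
  msa <- panel[[target_gene]]

  .stage_log("score", length(reads), " reads vs ",
             sum(vapply(panel, function(m) nrow(m$alleles), integer(1))),
             " alleles")
  sp <- .sp_from_config(config)
  tables <- lapply(reads, score_read_pair, db = panel,
                   target_gene = target_gene, params = sp)
  accepted <- filter_reads(tables, sp)
  log <- attr(accepted, "log")
  utils::write.table(log, file.path(out_dir, "filter_log.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .stage_log("filter", sum(accepted), "/", length(accepted),
             " reads accepted")

  realigned <- suppressWarnings(
    realign_accepted(reads, tables, msa, accepted, sp))
  n_dropped <- attr(realigned, "n_dropped")
  write_reads_tsv(realigned, file.path(out_dir, "reads_realigned.tsv"))
  write_integrated_msa(msa, file.path(out_dir, "integrated_msa.fasta"),
                       file.path(out_dir, "imputed_mask.tsv"))

  hp <- .hp_from_config(config)
  model <- build_model(msa, realigned, hp)
  cfg <- .sampler_from_config(config, seed)
  .stage_log("genotype", "running MCMC (", cfg$n_burnin, " burn-in + ",
             cfg$n_samples, " samples)")
  summary <- run_mcmc(model, cfg)

  geno <- call_genotype(summary)
  geno <- cbind(gene = target_gene, geno)
  utils::write.table(geno, file.path(out_dir, "genotype.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cons <- call_sequences(summary,
                         .cfg_get(config, "min_support", 0.9))
  .write_fasta(setNames(attr(cons, "sequences"),
                        paste0(target_gene, "_hap", 1:2)),
               file.path(out_dir, "consensus.fasta"))
  supp <- rbind(cbind(seq = 1L, cons[[1]]), cbind(seq = 2L, cons[[2]]))
  utils::write.table(supp, file.path(out_dir, "consensus_support.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sweep = seq_along(summary$trace),
               log_posterior = summary$trace),
    file.path(out_dir, "trace.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  manifest <- list(
    package = "BayesHLA",
    version = as.character(utils::packageVersion("BayesHLA")),
    seed = seed,
    target_gene = target_gene,
    config = config[setdiff(names(config), "out_dir")],
    input_digests = if (length(input_files))
      as.list(tools::md5sum(input_files[!vapply(input_files, is.null,
                                                logical(1))])) else list(),
    counts = list(reads_in = length(reads),
                  accepted = sum(accepted),
                  dropped_unrepresentable = n_dropped,
                  kept_samples = summary$n_samples),
    outputs = c("filter_log.tsv", "reads_realigned.tsv",
                "integrated_msa.fasta", "imputed_mask.tsv", "genotype.tsv",
                "consensus.fasta", "consensus_support.tsv", "trace.tsv"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .stage_log("done", "outputs in ", out_dir)
  invisible(list(summary = summary, genotype = geno, consensus = cons,
                 reads = realigned, msa = msa, out_dir = out_dir))
}

#' Extract candidate HLA reads from an indexed alignment file
#'
#' Returns reads overlapping the HLA region, unmapped reads, and the mates
#' of selected reads, deduplicated by read id and mate flag.  Needs the
#' optional Rsamtools package; plain SAM input is converted on the fly.
#'
#' @param alignment_file BAM (indexed) or SAM path.
#' @param region region string, default the hg19 HLA region
#'   \code{chr6:28477797-33448354}.
#' @return list of \code{\link{raw_read}} (mates paired by read id).
#' @export
extract_candidate_reads <- function(alignment_file,
                                    region = "chr6:28477797-33448354") {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("extract_candidate_reads needs the Rsamtools package")
  if (grepl("\\.sam$", alignment_file)) {
    alignment_file <- Rsamtools::asBam(alignment_file,
                                       tempfile(), overwrite = TRUE,
                                       indexDestination = TRUE)
  }
  m <- regmatches(region,
                  regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", region))[[1L]]
  if (length(m) != 4L) stop("malformed region: ", region)
  chr <- m[2L]
  lo <- as.numeric(gsub(",", "", m[3L]))
  hi <- as.numeric(gsub(",", "", m[4L]))
  what <- c("qname", "flag", "rname", "pos", "seq", "qual")
  all <- Rsamtools::scanBam(alignment_file,
                            param = Rsamtools::ScanBamParam(what = what))[[1L]]
  n <- length(all$qname)
  if (n == 0L) {
    warning("alignment file holds no reads")
    return(list())
  }
  unmapped <- bitwAnd(all$flag, 4L) != 0L
  in_region <- !unmapped & !is.na(all$rname) & as.character(all$rname) == chr &
    !is.na(all$pos) & all$pos <= hi &
    (all$pos + Biostrings::width(all$seq) - 1L) >= lo
  sel_ids <- unique(all$qname[unmapped | in_region])
  keep <- all$qname %in% sel_ids           # mates of selected reads too
  first <- bitwAnd(all$flag, 64L) != 0L
  key <- paste(all$qname, ifelse(first, 1L, 2L))
  keep <- keep & !duplicated(key)
  idx <- which(keep)
  by_id <- split(idx, all$qname[idx])
  lapply(names(by_id), function(id) {
    ii <- by_id[[id]]
    ii <- ii[order(!bitwAnd(all$flag[ii], 64L))]   # first-of-pair first
    bases <- as.character(all$seq[ii])
    quals <- lapply(as(all$qual[ii], "IntegerList"), as.integer)
    if (length(ii) >= 2L)
      raw_read(id, bases[1L], quals[[1L]], bases[2L], quals[[2L]])
    else raw_read(id, bases[1L], quals[[1L]])
  })
}

#' Command-line entry point
#'
#' Subcommands: \code{run} (full pipeline from a config file),
#' \code{simulate} (write a mock reference bundle and FASTQ pair),
#' \code{somatic} (compare the consensus of two finished runs),
#' \code{loh} (depth log-odds screen from two finished runs).
#'
#' @param args character vector, default \code{commandArgs(TRUE)}.
#' @return exit status, invisibly.
#' @export
hla_cli <- function(args = commandArgs(TRUE)) {
  usage <- paste(
    "usage: bayeshla <command> ...",
    "  run <config>                      full pipeline",
    "  simulate <config> <out_prefix>    mock reference + reads",
    "  somatic <normal_dir> <tumor_dir> <out_tsv>",
    "  loh <normal_dir> <tumor_dir> <out_tsv>", sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1L]
  if (cmd == "run") {
    run_pipeline(args[2L])
    return(invisible(0L))
  }
  if (cmd == "simulate") {
    config <- read_config(args[2L])
    seed <- as.integer(.cfg_get(config, "seed", 1L))
    scfg <- sim_config(
      n_alleles = .cfg_get(config, "sim_n_alleles", 20L),
      length = .cfg_get(config, "sim_length", 1000L),
      divergence = .cfg_get(config, "sim_divergence", 0.02),
      coverage = .cfg_get(config, "sim_coverage", 10),
      seed = seed)
    db <- generate_mock_db(scfg)
    gt <- .cfg_get(config, "sim_genotype", names(db$truth$sequences)[1:2])
    sim <- simulate_reads(db, gt, scfg, seed = seed + 1L)
    prefix <- args[3L]
    write_reference_bundle(db, paste0(prefix, "_ref.fasta"),
                           paste0(prefix, "_ref.tsv"))
    write_fastq(sim, prefix)
    jsonlite::write_json(list(genotype = gt, seed = seed),
                         paste0(prefix, "_truth.json"), auto_unbox = TRUE)
    return(invisible(0L))
  }
  if (cmd %in% c("somatic", "loh")) {
    ndir <- args[2L]; tdir <- args[3L]; out <- args[4L]
    read_cons <- function(d) {
      tab <- utils::read.delim(file.path(d, "consensus_support.tsv"),
                               stringsAsFactors = FALSE,
                               colClasses = c(symbol = "character"))
      split(tab[, c("column", "symbol", "support")], tab$seq)
    }
    ncons <- read_cons(ndir); tcons <- read_cons(tdir)
    if (cmd == "somatic") {
      calls <- call_somatic_mutations(ncons, tcons)
      utils::write.table(calls, out, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      return(invisible(0L))
    }
    msa <- read_integrated_msa(file.path(ndir, "integrated_msa.fasta"),
                               file.path(ndir, "imputed_mask.tsv"))
    ng <- utils::read.delim(file.path(ndir, "genotype.tsv"))
    tg <- utils::read.delim(file.path(tdir, "genotype.tsv"))
    nreads <- read_reads_tsv(file.path(ndir, "reads_realigned.tsv"),
                             msa$n_col)
    treads <- read_reads_tsv(file.path(tdir, "reads_realigned.tsv"),
                             msa$n_col)
    rep <- screen_loh(ng, tg, nreads, treads, msa, always_report = TRUE)
    utils::write.table(rep$snp_table, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(0L))
  }
  message(usage)
  invisible(1L)
}
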