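#' MCMC sampler configuration
#'
#' Defaults are tuned for desk-scale problems (a few hundred reads, 20-100
#' alleles); full-scale analyses would raise the sweep counts.  The
#' temperature ladder always starts at 1 (only the cold chain is
#' summarized); the reference-copy heuristic and the multi-start phase act
#' in the burn-in period only, so kept samples still follow the posterior.
#'
#' @param temperatures increasing ladder starting at 1.
#' @param n_burnin,n_samples,thin sweep counts; kept samples =
#'   \code{n_samples}, recorded every \code{thin} sweeps after burn-in.
#' @param mh_period run the two Metropolis-Hastings proposals every this
#'   many sweeps (0 = never).
#' @param multi_start,multi_start_len number and length of short exploratory
#'   chains whose best end states seed the main chains.
#' @param copy_period during burn-in, copy the reference sequence of each
#'   component's current type over its sequence every this many sweeps
#'   (0 = never).
#' @param seed integer RNG seed; recorded in every output.
#' @return an object of class \code{sampler_config}.
#' @export
sampler_config <- function(temperatures = c(1, 1.05, 1.11, 1.18),
                           n_burnin = 2000L, n_samples = 8000L, thin = 1L,
                           mh_period = 25L,
                           multi_start = 8L, multi_start_len = 200L,
                           copy_period = 250L, seed = 1L) {
  if (temperatures[1] != 1 || is.unsorted(temperatures))
    stop("temperature ladder must start at 1 and be non-decreasing")
  if (thin < 1L || n_samples < 0L || n_burnin < 0L)
    stop("invalid sweep counts")
  structure(list(temperatures = temperatures,
                 n_burnin = as.integer(n_burnin),
                 n_samples = as.integer(n_samples), thin = as.integer(thin),
                 mh_period = as.integer(mh_period),
                 multi_start = as.integer(multi_start),
                 multi_start_len = as.integer(multi_start_len),
                 copy_period = as.integer(copy_period),
                 seed = as.integer(seed)),
            class = "sampler_config")
}

# pack the model fields consumed by the compiled core
.model_pack <- function(model) {
  list(logL = model$logL, cov = model$cov, refdb = model$refdb,
       impdb = model$impdb, log_freq = model$log_freq,
       log_decoy = model$log_decoy, prior_tab = model$prior_tab,
       log_ind = model$log_ind, K = model$K)
}

.random_state <- function(model) {
  K <- model$K
  R <- sample.int(model$n_types, K, replace = TRUE)
  S <- model$refdb[R, , drop = FALSE]
  I <- sample.int(K, nrow(model$reads$sym), replace = TRUE)
  hla_state(R, S, I)
}

#' Gibbs updates of sequences, types, or indicators
#'
#' Resample each targeted block from its full conditional under the
#' tempered posterior: sequences column-wise given type and assigned reads,
#' types given sequences, indicators given sequences.
#'
#' @param state an \code{\link{hla_state}}.
#' @param model an \code{\link{hla_model}}.
#' @param temperature chain temperature (1 = posterior).
#' @return the updated \code{hla_state}.
#' @export
gibbs_update_S <- function(state, model, temperature = 1) {
  st <- cpp_gibbs_update(.model_pack(model), state, temperature, "S")
  hla_state(st$R, st$S, st$I)
}

#' @rdname gibbs_update_S
#' @export
gibbs_update_R <- function(state, model, temperature = 1) {
  st <- cpp_gibbs_update(.model_pack(model), state, temperature, "R")
  hla_state(st$R, st$S, st$I)
}

#' @rdname gibbs_update_S
#' @export
gibbs_update_I <- function(state, model, temperature = 1) {
  st <- cpp_gibbs_update(.model_pack(model), state, temperature, "I")
  hla_state(st$R, st$S, st$I)
}

#' Sequence of a component with uncovered columns masked to N
#'
#' @param state an \code{\link{hla_state}}.
#' @param model an \code{\link{hla_model}}.
#' @param k component index.
#' @return integer symbol vector; N wherever no read assigned to \code{k}
#'   covers the column (the gap between mates counts as uncovered).
#' @export
build_SN <- function(state, model, k) {
  cpp_build_SN(.model_pack(model), state, k)
}

#' Metropolis-Hastings type jump through the N-masked sequence
#'
#' Proposes a new type for component \code{k} from its posterior given the
#' N-masked sequence, a new sequence from the tempered full conditional
#' given that type, and accepts with the exact ratio in which the marginal
#' over sequences factorizes per column (computed exactly, never sampled).
#'
#' @inheritParams build_SN
#' @param temperature chain temperature.
#' @param sample_move if FALSE, only the proposal and the log ratio are
#'   computed (for diagnostics) and the state is returned unchanged.
#' @return list with \code{state}, \code{type_star}, \code{S_star},
#'   \code{log_r}, \code{accepted}.
#' @export
mh_uncovered_proposal <- function(state, model, k, temperature = 1,
                                  sample_move = TRUE) {
  if (!k %in% 1:2) stop("the uncovered-position proposal targets the two ",
                        "sample components")
  res <- cpp_mh_uncovered(.model_pack(model), state, k, temperature,
                          sample_move)
  res$state <- hla_state(res$state$R, res$state$S, res$state$I)
  res
}

#' Metropolis-Hastings swap of a sample component with a decoy
#'
#' Uniformly picks one sample and one decoy component, swaps their (type,
#' sequence) pairs, redraws all read indicators from the conditional under
#' the swapped sequences, and accepts with the exact marginalized ratio
#' (the indicator sum factorizes per read).
#'
#' @inheritParams mh_uncovered_proposal
#' @return list with \code{state}, \code{k1}, \code{k2}, \code{log_r},
#'   \code{accepted}.
#' @export
mh_decoy_swap <- function(state, model, temperature = 1, sample_move = TRUE) {
  if (model$K <= 2L) stop("decoy swap requires at least one decoy component")
  res <- cpp_mh_decoy_swap(.model_pack(model), state, temperature,
                           sample_move)
  res$state <- hla_state(res$state$R, res$state$S, res$state$I)
  res
}

#' Run the MCMC sampler and summarize the posterior
#'
#' Multi-start exploratory chains seed a parallel-tempering ensemble; each
#' sweep Gibbs-updates sequences, types and indicators in every chain, the
#' two Metropolis-Hastings proposals fire every \code{mh_period} sweeps,
#' reference sequences are copied over the sampled sequences periodically
#' during burn-in, and adjacent chains exchange states by standard
#' replica-swap moves.  Only cold-chain, post-burn-in, thinned states are
#' counted.
#'
#' @param model an \code{\link{hla_model}} with at least one read.
#' @param cfg a \code{\link{sampler_config}}.
#' @return an object of class \code{posterior_summary}: genotype counts
#'   (unordered type pairs), per-column symbol counts for the two sample
#'   sequences, per-read component assignment counts, the cold-chain log
#'   posterior trace, acceptance statistics and the seed.
#' @export
run_mcmc <- function(model, cfg = sampler_config()) {
  stopifnot(inherits(model, "hla_model"))
  if (nrow(model$reads$sym) == 0L)
    stop("no reads to analyse: all candidates were filtered out ",
         "(inspect the filter log)")
  set.seed(cfg$seed)
  pack <- .model_pack(model)
  nT <- length(cfg$temperatures)

  # multi-start: short single-chain runs; best final states seed the ladder
  starts <- lapply(seq_len(max(cfg$multi_start, 1L)), function(j) {
    st <- .random_state(model)
    if (cfg$multi_start_len > 0L) {
      r <- cpp_run_mcmc(pack, list(st), 1.0, cfg$multi_start_len, 0L, 1L,
                        cfg$mh_period, cfg$copy_period)
      st <- r$final_states[[1L]]
      st <- hla_state(st$R, st$S, st$I)
    }
    st
  })
  lps <- vapply(starts, function(st) cpp_log_posterior(pack, st), numeric(1))
  ord <- order(-lps)
  inits <- lapply(seq_len(nT), function(c) starts[[ord[(c - 1L) %%
                                                         length(ord) + 1L]]])
  res <- cpp_run_mcmc(pack, inits, cfg$temperatures, cfg$n_burnin,
                      cfg$n_samples, cfg$thin, cfg$mh_period,
                      cfg$copy_period)

  types <- rownames(model$msa$alleles)
  geno <- res$genotypes
  pair_key <- paste(types[geno[, 1]], types[geno[, 2]], sep = "/")
  counts <- sort(table(pair_key), decreasing = TRUE)
  structure(list(
    gene = model$msa$gene,
    genotype_counts = counts,
    n_samples = res$n_kept,
    seq_counts = list(res$seq_counts1, res$seq_counts2),
    I_counts = res$I_counts,
    read_ids = model$reads$ids,
    trace = res$trace,
    accept = res$accept,
    types = types,
    n_col = model$n_col,
    feature_map = model$msa$feature_map,
    seed = cfg$seed,
    config = cfg), class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("Posterior summary for HLA-", x$gene, ": ", x$n_samples,
      " kept samples\n", sep = "")
  top <- utils::head(call_genotype(x), 3)
  print(top)
  invisible(x)
}

#' Rank sampled genotypes by posterior fraction
#'
#' @param summary a \code{posterior_summary} from \code{\link{run_mcmc}}.
#' @return data.frame (rank, allele1, allele2, count, fraction), unordered
#'   pairs pooled, ties broken lexicographically.
#' @export
call_genotype <- function(summary) {
  stopifnot(summary$n_samples > 0)
  counts <- summary$genotype_counts
  keys <- names(counts)
  ord <- order(-as.integer(counts), keys)
  parts <- strsplit(keys[ord], "/", fixed = TRUE)
  data.frame(rank = seq_along(ord),
             allele1 = vapply(parts, `[`, character(1), 1L),
             allele2 = vapply(parts, `[`, character(1), 2L),
             count = as.integer(counts)[ord],
             fraction = as.integer(counts)[ord] / summary$n_samples)
}

#' Consensus HLA sequences with per-column support
#'
#' Per column the modal sampled symbol and its fraction; columns whose
#' modal fraction falls below \code{min_support} are reported as N.  Label
#' switching between the two sample components is resolved during sampling
#' by greedy matching against the running consensus.
#'
#' @param summary a \code{posterior_summary}.
#' @param min_support consensus support threshold (default 0.9).
#' @return list of two data.frames (column, symbol, support) plus the
#'   consensus strings in \code{attr(, "sequences")}.
#' @export
call_sequences <- function(summary, min_support = 0.9) {
  stopifnot(summary$n_samples > 0)
  out <- lapply(summary$seq_counts, function(cnt) {
    mode_idx <- max.col(cnt, ties.method = "first")
    supp <- cnt[cbind(seq_len(nrow(cnt)), mode_idx)] / summary$n_samples
    sym <- ifelse(supp < min_support, SYM_N, mode_idx)
    data.frame(column = seq_len(nrow(cnt)),
               symbol = HLA_SYMBOLS[sym], support = supp)
  })
  attr(out, "sequences") <- vapply(out, function(d)
    paste(d$symbol, collapse = ""), character(1))
  out
}
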