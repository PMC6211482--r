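#' Phred quality to mismatch probability
#'
#' @param q Phred quality score(s), non-negative.
#' @return \code{10^(-q/10)}, vectorized.
#' @export
#' @examples
#' mismatch_prob(c(0, 10, 30))
mismatch_prob <- function(q) {
  if (any(q < 0)) stop("Phred qualities must be non-negative")
  10^(-q / 10)
}

.check_symbols <- function(x, what) {
  if (!all(x %in% HLA_SYMBOLS))
    stop(what, " contains symbols outside {A,C,G,T,N,-}")
}

#' Likelihood of one read symbol given the underlying HLA sequence symbol
#'
#' Implements the piecewise per-base emission model.  With sequence symbol a
#' concrete base, the read reproduces it with probability
#' \code{(1-gamma_del)(1-gamma_N)(1-p_hat)}, substitutes it with
#' \code{(1-gamma_del)(1-gamma_N)p_hat/3}, reads N with
#' \code{(1-gamma_del)gamma_N} and drops it with \code{gamma_del}; a sequence
#' N emits any base uniformly; a sequence gap stays a gap with probability
#' \code{1-gamma_ins} and emits spurious bases at rate \code{gamma_ins}.
#' For every sequence symbol the emission distribution over the six read
#' symbols sums to one.
#'
#' @param read_symbol,seq_symbol character vectors over A,C,G,T,N,-.
#' @param p_hat per-base mismatch probability in [0,1] (from
#'   \code{\link{mismatch_prob}}).
#' @param hp an \code{\link{hla_hyperparams}} object.
#' @return numeric vector of probabilities.
#' @export
base_likelihood <- function(read_symbol, seq_symbol, p_hat, hp) {
  .check_symbols(read_symbol, "read_symbol")
  .check_symbols(seq_symbol, "seq_symbol")
  if (any(p_hat < 0 | p_hat > 1)) stop("p_hat must lie in [0, 1]")
  n <- max(length(read_symbol), length(seq_symbol), length(p_hat))
  r <- rep_len(read_symbol, n); s <- rep_len(seq_symbol, n)
  p <- rep_len(p_hat, n)
  gd <- hp$gamma_del; gi <- hp$gamma_ins; gN <- hp$gamma_N
  out <- numeric(n)
  base <- c("A", "C", "G", "T")
  sb <- s %in% base; sN <- s == "N"; sg <- s == "-"
  rb <- r %in% base; rN <- r == "N"; rg <- r == "-"
  out[sb & rb & r == s]  <- (1 - gd) * (1 - gN) * (1 - p[sb & rb & r == s])
  out[sb & rb & r != s]  <- (1 - gd) * (1 - gN) * p[sb & rb & r != s] / 3
  out[sb & rN]           <- (1 - gd) * gN
  out[sb & rg]           <- gd
  out[sN & rb]           <- (1 - gd) * (1 - gN) / 4
  out[sN & rN]           <- (1 - gd) * gN
  out[sN & rg]           <- gd
  out[sg & rb]           <- gi * (1 - gN) / 4
  out[sg & rN]           <- gi * gN
  out[sg & rg]           <- 1 - gi
  out
}

#' Prior of one sample-sequence symbol given the reference symbol of its type
#'
#' Mirrors \code{\link{base_likelihood}} with the germline-variant rates
#' \code{delta} in place of the error rates: a reference base is kept with
#' probability \code{(1-delta_del)(1-delta_N)(1-delta_sub)}, substituted at
#' rate \code{delta_sub} (split over the three alternatives), called N at
#' rate \code{delta_N} or deleted at rate \code{delta_del}; reference gaps
#' gain inserted bases at rate \code{delta_ins}.  At imputed reference
#' positions (\code{imputed = TRUE}) the larger \code{delta_*_imp} rates are
#' used.
#'
#' @param seq_symbol,ref_symbol character vectors over A,C,G,T,N,-.
#' @param imputed logical: was the reference base at this position imputed
#'   from another allele?
#' @param hp an \code{\link{hla_hyperparams}} object.
#' @return numeric vector of probabilities.
#' @export
seq_prior_base <- function(seq_symbol, ref_symbol, imputed, hp) {
  .check_symbols(seq_symbol, "seq_symbol")
  .check_symbols(ref_symbol, "ref_symbol")
  n <- max(length(seq_symbol), length(ref_symbol), length(imputed))
  s <- rep_len(seq_symbol, n); r <- rep_len(ref_symbol, n)
  im <- rep_len(as.logical(imputed), n)
  d <- function(name) ifelse(im, hp$delta_imp[[name]], hp$delta[[name]])
  ds <- d("sub"); dd <- d("del"); di <- d("ins"); dN <- d("N")
  out <- numeric(n)
  base <- c("A", "C", "G", "T")
  rb <- r %in% base; rN <- r == "N"; rg <- r == "-"
  sb <- s %in% base; sN <- s == "N"; sg <- s == "-"
  i <- rb & sb & s == r; out[i] <- (1 - dd[i]) * (1 - dN[i]) * (1 - ds[i])
  i <- rb & sb & s != r; out[i] <- (1 - dd[i]) * (1 - dN[i]) * ds[i] / 3
  i <- rb & sN;          out[i] <- (1 - dd[i]) * dN[i]
  i <- rb & sg;          out[i] <- dd[i]
  i <- rN & sb;          out[i] <- (1 - dd[i]) * (1 - dN[i]) / 4
  i <- rN & sN;          out[i] <- (1 - dd[i]) * dN[i]
  i <- rN & sg;          out[i] <- dd[i]
  i <- rg & sb;          out[i] <- di[i] * (1 - dN[i]) / 4
  i <- rg & sN;          out[i] <- di[i] * dN[i]
  i <- rg & sg;          out[i] <- 1 - di[i]
  out
}

#' Allele-frequency prior over the HLA types of one gene
#'
#' Population frequencies (when available) are smoothed as
#' \code{p ~ (freq + lambda) / (1 + lambda * n)} so unobserved alleles keep
#' positive prior mass; with no table the prior is uniform.  Decoy
#' components always use the constant prior \code{1/n}.
#'
#' @param type_names character vector of allele names in the reference
#'   panel.
#' @param freq optional named numeric vector of population frequencies
#'   (names matched to \code{type_names}; missing alleles get frequency 0).
#' @param lambda smoothing pseudo-frequency.
#' @return an object of class \code{freq_prior} with fields \code{p}
#'   (named, sums to 1) and \code{p_decoy}.
#' @export
freq_prior <- function(type_names, freq = NULL, lambda = 1e-3) {
  stopifnot(length(type_names) > 0, !anyDuplicated(type_names))
  n <- length(type_names)
  if (is.null(freq)) {
    p <- rep(1 / n, n)
  } else {
    f <- rep(0, n); names(f) <- type_names
    keep <- intersect(names(freq), type_names)
    f[keep] <- pmax(freq[keep], 0)
    if (sum(f) > 0) f <- f / sum(f)
    p <- (f + lambda) / (1 + lambda * n)
    p <- p / sum(p)
  }
  names(p) <- type_names
  structure(list(p = p, p_decoy = 1 / n), class = "freq_prior")
}

#' Prior probability of an HLA type
#'
#' @param type_name allele name (must be present in the prior).
#' @param is_decoy is the component a decoy?  Decoys use the constant prior.
#' @param fp a \code{\link{freq_prior}}.
#' @return scalar probability.
#' @export
type_prior <- function(type_name, is_decoy, fp) {
  if (!type_name %in% names(fp$p)) stop("unknown HLA type: ", type_name)
  if (is_decoy) fp$p_decoy else unname(fp$p[type_name])
}

#' Prior of the read-assignment indicator
#'
#' A read is assigned to one of the two sample components with prior weight
#' 1 and to each of \code{n_decoy} decoys with weight \code{epsilon};
#' weights are normalized over the \code{2 + n_decoy} components.
#'
#' @param i component index in \code{1:(n_nondecoy + n_decoy)}.
#' @param n_nondecoy number of sample components (2).
#' @param n_decoy number of decoy components.
#' @param epsilon decoy prior weight.
#' @return scalar probability.
#' @export
indicator_prior <- function(i, n_nondecoy = 2L, n_decoy = 0L, epsilon = 0.01) {
  K <- n_nondecoy + n_decoy
  if (i < 1 || i > K) stop("indicator index out of range")
  z <- n_nondecoy + n_decoy * epsilon
  if (i <= n_nondecoy) 1 / z else epsilon / z
}

# ---- numeric lookup tables shared with the C++ core --------------------

# log seq-prior table: dims [seq_symbol 1..6, ref_symbol 1..6, imputed+1]
seq_prior_log_table <- function(hp) {
  tab <- array(NA_real_, dim = c(6, 6, 2))
  for (im in 0:1)
    for (r in 1:6)
      tab[, r, im + 1] <- log(seq_prior_base(HLA_SYMBOLS, HLA_SYMBOLS[r],
                                             im == 1, hp))
  tab
}

# Per-read log-likelihood array, dims [read, column, seq_symbol 1..6];
# exact zeros at uncovered columns so they drop out of all sums.
build_loglik_array <- function(reads, hp) {
  sym <- reads$sym; phat <- reads$phat
  nr <- nrow(sym); nc <- ncol(sym)
  arr <- array(0, dim = c(nr, nc, 6))
  cov <- sym > 0L
  if (!any(cov)) return(arr)
  idx <- which(cov)
  rs <- sym[idx]; p <- phat[idx]
  for (s in 1:6) {
    v <- log(base_likelihood(HLA_SYMBOLS[rs], HLA_SYMBOLS[s], p, hp))
    slice <- matrix(0, nr, nc)
    slice[idx] <- v
    arr[, , s] <- slice
  }
  arr
}

#' Log-likelihood of one realigned read given a sample HLA sequence
#'
#' Sums the per-base log emission probabilities over the columns the read
#' covers; uncovered columns (including the gap between mates of a pair)
#' contribute nothing.
#'
#' @param read_sym integer vector of read symbol codes per MSA column (0 =
#'   not covered, 1..6 = A,C,G,T,N,-).
#' @param read_phat numeric vector of per-column mismatch probabilities.
#' @param seq integer vector of sequence symbol codes (1..6), same length.
#' @param hp an \code{\link{hla_hyperparams}} object.
#' @return scalar log-probability.
#' @export
read_loglik <- function(read_sym, read_phat, seq, hp) {
  stopifnot(length(read_sym) == length(seq))
  cov <- which(read_sym > 0L)
  if (length(cov) == 0L) return(0)
  sum(log(base_likelihood(HLA_SYMBOLS[read_sym[cov]],
                          HLA_SYMBOLS[seq[cov]],
                          read_phat[cov], hp)))
}

#' Bundle reference panel, realigned reads and priors into a model object
#'
#' Precomputes the integer reference matrix, imputation mask, per-read
#' log-likelihood array and log prior tables consumed by both the R
#' reference implementation of the posterior and the compiled sampler.
#'
#' @param msa an \code{\link{hla_msa}} reference panel.
#' @param reads an \code{hla_reads} object of realigned reads (see
#'   \code{\link{realign_accepted}}).
#' @param hp an \code{\link{hla_hyperparams}} object.
#' @param fp a \code{\link{freq_prior}}; uniform if omitted.
#' @return an object of class \code{hla_model}.
#' @export
build_model <- function(msa, reads, hp = hla_hyperparams(), fp = NULL) {
  stopifnot(inherits(msa, "hla_msa"))
  if (is.null(fp)) fp <- freq_prior(rownames(msa$alleles))
  stopifnot(identical(names(fp$p), rownames(msa$alleles)))
  K <- 2L + hp$n_decoy
  nc <- msa$n_col
  if (!is.null(reads) && ncol(reads$sym) != nc)
    stop("reads and MSA disagree on column count")
  if (is.null(reads))
    reads <- list(ids = character(0),
                  sym = matrix(integer(0), 0, nc),
                  phat = matrix(numeric(0), 0, nc))
  structure(list(
    msa = msa,
    reads = reads,
    hp = hp, fp = fp,
    K = K,
    n_types = nrow(msa$alleles),
    n_col = nc,
    refdb = msa$alleles,            # integer matrix n_types x n_col
    impdb = msa$imputed * 1L,       # integer mask, same dims
    logL = build_loglik_array(reads, hp),
    cov = (reads$sym > 0L) * 1L,
    log_freq = log(unname(fp$p)),
    log_decoy = log(fp$p_decoy),
    prior_tab = seq_prior_log_table(hp),
    log_ind = log(vapply(seq_len(K), indicator_prior,
                         numeric(1), n_nondecoy = 2L,
                         n_decoy = hp$n_decoy, epsilon = hp$epsilon))
  ), class = "hla_model")
}

#' Construct one MCMC state
#'
#' @param R integer vector of type indices, length \code{2 + n_decoy}; the
#'   first two components are the sample haplotypes, the rest decoys.
#' @param S integer matrix (components x columns) of sequence symbol codes.
#' @param I integer vector assigning each read to a component.
#' @return an object of class \code{hla_state}.
#' @export
hla_state <- function(R, S, I) {
  R <- as.integer(R); I <- as.integer(I)
  stopifnot(length(R) >= 2L, nrow(S) == length(R))
  if (length(I) && (min(I) < 1L || max(I) > length(R)))
    stop("indicator out of range")
  structure(list(R = R, S = S, I = I), class = "hla_state")
}

#' Unnormalized log posterior of a model state (reference implementation)
#'
#' Pure-R evaluation of the joint density: read log-likelihoods under the
#' assigned sequences, plus type priors, sequence priors given types, and
#' indicator priors.  Used as the oracle for the compiled sampler.
#'
#' @param state an \code{\link{hla_state}}.
#' @param model an \code{\link{hla_model}}.
#' @return scalar unnormalized log posterior.
#' @export
log_posterior <- function(state, model) {
  K <- length(state$R)
  stopifnot(K == model$K)
  hp <- model$hp
  lp <- 0
  for (k in seq_len(K)) {
    is_decoy <- k > 2L
    lp <- lp + if (is_decoy) model$log_decoy else model$log_freq[state$R[k]]
    ref <- model$refdb[state$R[k], ]
    imp <- model$impdb[state$R[k], ]
    lp <- lp + sum(model$prior_tab[cbind(state$S[k, ], ref, imp + 1L)])
  }
  nr <- nrow(model$reads$sym)
  for (i in seq_len(nr)) {
    k <- state$I[i]
    lp <- lp + model$log_ind[k] +
      read_loglik(model$reads$sym[i, ], model$reads$phat[i, ],
                  state$S[k, ], hp)
  }
  lp
}
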