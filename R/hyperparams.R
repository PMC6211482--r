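#' Scoring constants for the HLA-read (HR) score and read filtering
#'
#' The HR score of a read/allele alignment is a sum over alignment columns of
#' a quality-aware mismatch/gap/N penalty plus a constant per-base length
#' reward \code{beta}.  Reads are kept for genotyping when the best score
#' within the target gene clears an absolute threshold and exceeds the best
#' score in any other gene by a margin (separate thresholds for unpaired and
#' paired reads; paired thresholds apply to mate sums and should be the
#' looser pair).
#'
#' None of these constants are fixed by theory; the defaults are tuning
#' choices documented in the methods vignette and exposed here.
#'
#' @param alpha_del_open,alpha_del_ext penalties (< 0) for opening/extending
#'   a deletion in the read.
#' @param alpha_ins_open,alpha_ins_ext penalties (< 0) for opening/extending
#'   an insertion in the read.
#' @param alpha_N penalty (< 0) for an N opposite a concrete symbol.
#' @param beta positive per-base reward favouring longer alignments.
#' @param theta_u_m,theta_u_d absolute and margin thresholds for unpaired
#'   reads.
#' @param theta_p_m,theta_p_d thresholds for mate-pair sums; must not exceed
#'   their unpaired counterparts.
#' @return an object of class \code{score_params}.
#' @export
score_params <- function(alpha_del_open = -6, alpha_del_ext = -1,
                         alpha_ins_open = -6, alpha_ins_ext = -1,
                         alpha_N = -2, beta = 0.25,
                         theta_u_m = -20, theta_u_d = 2,
                         theta_p_m = -40, theta_p_d = 0) {
  alphas <- c(alpha_del_open, alpha_del_ext, alpha_ins_open, alpha_ins_ext,
              alpha_N)
  if (any(!is.finite(alphas)) || any(alphas >= 0))
    stop("all alpha penalties must be finite and negative")
  if (!is.finite(beta) || beta <= 0)
    stop("beta must be a positive finite reward")
  if (theta_p_m > theta_u_m || theta_p_d > theta_u_d)
    stop("paired thresholds must not exceed unpaired thresholds")
  structure(list(alpha_del_open = alpha_del_open,
                 alpha_del_ext = alpha_del_ext,
                 alpha_ins_open = alpha_ins_open,
                 alpha_ins_ext = alpha_ins_ext,
                 alpha_N = alpha_N, beta = beta,
                 theta_u_m = theta_u_m, theta_u_d = theta_u_d,
                 theta_p_m = theta_p_m, theta_p_d = theta_p_d),
            class = "score_params")
}

#' Hyperparameters of the Bayesian HLA model
#'
#' \code{gamma_*} are sequencing-error rates entering the read likelihood
#' (deletion error, insertion error, N).  \code{delta_*} are germline-variant
#' rates entering the sequence prior given an HLA type (substitution,
#' deletion, insertion, N); a second, larger set is used at reference
#' positions whose base was imputed from another allele, which shields the
#' model from misimputation.  \code{epsilon} is the prior odds that a read
#' originates from a decoy (non-target homologous) component rather than one
#' of the two sample haplotypes.
#'
#' @param gamma_del,gamma_ins,gamma_N read error probabilities in (0,1).
#' @param delta_sub,delta_del,delta_ins,delta_N germline variant
#'   probabilities at normally determined reference positions.
#' @param delta_sub_imp,delta_del_imp,delta_ins_imp,delta_N_imp the same
#'   rates at imputed reference positions (each must be >= its normal
#'   counterpart).
#' @param epsilon positive prior weight of each decoy component relative to
#'   the two sample components.
#' @param n_decoy number of decoy components (>= 0).
#' @return an object of class \code{hla_hyperparams}.
#' @export
hla_hyperparams <- function(gamma_del = 1e-3, gamma_ins = 1e-3,
                            gamma_N = 1e-4,
                            delta_sub = 5e-3, delta_del = 1e-3,
                            delta_ins = 1e-3, delta_N = 1e-4,
                            delta_sub_imp = 0.02, delta_del_imp = 0.005,
                            delta_ins_imp = 0.005, delta_N_imp = 2e-4,
                            epsilon = 0.01, n_decoy = 2L) {
  pr <- c(gamma_del, gamma_ins, gamma_N, delta_sub, delta_del, delta_ins,
          delta_N, delta_sub_imp, delta_del_imp, delta_ins_imp, delta_N_imp)
  if (any(pr <= 0) || any(pr >= 1))
    stop("all gamma/delta rates must lie strictly in (0, 1)")
  if (delta_sub_imp < delta_sub || delta_del_imp < delta_del ||
      delta_ins_imp < delta_ins || delta_N_imp < delta_N)
    stop("imputed-position delta rates must be >= their normal counterparts")
  if (!is.finite(epsilon) || epsilon < 0)
    stop("epsilon must be a non-negative real")
  n_decoy <- as.integer(n_decoy)
  if (n_decoy < 0L) stop("n_decoy must be >= 0")
  structure(list(gamma_del = gamma_del, gamma_ins = gamma_ins,
                 gamma_N = gamma_N,
                 delta = c(sub = delta_sub, del = delta_del,
                           ins = delta_ins, N = delta_N),
                 delta_imp = c(sub = delta_sub_imp, del = delta_del_imp,
                               ins = delta_ins_imp, N = delta_N_imp),
                 epsilon = epsilon, n_decoy = n_decoy),
            class = "hla_hyperparams")
}
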