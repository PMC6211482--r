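# model_core: emission likelihood, sequence prior, type and indicator
# priors, log posterior

test_that("base_likelihood matches the printed piecewise cases", {
  hp <- hla_hyperparams(gamma_del = 1e-3, gamma_ins = 2e-3, gamma_N = 1e-3)
  # hand evaluations of the three-case definition
  expect_equal(base_likelihood("A", "A", 0.01, hp),
               0.999 * 0.999 * 0.99, tolerance = 1e-12)
  expect_equal(base_likelihood("C", "A", 0.01, hp),
               0.999 * 0.999 * 0.01 / 3, tolerance = 1e-12)
  expect_equal(base_likelihood("N", "A", 0.5, hp), 0.999 * 0.001)
  expect_equal(base_likelihood("-", "A", 0.5, hp), 1e-3)
  expect_equal(base_likelihood("G", "N", 0.5, hp), 0.999 * 0.999 / 4)
  expect_equal(base_likelihood("G", "-", 0.5, hp), 0.002 * 0.999 / 4)
  expect_equal(base_likelihood("-", "-", 0.5, hp), 0.998)
  expect_error(base_likelihood("Z", "A", 0.5, hp), "outside")
})

test_that("seq_prior_base mirrors the likelihood with delta rates", {
  hp <- hla_hyperparams(delta_sub = 1e-3, delta_del = 1e-3,
                        delta_ins = 1e-3, delta_N = 1e-3,
                        delta_N_imp = 2e-3)
  expect_equal(seq_prior_base("A", "A", FALSE, hp),
               0.999 * 0.999 * 0.999, tolerance = 1e-12)
  hp2 <- hla_hyperparams(delta_sub = 3e-3)
  expect_equal(seq_prior_base("C", "A", FALSE, hp2),
               (1 - 1e-3) * (1 - 1e-4) * 1e-3, tolerance = 1e-12)
  expect_equal(seq_prior_base("-", "-", FALSE,
                              hla_hyperparams(delta_ins = 1e-3)), 0.999)
  # imputed positions switch to the larger delta set
  hp3 <- hla_hyperparams(delta_sub = 1e-3, delta_sub_imp = 0.03)
  expect_gt(seq_prior_base("C", "A", TRUE, hp3),
            seq_prior_base("C", "A", FALSE, hp3))
})

test_that("emission and prior distributions are normalized for random
           hyperparameters", {
  set.seed(11)
  for (rep in 1:50) {
    hp <- hla_hyperparams(
      gamma_del = runif(1, 1e-6, 0.4), gamma_ins = runif(1, 1e-6, 0.4),
      gamma_N = runif(1, 1e-6, 0.4),
      delta_sub = runif(1, 1e-6, 0.2), delta_del = runif(1, 1e-6, 0.2),
      delta_ins = runif(1, 1e-6, 0.2), delta_N = runif(1, 1e-6, 0.2),
      delta_sub_imp = 0.5, delta_del_imp = 0.5, delta_ins_imp = 0.5,
      delta_N_imp = 0.5)
    p_hat <- runif(1)
    for (s in SYMS) {
      expect_equal(sum(base_likelihood(SYMS, s, p_hat, hp)), 1,
                   tolerance = 1e-12)
      for (im in c(FALSE, TRUE))
        expect_equal(sum(seq_prior_base(SYMS, s, im, hp)), 1,
                     tolerance = 1e-12)
    }
  }
})

test_that("type_prior smooths frequencies and decoys stay constant", {
  fp <- freq_prior(c("t1", "t2"), freq = c(t1 = 0.9, t2 = 0.1),
                   lambda = 0)
  expect_equal(type_prior("t1", FALSE, fp), 0.9)
  expect_equal(type_prior("t1", TRUE, fp), 0.5)   # decoy = 1/n always
  fp20 <- freq_prior(sprintf("t%d", 1:20))
  expect_equal(unname(fp20$p), rep(0.05, 20))
  expect_error(type_prior("missing", FALSE, fp), "unknown")
  # smoothing keeps unobserved alleles positive
  fps <- freq_prior(c("a", "b", "c"), freq = c(a = 1), lambda = 1e-3)
  expect_true(all(fps$p > 0))
  expect_equal(sum(fps$p), 1)
})

test_that("indicator_prior is the normalized 1/epsilon split", {
  expect_equal(indicator_prior(1, 2, 2, 0.01), 1 / 2.02)
  expect_equal(indicator_prior(3, 2, 2, 0.01), 0.01 / 2.02)
  expect_equal(vapply(1:4, indicator_prior, numeric(1),
                      n_nondecoy = 2, n_decoy = 2, epsilon = 1),
               rep(0.25, 4))
  set.seed(2)
  for (nd in 0:3) {
    eps <- runif(1)
    expect_equal(sum(vapply(seq_len(2 + nd), indicator_prior, numeric(1),
                            n_nondecoy = 2, n_decoy = nd, epsilon = eps)),
                 1, tolerance = 1e-12)
  }
})

test_that("read_loglik sums covered columns only", {
  hp <- hla_hyperparams(gamma_del = 1e-3, gamma_N = 1e-3)
  n_col <- 12L
  reads <- tiny_reads(list(list(start = 2L, bases = "ACGTACGTAC",
                                quals = 20L)), n_col)
  seq1 <- enc("AACGTACGTACG")
  ll <- read_loglik(reads$sym[1, ], reads$phat[1, ], seq1, hp)
  expect_equal(ll, 10 * log(0.999 * 0.999 * 0.99), tolerance = 1e-10)
  # empty coverage: zero
  empty <- tiny_reads(list(list(start = 1L, bases = "A", quals = 20L)), 5L)
  expect_equal(read_loglik(rep(0L, 5), rep(0, 5), enc("ACGTA"), hp), 0)
  # a single N column
  rn <- tiny_reads(list(list(start = 1L, bases = "N", quals = 20L)), 1L)
  expect_equal(read_loglik(rn$sym[1, ], rn$phat[1, ], enc("A"), hp),
               log(0.999 * 0.001), tolerance = 1e-10)
})

test_that("per-read log-likelihood array agrees with base_likelihood", {
  model <- random_tiny_model(seed = 5)
  hp <- model$hp
  for (i in seq_len(nrow(model$reads$sym)))
    for (s in 1:6) {
      cov <- which(model$reads$sym[i, ] > 0L)
      expect_equal(
        model$logL[i, cov, s],
        log(base_likelihood(SYMS[model$reads$sym[i, cov]], SYMS[s],
                            model$reads$phat[i, cov], hp)),
        tolerance = 1e-12)
      expect_true(all(model$logL[i, -cov, s] == 0))
    }
})

test_that("log_posterior: closed form with no reads; monotone in agreement", {
  msa <- tiny_msa(list("A*01:01" = "ACGTA", "A*02:01" = "ACCTA"))
  hp <- hla_hyperparams(n_decoy = 0L)
  model <- build_model(msa, NULL, hp)
  st <- hla_state(c(1L, 2L), msa$alleles[1:2, ], integer(0))
  lp <- log_posterior(st, model)
  match_p <- seq_prior_base("A", "A", FALSE, hp)
  expect_equal(lp, 2 * log(1 / 2) + 10 * log(match_p), tolerance = 1e-10)
  # flipping one sequence base away from reference and reads lowers it
  model2 <- random_tiny_model(seed = 9)
  st2 <- hla_state(c(1L, 2L, 1L, 2L),
                   model2$refdb[c(1, 2, 1, 2), ],
                   rep(1L, nrow(model2$reads$sym)))
  lp2 <- log_posterior(st2, model2)
  covered <- which(model2$cov[1, ] == 1L)[1]
  stq <- st2
  cur <- stq$S[1, covered]
  alt <- setdiff(1:4, c(cur, model2$refdb[1, covered],
                        model2$reads$sym[1, covered]))[1]
  stq$S[1, covered] <- alt
  expect_lt(log_posterior(stq, model2), lp2)
})

test_that("log_posterior differences match a naive non-log density oracle", {
  model <- random_tiny_model(seed = 21, n_col = 4, n_reads = 3,
                             read_len = 3)
  naive_density <- function(state) {
    # direct product of probabilities, no logs
    d <- 1
    for (k in seq_len(model$K)) {
      d <- d * (if (k <= 2) exp(model$log_freq[state$R[k]]) else
        exp(model$log_decoy))
      ref <- model$refdb[state$R[k], ]; imp <- model$impdb[state$R[k], ]
      d <- d * prod(seq_prior_base(SYMS[state$S[k, ]], SYMS[ref],
                                   imp == 1L, model$hp))
    }
    for (i in seq_len(nrow(model$reads$sym))) {
      k <- state$I[i]
      d <- d * exp(model$log_ind[k])
      cov <- which(model$reads$sym[i, ] > 0L)
      d <- d * prod(base_likelihood(SYMS[model$reads$sym[i, cov]],
                                    SYMS[state$S[k, cov]],
                                    model$reads$phat[i, cov], model$hp))
    }
    d
  }
  s1 <- random_state_for(model, 1)
  s2 <- random_state_for(model, 2)
  expect_equal(log_posterior(s1, model) - log_posterior(s2, model),
               log(naive_density(s1) / naive_density(s2)),
               tolerance = 1e-9)
  # and the compiled evaluation agrees with the R reference
  pack <- BayesHLA:::.model_pack(model)
  expect_equal(BayesHLA:::cpp_log_posterior(pack, s1),
               log_posterior(s1, model), tolerance = 1e-9)
})
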