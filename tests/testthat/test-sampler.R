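# sampler: full conditionals, masked-sequence proposals, decoy swaps,
# summaries

test_that("Gibbs full conditionals equal renormalized log_posterior
           restrictions", {
  model <- random_tiny_model(seed = 31)
  pack <- BayesHLA:::.model_pack(model)
  st <- random_state_for(model, 1)
  # S conditional at a covered column
  for (k in 1:model$K) for (n in c(1L, 3L)) {
    w <- BayesHLA:::cpp_cond_S(pack, st, k, n)
    lp <- vapply(1:6, function(s) {
      st2 <- st; st2$S[k, n] <- s
      log_posterior(st2, model)
    }, numeric(1))
    expect_equal(w - w[1], lp - lp[1], tolerance = 1e-9)
  }
  # R conditional
  for (k in 1:model$K) {
    w <- BayesHLA:::cpp_cond_R(pack, st, k)
    lp <- vapply(seq_len(model$n_types), function(t) {
      st2 <- st; st2$R[k] <- t
      log_posterior(st2, model)
    }, numeric(1))
    expect_equal(w - w[1], lp - lp[1], tolerance = 1e-9)
  }
  # I conditional
  for (i in seq_len(nrow(model$reads$sym))) {
    w <- BayesHLA:::cpp_cond_I(pack, st, i)
    lp <- vapply(seq_len(model$K), function(k) {
      st2 <- st; st2$I[i] <- k
      log_posterior(st2, model)
    }, numeric(1))
    expect_equal(w - w[1], lp - lp[1], tolerance = 1e-9)
  }
})

test_that("gibbs_update examples behave as the conditionals dictate", {
  # 20 agreeing high-quality reads pin the sequence symbol
  msa <- tiny_msa(list("A*01:01" = "ACGTA", "A*02:01" = "ACCTA"))
  reads <- tiny_reads(rep(list(list(start = 1L, bases = "ACGTA",
                                    quals = 30L)), 20), 5L)
  model <- build_model(msa, reads, hla_hyperparams(n_decoy = 0L))
  pack <- BayesHLA:::.model_pack(model)
  st <- hla_state(c(1L, 2L), msa$alleles[1:2, ], rep(1L, 20))
  w <- BayesHLA:::cpp_cond_S(pack, st, 1L, 3L)
  p <- exp(w - max(w)); p <- p / sum(p)
  expect_gt(p[3], 0.999)              # G overwhelmingly
  # no covering reads: conditional equals the prior alone
  w2 <- BayesHLA:::cpp_cond_S(pack, hla_state(c(1L, 2L),
                                              msa$alleles[1:2, ],
                                              rep(2L, 20)), 1L, 3L)
  expect_equal(w2 - max(w2),
               log(seq_prior_base(SYMS, "G", FALSE, model$hp)) -
                 max(log(seq_prior_base(SYMS, "G", FALSE, model$hp))),
               tolerance = 1e-9)
  # temperature -> infinity flattens the sampled conditional
  set.seed(1)
  draws <- replicate(300, {
    stx <- gibbs_update_S(st, model, temperature = 1e9)
    stx$S[1, 3]
  })
  expect_gt(length(unique(draws)), 4)
  # R conditional: S identical to one allele picks it decisively
  stR <- hla_state(c(2L, 2L), msa$alleles[c(1, 1), ], rep(1L, 20))
  wr <- BayesHLA:::cpp_cond_R(pack, stR, 1L)
  pr <- exp(wr - max(wr)); pr <- pr / sum(pr)
  expect_gt(pr[1], 0.99)
  # read matching S_1 and not S_2 is assigned k = 1
  wi <- BayesHLA:::cpp_cond_I(pack, st, 1L)
  pi <- exp(wi - max(wi)); pi <- pi / sum(pi)
  expect_gt(pi[1], 0.6)               # S_1 == S_2 here except read noise
})

test_that("build_SN masks exactly the uncovered columns", {
  msa <- tiny_msa(list("A*01:01" = "ACGTA", "A*02:01" = "ACCTA"))
  reads <- tiny_reads(list(list(start = 1L, bases = "ACG", quals = 30L)),
                      5L)
  model <- build_model(msa, reads, hla_hyperparams(n_decoy = 0L))
  st <- hla_state(c(1L, 2L), msa$alleles[1:2, ], 1L)
  expect_equal(build_SN(st, model, 1L), c(enc("ACG"), 5L, 5L))
  expect_equal(build_SN(st, model, 2L), rep(5L, 5))   # no reads assigned
  full <- tiny_reads(list(list(start = 1L, bases = "ACGTA", quals = 30L)),
                     5L)
  model2 <- build_model(msa, full, hla_hyperparams(n_decoy = 0L))
  expect_equal(build_SN(hla_state(c(1L, 2L), msa$alleles[1:2, ], 1L),
                        model2, 1L),
               unname(msa$alleles[1, ]))
})

test_that("masked-sequence MH ratio matches the brute-force oracle", {
  for (seed in c(3, 4)) {
    model <- random_tiny_model(seed = seed, n_col = 4, n_reads = 3,
                               read_len = 3)
    pack <- BayesHLA:::.model_pack(model)
    st <- random_state_for(model, seed + 100)
    for (k in 1:2) {
      set.seed(seed)
      res <- mh_uncovered_proposal(st, model, k, sample_move = FALSE)
      oracle <- brute_mh_unc_ratio(model, st, k, res$type_star, res$S_star)
      expect_equal(res$log_r, oracle, tolerance = 1e-9)
    }
  }
  # identity proposal accepts for sure: single-type panel
  msa1 <- tiny_msa(list("A*01:01" = "ACGT"))
  reads <- tiny_reads(list(list(start = 1L, bases = "ACGT", quals = 30L)),
                      4L)
  m1 <- build_model(msa1, reads, hla_hyperparams(n_decoy = 1L))
  st1 <- hla_state(c(1L, 1L, 1L), m1$refdb[c(1, 1, 1), ], 1L)
  set.seed(5)
  r1 <- mh_uncovered_proposal(st1, m1, 1L, sample_move = FALSE)
  # proposed sequence may still differ at uncovered columns, but with one
  # type the type-jump terms cancel; with full coverage r* is exactly 1
  expect_equal(r1$type_star, 1L)
  expect_equal(r1$log_r, 0, tolerance = 1e-9)
})

test_that("two types differing only at an uncovered column exchange freely", {
  msa <- tiny_msa(list("A*01:01" = "ACGTA", "A*02:01" = "ACGTC"))
  reads <- tiny_reads(list(list(start = 1L, bases = "ACGT", quals = 30L)),
                      5L)                      # column 5 uncovered
  model <- build_model(msa, reads, hla_hyperparams(n_decoy = 0L))
  st <- hla_state(c(1L, 2L), msa$alleles[1:2, ], 1L)
  accept <- logical(200)
  jumps <- 0L
  set.seed(8)
  for (r in 1:200) {
    res <- mh_uncovered_proposal(st, model, 1L)
    accept[r] <- res$accepted
    if (res$state$R[1] != st$R[1]) jumps <- jumps + 1L
    st <- res$state
  }
  expect_gt(mean(accept), 0.95)       # ratios ~1 by the cancellation
  expect_gt(jumps, 20L)               # both types actually visited
})

test_that("decoy-swap MH ratio matches the brute-force oracle", {
  for (seed in c(6, 7)) {
    model <- random_tiny_model(seed = seed, n_col = 4, n_reads = 3,
                               read_len = 3)
    pack <- BayesHLA:::.model_pack(model)
    st <- random_state_for(model, seed + 200)
    set.seed(seed)
    res <- mh_decoy_swap(st, model, sample_move = FALSE)
    oracle <- brute_mh_swap_ratio(model, st, res$k1, res$k2)
    expect_equal(res$log_r, oracle, tolerance = 1e-9)
  }
  # swapping identical components gives r* = 1
  msa <- tiny_msa(list("A*01:01" = "ACGT"))
  reads <- tiny_reads(list(list(start = 1L, bases = "ACGT", quals = 30L)),
                      4L)
  m1 <- build_model(msa, reads, hla_hyperparams(n_decoy = 1L))
  st1 <- hla_state(c(1L, 1L, 1L), m1$refdb[c(1, 1, 1), ], 1L)
  set.seed(9)
  r1 <- mh_decoy_swap(st1, m1, sample_move = FALSE)
  expect_equal(r1$log_r, 0, tolerance = 1e-9)
  # swapping away a well-fitting component is strongly disfavoured
  msa2 <- tiny_msa(list("A*01:01" = "ACGTACGT", "A*02:01" = "TGCATGCA"))
  reads2 <- tiny_reads(rep(list(list(start = 1L, bases = "ACGTACGT",
                                     quals = 30L)), 4), 8L)
  m2 <- build_model(msa2, reads2, hla_hyperparams(n_decoy = 1L))
  st2 <- hla_state(c(1L, 2L, 2L), m2$refdb[c(1, 2, 2), ], rep(1L, 4))
  worst <- Inf
  set.seed(10)
  for (r in 1:10) {
    res <- mh_decoy_swap(st2, m2, sample_move = FALSE)
    worst <- min(worst, res$log_r)
  }
  expect_lt(worst, -10)
})

test_that("run_mcmc is deterministic under a fixed seed and errors on zero
           reads", {
  model <- random_tiny_model(seed = 41)
  cfg <- sampler_config(n_burnin = 50, n_samples = 100, multi_start = 2,
                        multi_start_len = 20, copy_period = 20,
                        temperatures = c(1, 1.1), seed = 99)
  s1 <- run_mcmc(model, cfg)
  s2 <- run_mcmc(model, cfg)
  expect_identical(s1$genotype_counts, s2$genotype_counts)
  expect_identical(s1$trace, s2$trace)
  expect_identical(s1$seq_counts, s2$seq_counts)
  expect_equal(s1$seed, 99L)
  empty <- build_model(model$msa, NULL, model$hp)
  expect_error(run_mcmc(empty, cfg), "filter log")
})

test_that("call_genotype pools unordered pairs and ranks by count", {
  summ <- structure(list(
    genotype_counts = table(c(rep("a/b", 800), rep("a/c", 200))),
    n_samples = 1000L), class = "posterior_summary")
  g <- call_genotype(summ)
  expect_equal(g$allele1[1], "a"); expect_equal(g$allele2[1], "b")
  expect_equal(g$fraction, c(0.8, 0.2))
  # ordered samples pool: the sampler emits sorted pairs by construction
  model <- random_tiny_model(seed = 43)
  cfg <- sampler_config(n_burnin = 30, n_samples = 60, multi_start = 1,
                        multi_start_len = 10, copy_period = 10,
                        temperatures = 1, seed = 3)
  s <- run_mcmc(model, cfg)
  g2 <- call_genotype(s)
  expect_true(all(g2$allele1 <= g2$allele2))
  expect_equal(sum(g2$count), s$n_samples)
})

test_that("call_sequences reports modal symbols and masks weak columns", {
  cnt1 <- matrix(0L, 3, 6); cnt2 <- matrix(0L, 3, 6)
  cnt1[1, 1] <- 100L                       # all A
  cnt1[2, 2] <- 50L; cnt1[2, 3] <- 50L     # 50/50 split -> N
  cnt1[3, 4] <- 95L; cnt1[3, 1] <- 5L
  cnt2[, 1] <- 100L
  summ <- structure(list(seq_counts = list(cnt1, cnt2), n_samples = 100L),
                    class = "posterior_summary")
  cons <- call_sequences(summ, min_support = 0.9)
  expect_equal(cons[[1]]$symbol, c("A", "N", "T"))
  expect_equal(cons[[1]]$support, c(1, 0.5, 0.95))
  expect_equal(attr(cons, "sequences")[2], "AAA")
})
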