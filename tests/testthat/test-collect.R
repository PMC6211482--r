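# read_collection: HR scoring, filtering, realignment

test_that("mismatch_prob is the Phred transform", {
  expect_equal(mismatch_prob(c(0, 10, 30)), c(1, 0.1, 0.001))
  expect_error(mismatch_prob(-1), "non-negative")
})

test_that("hr_score evaluates the column formula", {
  sp <- score_params(beta = 0.25)
  # perfect match, length 100: only beta terms
  s100 <- strrep("A", 100)
  expect_equal(hr_score(s100, s100, rep(30L, 100), sp), 25.0)
  # one mismatch at q=20 dominates when beta is negligible
  spb <- score_params(beta = 1e-9)
  r <- "AAAAAAAAAA"; t <- "AAAAACAAAA"
  expect_equal(hr_score(r, t, rep(20L, 10), spb), log(0.01 / 3),
               tolerance = 1e-6)
  # gap open/extend classification by previous read/type column
  sp2 <- score_params(alpha_del_open = -5, alpha_del_ext = -1, beta = 1e-9)
  expect_equal(hr_score("A--A", "ACGA", c(30L, 30L), sp2), -6,
               tolerance = 1e-6)
  sp3 <- score_params(alpha_ins_open = -5, alpha_ins_ext = -2, beta = 1e-9)
  expect_equal(hr_score("ACGA", "A--A", rep(30L, 4), sp3), -7,
               tolerance = 1e-6)
  # N opposite a concrete symbol
  spN <- score_params(alpha_N = -2, beta = 1e-9)
  expect_equal(hr_score("AN", "AC", c(30L, 30L), spN), -2,
               tolerance = 1e-6)
})

test_that("hr_score is monotone non-increasing in mismatches", {
  sp <- score_params()
  t <- "ACGTACGTACGTACGT"
  q <- rep(25L, 16)
  scores <- vapply(0:4, function(k) {
    r <- strsplit(t, "")[[1]]
    if (k > 0) r[seq_len(k)] <- c("C", "A", "T", "G")[seq_len(k)]
    hr_score(paste(r, collapse = ""), t, q, sp)
  }, numeric(1))
  expect_true(all(diff(scores) < 0))
})

test_that("the compiled aligner reproduces hr_score and an R DP oracle", {
  sp <- score_params()
  set.seed(8)
  for (rep in 1:10) {
    allele <- paste(sample(SYMS[1:4], 40, replace = TRUE), collapse = "")
    start <- sample(20, 1)
    frag <- strsplit(substr(allele, start, start + 11), "")[[1]]
    mut <- sample(12, 2)
    frag[mut] <- sample(SYMS[1:4], 2, replace = TRUE)
    read <- paste(frag, collapse = "")
    quals <- sample(15:35, 12, replace = TRUE)
    cpp <- BayesHLA:::cpp_align_read(enc(read), mismatch_prob(quals),
                                     enc(allele),
                                     sp$alpha_del_open, sp$alpha_del_ext,
                                     sp$alpha_ins_open, sp$alpha_ins_ext,
                                     sp$alpha_N, sp$beta)
    # DP score equals the independent R matrix DP
    expect_equal(cpp$score, r_semiglobal_score(read, quals, allele, sp),
                 tolerance = 1e-9)
    # and re-scoring the returned alignment with hr_score agrees
    rsym <- ifelse(cpp$read_idx > 0,
                   strsplit(read, "")[[1]][pmax(cpp$read_idx, 1)], "-")
    tsym <- ifelse(cpp$allele_idx > 0,
                   strsplit(allele, "")[[1]][pmax(cpp$allele_idx, 1)], "-")
    expect_equal(hr_score(paste(rsym, collapse = ""),
                          paste(tsym, collapse = ""),
                          quals[cpp$read_idx[cpp$read_idx > 0]], sp),
                 cpp$score, tolerance = 1e-9)
    # batch scorer agrees with single-alignment scorer
    batch <- BayesHLA:::cpp_score_db(enc(read), mismatch_prob(quals),
                                     list(enc(allele)),
                                     sp$alpha_del_open, sp$alpha_del_ext,
                                     sp$alpha_ins_open, sp$alpha_ins_ext,
                                     sp$alpha_N, sp$beta)
    expect_equal(batch[1], cpp$score, tolerance = 1e-9)
  }
})

test_that("score_read_against_db finds the source type", {
  msa <- tiny_msa(list("A*01:01" = "ACGTACGTACGTACGTACGT",
                       "A*02:01" = "ACGTACGTCCGTACGTACGT",
                       "A*03:01" = "TCGTACGTACGTACGAACGT"))
  sp <- score_params(beta = 0.25)
  rd <- raw_read("r1", "ACGTACGTACGT", rep(30L, 12))
  tab <- score_read_against_db(rd, list(A = msa), "A", sp)
  expect_equal(tab$best_type, "A*01:01")
  expect_equal(tab$s_star, 0.25 * 12, tolerance = 1e-9)
  expect_equal(tab$s_bar_star, -Inf)
  expect_error(score_read_against_db(rd, list(), "A"), "empty")
  # all-N read is dominated by alpha_N / gap terms and must be filtered out
  msaL <- tiny_msa(list("A*01:01" = paste(
    rep(c("ACGTT", "GATCC", "TTAGC", "CCGAA"), 10), collapse = "")))
  spd <- score_params()
  rn <- raw_read("rn", strrep("N", 100), rep(30L, 100))
  tn <- score_read_against_db(rn, list(A = msaL), "A", spd)
  expect_lt(tn$s_star, spd$theta_u_m)
  expect_false(filter_reads(list(tn), spd)[1])
})

test_that("a diverged paralog out-scores the target gene on its own reads", {
  scfg <- sim_config(n_alleles = 6, length = 400, n_homolog = 3,
                     homolog_divergence = 0.05, seed = 14)
  db <- generate_mock_db(scfg)
  panel <- mock_db_msa(db)
  set.seed(15)
  # reads copied verbatim from a homolog allele
  hseq <- db$truth$homolog_sequences[[1]]
  wins <- 0L
  for (rep in 1:10) {
    start <- sample(300, 1)
    rd <- raw_read("h", substr(hseq, start, start + 79), rep(30L, 80))
    tab <- score_read_against_db(rd, panel, "A")
    # brute-force check of the maxima over the stored score vectors
    expect_equal(tab$s_star, max(tab$scores$A))
    expect_equal(tab$s_bar_star, max(tab$scores$B))
    if (tab$s_bar_star > tab$s_star) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("filter_reads applies the strict threshold pairs", {
  mk <- function(s, sb) structure(list(s_star = s, s_bar_star = sb,
                                       id = "x", target_gene = "A",
                                       scores = list()),
                                  class = "hr_table")
  mkp <- function(s1, sb1, s2, sb2)
    structure(list(mate1 = mk(s1, sb1), mate2 = mk(s2, sb2), id = "p"),
              class = "hr_pair")
  sp <- score_params(theta_u_m = -100, theta_u_d = 20,
                     theta_p_m = -100, theta_p_d = 10)
  expect_true(filter_reads(list(mk(-50, -80)), sp)[1])
  sp2 <- score_params(theta_u_m = -100, theta_u_d = 0,
                      theta_p_m = -100, theta_p_d = 0)
  expect_false(filter_reads(list(mk(-50, -40)), sp2)[1])
  # pair: sum passes the mass threshold but not the margin
  expect_false(filter_reads(list(mkp(-30, -32.5, -30, -32.5)), sp)[1])
  expect_true(filter_reads(list(mkp(-30, -50, -30, -50)), sp)[1])
  # -Inf never passes, even with -Inf thresholds
  sp_inf <- score_params(theta_u_m = -Inf, theta_u_d = -Inf,
                         theta_p_m = -Inf, theta_p_d = -Inf)
  expect_false(filter_reads(list(mk(-Inf, -Inf)), sp_inf)[1])
  # thresholds at -Inf accept every aligned read; +Inf accepts none
  expect_true(filter_reads(list(mk(-1e6, 1e6)), sp_inf)[1])
  sp_hi <- score_params(theta_u_m = Inf, theta_u_d = -Inf,
                        theta_p_m = Inf, theta_p_d = -Inf)
  expect_false(filter_reads(list(mk(1e6, -1e6)), sp_hi)[1])
})

test_that("s_star equals an exhaustive scorer on a small panel", {
  sp <- score_params()
  set.seed(19)
  seqs <- lapply(1:8, function(i)
    paste(sample(SYMS[1:4], 30, replace = TRUE), collapse = ""))
  names(seqs) <- sprintf("A*%02d:01", 1:8)
  msa <- tiny_msa(seqs)
  read <- substr(seqs[[3]], 5, 20)
  quals <- rep(28L, 16)
  tab <- score_read_against_db(raw_read("r", read, quals),
                               list(A = msa), "A", sp)
  oracle <- vapply(seqs, function(s)
    r_semiglobal_score(read, quals, s, sp), numeric(1))
  expect_equal(unname(tab$scores$A), unname(oracle), tolerance = 1e-9)
  expect_equal(tab$s_star, max(oracle), tolerance = 1e-9)
})

test_that("realign_accepted concatenates mates with an uncovered gap", {
  set.seed(77)
  seq <- paste(sample(SYMS[1:4], 120, replace = TRUE), collapse = "")
  msa <- tiny_msa(list("A*01:01" = seq))
  sp <- score_params()
  rd <- raw_read("p1", substr(seq, 1, 30), rep(30L, 30),
                 substr(seq, 61, 90), rep(30L, 30))
  tab <- score_read_pair(rd, list(A = msa), "A", sp)
  re <- realign_accepted(list(rd), list(tab), msa, TRUE, sp)
  expect_equal(length(re$ids), 1L)
  covered <- which(re$sym[1, ] > 0L)
  expect_equal(covered, c(1:30, 61:90))
  expect_equal(re$best_type[1], "A*01:01")
  # tie in best type resolves to the lexicographically smaller name
  msa2 <- tiny_msa(list("A*02:01" = seq, "A*01:01" = seq))
  tab2 <- score_read_pair(rd, list(A = msa2), "A", sp)
  expect_equal(BayesHLA:::.best_type(tab2), "A*01:01")
})
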