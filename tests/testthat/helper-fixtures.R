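# Shared fixtures and independent oracles.  Everything here is generated in
# code; no data files.

enc <- BayesHLA:::encode_seq
dec <- BayesHLA:::decode_seq
SYMS <- c("A", "C", "G", "T", "N", "-")

# small integrated MSA directly from aligned strings (already in one column
# space; imputation mask all-false unless given)
tiny_msa <- function(seqs, gene = "A", imputed = NULL,
                     feature_map = NULL) {
  alleles <- do.call(rbind, lapply(seqs, enc))
  rownames(alleles) <- names(seqs)
  if (is.null(imputed))
    imputed <- matrix(FALSE, nrow(alleles), ncol(alleles))
  rownames(imputed) <- names(seqs)
  structure(list(gene = gene, n_col = ncol(alleles), alleles = alleles,
                 imputed = imputed,
                 feature_map = if (is.null(feature_map))
                   rep("exon1", ncol(alleles)) else feature_map,
                 level = setNames(rep("genomic", nrow(alleles)),
                                  names(seqs)),
                 imputation_donor = NULL),
            class = "hla_msa")
}

# reads placed directly in MSA columns: list of list(start, bases, quals)
tiny_reads <- function(placed, n_col) {
  n <- length(placed)
  sym <- matrix(0L, n, n_col); phat <- matrix(0, n, n_col)
  for (i in seq_len(n)) {
    p <- placed[[i]]
    codes <- enc(p$bases)
    span <- p$start + seq_along(codes) - 1L
    sym[i, span] <- codes
    q <- rep_len(p$quals, length(codes))
    phat[i, span] <- ifelse(codes == 6L, 0, mismatch_prob(q))
  }
  structure(list(ids = sprintf("r%02d", seq_len(n)), sym = sym,
                 phat = phat, best_type = rep(NA_character_, n)),
            class = "hla_reads")
}

# random enumerable instance for posterior-exactness checks
random_tiny_model <- function(seed, n_alleles = 4, n_col = 6, n_reads = 4,
                              read_len = 4, n_decoy = 2,
                              hp = hla_hyperparams(n_decoy = n_decoy)) {
  set.seed(seed)
  base <- sample(SYMS[1:4], n_col, replace = TRUE)
  seqs <- lapply(seq_len(n_alleles), function(i) {
    s <- base
    flip <- runif(n_col) < 0.3
    s[flip] <- sample(SYMS[1:4], sum(flip), replace = TRUE)
    paste(s, collapse = "")
  })
  names(seqs) <- sprintf("A*%02d:01", seq_len(n_alleles))
  msa <- tiny_msa(seqs)
  src <- sample(n_alleles, n_reads, replace = TRUE)
  placed <- lapply(seq_len(n_reads), function(i) {
    start <- sample(n_col - read_len + 1L, 1L)
    tmpl <- strsplit(seqs[[src[i]]], "")[[1L]][start + seq_len(read_len) - 1L]
    err <- runif(read_len) < 0.1
    tmpl[err] <- sample(SYMS[1:4], sum(err), replace = TRUE)
    list(start = start, bases = paste(tmpl, collapse = ""), quals = 20L)
  })
  reads <- tiny_reads(placed, n_col)
  build_model(msa, reads, hp)
}

random_state_for <- function(model, seed) {
  set.seed(seed)
  K <- model$K
  R <- sample.int(model$n_types, K, replace = TRUE)
  S <- matrix(sample.int(6L, K * model$n_col, replace = TRUE,
                         prob = c(rep(0.2, 4), 0.1, 0.1)),
              K, model$n_col)
  I <- sample.int(K, nrow(model$reads$sym), replace = TRUE)
  hla_state(R, S, I)
}

# ---- oracles ----------------------------------------------------------

# exact genotype posterior over unordered non-decoy type pairs, by
# enumerating all (R, I) combinations and marginalizing every sequence
# column analytically
enum_genotype_posterior <- function(model) {
  K <- model$K; nt <- model$n_types; nr <- nrow(model$reads$sym)
  N <- model$n_col
  L <- exp(model$logL)                    # [read, col, sym] likelihoods
  prior <- exp(model$prior_tab)           # [sym, refsym, imp]
  # m[t, subset]: marginal likelihood of one component with type t given
  # the subset of reads assigned to it
  subsets <- 0:(2^nr - 1)
  m <- matrix(0, nt, length(subsets))
  for (t in seq_len(nt)) {
    ref <- model$refdb[t, ]; imp <- model$impdb[t, ] + 1L
    for (a in subsets) {
      ids <- which(bitwAnd(a, 2^(seq_len(nr) - 1L)) > 0L)
      tot <- 0
      for (n in seq_len(N)) {
        w <- prior[, ref[n], imp[n]]
        for (i in ids) if (model$cov[i, n] == 1L) w <- w * L[i, n, ]
        tot <- tot + log(sum(w))
      }
      m[t, a + 1L] <- tot
    }
  }
  lp_type <- cbind(matrix(model$log_freq, nt, 2),
                   matrix(model$log_decoy, nt, K - 2))
  Igrid <- as.matrix(expand.grid(rep(list(seq_len(K)), nr)))
  masks <- sapply(seq_len(K), function(k)
    as.vector((Igrid == k) %*% 2^(seq_len(nr) - 1L)))
  dim(masks) <- c(nrow(Igrid), K)
  lpI <- rowSums(matrix(model$log_ind[Igrid], nrow(Igrid)))
  Rgrid <- as.matrix(expand.grid(rep(list(seq_len(nt)), K)))
  post <- numeric(nrow(Rgrid))
  for (r in seq_len(nrow(Rgrid))) {
    lp <- sum(lp_type[cbind(Rgrid[r, ], seq_len(K))])
    v <- lpI
    for (k in seq_len(K)) v <- v + m[Rgrid[r, k], masks[, k] + 1L]
    mx <- max(v)
    post[r] <- lp + mx + log(sum(exp(v - mx)))
  }
  post <- exp(post - max(post)); post <- post / sum(post)
  key <- paste(pmin(Rgrid[, 1], Rgrid[, 2]), pmax(Rgrid[, 1], Rgrid[, 2]))
  tapply(post, key, sum)
}

# brute-force log of the uncovered-proposal MH ratio for a realized
# proposal (t_star, S_star); sequence marginals summed by full enumeration
# over every sequence of the component's columns
brute_mh_unc_ratio <- function(model, state, k, t_star, S_star) {
  N <- model$n_col; hp <- model$hp
  asgn <- which(state$I == k)
  covk <- rep(FALSE, N)
  for (i in asgn) covk <- covk | model$cov[i, ] == 1L
  SN <- ifelse(covk, state$S[k, ], 5L)
  SNs <- ifelse(covk, S_star, 5L)
  lp_seq <- function(seq, t) {
    sum(model$prior_tab[cbind(seq, model$refdb[t, ], model$impdb[t, ] + 1L)])
  }
  lik_reads <- function(seq) {
    tot <- 0
    for (i in asgn)
      tot <- tot + read_loglik(model$reads$sym[i, ], model$reads$phat[i, ],
                               seq, hp)
    tot
  }
  # sum over all 6^N sequences of p(S|t) p(X_k|S), by enumeration
  # (vectorized over the full sequence grid)
  grid <- as.matrix(expand.grid(rep(list(1:6), N)))
  nr_tot <- nrow(model$reads$sym)
  ZS <- function(t) {
    ref <- model$refdb[t, ]; imp <- model$impdb[t, ]
    v <- numeric(nrow(grid))
    for (n in seq_len(N)) {
      v <- v + model$prior_tab[grid[, n] + 6L * (ref[n] - 1L) +
                                 36L * imp[n]]
      for (i in asgn)
        if (model$cov[i, n] == 1L)
          v <- v + model$logL[i + nr_tot * ((n - 1L) +
                                              N * (grid[, n] - 1L))]
    }
    mx <- max(v)
    mx + log(sum(exp(v - mx)))
  }
  lpR <- function(t, kk) if (kk <= 2) model$log_freq[t] else model$log_decoy
  ZR <- function(SNseq) {
    v <- vapply(seq_len(model$n_types), function(t)
      lpR(t, k) + lp_seq(SNseq, t), numeric(1))
    mx <- max(v)
    mx + log(sum(exp(v - mx)))
  }
  t_cur <- state$R[k]
  ZS(t_star) - ZS(t_cur) + lp_seq(SNs, t_cur) - lp_seq(SN, t_star) +
    ZR(SN) - ZR(SNs)
}

# brute-force log of the decoy-swap MH ratio for realized slots (k1, k2);
# indicator marginal by full enumeration over all K^n_reads assignments
brute_mh_swap_ratio <- function(model, state, k1, k2) {
  K <- model$K; nr <- nrow(model$reads$sym); hp <- model$hp
  llik <- sapply(seq_len(K), function(k)
    vapply(seq_len(nr), function(i)
      read_loglik(model$reads$sym[i, ], model$reads$phat[i, ],
                  state$S[k, ], hp), numeric(1)))
  dim(llik) <- c(nr, K)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), nr)))
  ZI <- function(lmat) {
    v <- numeric(nrow(grid))
    for (i in seq_len(nr))
      v <- v + model$log_ind[grid[, i]] + lmat[i, ][grid[, i]]
    mx <- max(v)
    mx + log(sum(exp(v - mx)))
  }
  perm <- seq_len(K); perm[c(k1, k2)] <- c(k2, k1)
  model$log_freq[state$R[k2]] - model$log_freq[state$R[k1]] +
    ZI(llik[, perm, drop = FALSE]) - ZI(llik)
}

# independent semi-global affine-gap scorer (plain R matrix DP) used as the
# oracle for the compiled aligner on tiny panels
r_semiglobal_score <- function(read, quals, allele, params) {
  r <- enc(read); t <- enc(allele)
  L <- length(r); M <- length(t)
  p <- mismatch_prob(quals)
  colsc <- function(i, j) {
    if (r[i] == 5L || t[j] == 5L) params$alpha_N + params$beta
    else if (r[i] == t[j]) params$beta
    else log(p[i] / 3) + params$beta
  }
  NEG <- -Inf
  Mx <- matrix(NEG, L + 1, M + 1); Dx <- Mx; Ix <- Mx
  Mx[1, ] <- 0
  for (i in 1:L) for (j in 1:M) {
    Mx[i + 1, j + 1] <- colsc(i, j) +
      max(Mx[i, j], Dx[i, j], Ix[i, j])
    Dx[i + 1, j + 1] <- max(Mx[i + 1, j] + params$alpha_del_open,
                            Ix[i + 1, j] + params$alpha_del_open,
                            Dx[i + 1, j] + params$alpha_del_ext)
    # the first consumed read base must anchor on an allele base
    Ix[i + 1, j + 1] <- if (i == 1) NEG else params$beta +
      max(Mx[i, j + 1] + params$alpha_ins_open,
          Dx[i, j + 1] + params$alpha_ins_open,
          Ix[i, j + 1] + params$alpha_ins_ext)
  }
  max(Mx[L + 1, -1], Ix[L + 1, -1])
}
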