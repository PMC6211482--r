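#include <Rcpp.h>
using namespace Rcpp;

// Sampler core for the Bayesian HLA model.
//
// All exported entry points take a packed model list (built by
// build_model() on the R side) carrying:
//   logL      numeric array [n_reads, N, 6]  per-read per-column per-symbol
//             log emission, exactly 0 at uncovered columns
//   cov       integer matrix [n_reads, N]    1 where the read covers
//   refdb     integer matrix [n_types, N]    reference symbols 1..6
//   impdb     integer matrix [n_types, N]    1 at imputed positions
//   log_freq  numeric [n_types]              log type prior (sample slots)
//   log_decoy scalar                         log constant decoy type prior
//   prior_tab numeric array [6, 6, 2]        log p(seq sym | ref sym, imp)
//   log_ind   numeric [K]                    log indicator prior
// and a state (R: K type indices, S: K x N symbol matrix, I: n_reads
// component indices), all 1-based on the R side.

struct ModelC {
  int nr, N, nt, K;
  const double *logL;
  const int *cov, *refdb, *impdb;
  const double *log_freq;
  double log_decoy;
  const double *prior_tab;
  const double *log_ind;

  double ll(int i, int n, int s) const {          // s 0-based
    return logL[i + (size_t)nr * (n + (size_t)N * s)];
  }
  bool covered(int i, int n) const { return cov[i + (size_t)nr * n] != 0; }
  int ref(int t, int n) const { return refdb[t + (size_t)nt * n] - 1; }
  int imp(int t, int n) const { return impdb[t + (size_t)nt * n]; }
  double pr(int s, int r, int im) const {         // s, r 0-based
    return prior_tab[s + 6 * (r + 6 * im)];
  }
  double lpR(int t, int k) const { return k < 2 ? log_freq[t] : log_decoy; }
};

static ModelC unpack(const List &m) {
  ModelC md;
  NumericVector logL = m["logL"];
  IntegerVector dim = logL.attr("dim");
  md.nr = dim[0]; md.N = dim[1];
  IntegerMatrix refdb = m["refdb"];
  md.nt = refdb.nrow();
  md.K = as<int>(m["K"]);
  md.logL = REAL(logL);
  md.cov = INTEGER(as<IntegerMatrix>(m["cov"]));
  md.refdb = INTEGER(refdb);
  md.impdb = INTEGER(as<IntegerMatrix>(m["impdb"]));
  md.log_freq = REAL(as<NumericVector>(m["log_freq"]));
  md.log_decoy = as<double>(m["log_decoy"]);
  md.prior_tab = REAL(as<NumericVector>(m["prior_tab"]));
  md.log_ind = REAL(as<NumericVector>(m["log_ind"]));
  return md;
}

struct St {                    // working state, 0-based indices
  std::vector<int> R;          // K
  std::vector<int> S;          // K x N, column-major (k + K*n), symbols 0..5
  std::vector<int> I;          // nr
};

static St state_in(const List &s, const ModelC &m) {
  St st;
  IntegerVector R = s["R"], I = s["I"];
  IntegerMatrix S = s["S"];
  st.R.resize(m.K); st.I.resize(m.nr);
  st.S.resize((size_t)m.K * m.N);
  for (int k = 0; k < m.K; ++k) st.R[k] = R[k] - 1;
  for (int i = 0; i < m.nr; ++i) st.I[i] = I[i] - 1;
  for (int k = 0; k < m.K; ++k)
    for (int n = 0; n < m.N; ++n) st.S[k + (size_t)m.K * n] = S(k, n) - 1;
  return st;
}

static List state_out(const St &st, const ModelC &m) {
  IntegerVector R(m.K), I(m.nr);
  IntegerMatrix S(m.K, m.N);
  for (int k = 0; k < m.K; ++k) R[k] = st.R[k] + 1;
  for (int i = 0; i < m.nr; ++i) I[i] = st.I[i] + 1;
  for (int k = 0; k < m.K; ++k)
    for (int n = 0; n < m.N; ++n) S(k, n) = st.S[k + (size_t)m.K * n] + 1;
  return List::create(_["R"] = R, _["S"] = S, _["I"] = I);
}

static inline double lse(const double *w, int n) {
  double mx = w[0];
  for (int s = 1; s < n; ++s) if (w[s] > mx) mx = w[s];
  double z = 0;
  for (int s = 0; s < n; ++s) z += std::exp(w[s] - mx);
  return mx + std::log(z);
}

// sample index proportional to exp(beta * w)
static int sample_cat(const double *w, int n, double beta) {
  double buf[64];
  std::vector<double> heap;
  double *p = buf;
  if (n > 64) { heap.resize(n); p = heap.data(); }
  double mx = -1e300;
  for (int s = 0; s < n; ++s) { p[s] = beta * w[s]; if (p[s] > mx) mx = p[s]; }
  double tot = 0;
  for (int s = 0; s < n; ++s) { p[s] = std::exp(p[s] - mx); tot += p[s]; }
  double u = unif_rand() * tot, acc = 0;
  for (int s = 0; s < n; ++s) { acc += p[s]; if (u <= acc) return s; }
  return n - 1;
}

static double log_post(const ModelC &m, const St &st) {
  double lp = 0;
  for (int k = 0; k < m.K; ++k) {
    int t = st.R[k];
    lp += m.lpR(t, k);
    for (int n = 0; n < m.N; ++n)
      lp += m.pr(st.S[k + (size_t)m.K * n], m.ref(t, n), m.imp(t, n));
  }
  for (int i = 0; i < m.nr; ++i) {
    int k = st.I[i];
    lp += m.log_ind[k];
    for (int n = 0; n < m.N; ++n)
      if (m.covered(i, n)) lp += m.ll(i, n, st.S[k + (size_t)m.K * n]);
  }
  return lp;
}

static std::vector<int> assigned_reads(const St &st, int k, int nr) {
  std::vector<int> out;
  for (int i = 0; i < nr; ++i) if (st.I[i] == k) out.push_back(i);
  return out;
}

// A(n, s) = sum of log emissions at column n under symbol s over the reads
// assigned to component k (the per-column likelihood profile).
static void profile_A(const ModelC &m, const std::vector<int> &asgn,
                      std::vector<double> &A) {
  std::fill(A.begin(), A.end(), 0.0);
  for (int i : asgn)
    for (int n = 0; n < m.N; ++n)
      if (m.covered(i, n))
        for (int s = 0; s < 6; ++s)
          A[n + (size_t)m.N * s] += m.ll(i, n, s);
}

static void gibbs_S(const ModelC &m, St &st, int k, double beta,
                    std::vector<double> *ws = nullptr) {
  std::vector<int> asgn = assigned_reads(st, k, m.nr);
  std::vector<double> local;
  std::vector<double> &A = ws ? *ws : local;
  A.assign((size_t)m.N * 6, 0.0);
  profile_A(m, asgn, A);
  int t = st.R[k];
  double w[6];
  for (int n = 0; n < m.N; ++n) {
    int r = m.ref(t, n), im = m.imp(t, n);
    for (int s = 0; s < 6; ++s)
      w[s] = m.pr(s, r, im) + A[n + (size_t)m.N * s];
    st.S[k + (size_t)m.K * n] = sample_cat(w, 6, beta);
  }
}

static void gibbs_R(const ModelC &m, St &st, int k, double beta) {
  std::vector<double> w(m.nt);
  for (int t = 0; t < m.nt; ++t) {
    double v = m.lpR(t, k);
    for (int n = 0; n < m.N; ++n)
      v += m.pr(st.S[k + (size_t)m.K * n], m.ref(t, n), m.imp(t, n));
    w[t] = v;
  }
  st.R[k] = sample_cat(w.data(), m.nt, beta);
}

static void gibbs_I(const ModelC &m, St &st, double beta) {
  std::vector<double> w(m.K);
  for (int i = 0; i < m.nr; ++i) {
    for (int k = 0; k < m.K; ++k) {
      double v = m.log_ind[k];
      for (int n = 0; n < m.N; ++n)
        if (m.covered(i, n)) v += m.ll(i, n, st.S[k + (size_t)m.K * n]);
      w[k] = v;
    }
    st.I[i] = sample_cat(w.data(), m.K, beta);
  }
}

static void build_SN(const ModelC &m, const St &st, int k, std::vector<int> &SN) {
  std::vector<char> cov(m.N, 0);
  for (int i = 0; i < m.nr; ++i)
    if (st.I[i] == k)
      for (int n = 0; n < m.N; ++n) if (m.covered(i, n)) cov[n] = 1;
  SN.resize(m.N);
  for (int n = 0; n < m.N; ++n)
    SN[n] = cov[n] ? st.S[k + (size_t)m.K * n] : 4;   // 4 = N (0-based)
}

static double lp_seq_given_type(const ModelC &m, const std::vector<int> &seq,
                                int t) {
  double v = 0;
  for (int n = 0; n < m.N; ++n) v += m.pr(seq[n], m.ref(t, n), m.imp(t, n));
  return v;
}

// sum over n of log sum_s exp(beta * (prior(s | t, n) + A(n, s)))
static double logZS(const ModelC &m, const std::vector<double> &A, int t,
                    double beta) {
  double tot = 0, w[6];
  for (int n = 0; n < m.N; ++n) {
    int r = m.ref(t, n), im = m.imp(t, n);
    for (int s = 0; s < 6; ++s)
      w[s] = beta * (m.pr(s, r, im) + A[n + (size_t)m.N * s]);
    tot += lse(w, 6);
  }
  return tot;
}

// Metropolis-Hastings jump over types via the N-masked sequence: propose a
// type from p(R* | S^N), a sequence from its tempered full conditional, and
// accept with the exact ratio (which reduces to the textbook masked-sequence
// ratio whenever the proposed sequence equals the current one at covered
// columns).  Returns the log ratio and whether the move was applied.
static List mh_uncovered(const ModelC &m, St &st, int k, double beta,
                         bool sample_move) {
  std::vector<int> asgn = assigned_reads(st, k, m.nr);
  std::vector<double> A((size_t)m.N * 6);
  profile_A(m, asgn, A);
  std::vector<int> SN;
  build_SN(m, st, k, SN);

  int t_cur = st.R[k];
  std::vector<double> lw(m.nt);
  for (int t = 0; t < m.nt; ++t)
    lw[t] = beta * (m.lpR(t, k) + lp_seq_given_type(m, SN, t));
  double ZR_f = lse(lw.data(), m.nt);
  int t_star = sample_cat(lw.data(), m.nt, 1.0);  // lw already tempered

  std::vector<int> S_star(m.N);
  double w[6];
  for (int n = 0; n < m.N; ++n) {
    int r = m.ref(t_star, n), im = m.imp(t_star, n);
    for (int s = 0; s < 6; ++s)
      w[s] = m.pr(s, r, im) + A[n + (size_t)m.N * s];
    S_star[n] = sample_cat(w, 6, beta);
  }

  // reverse-move mask: S* at columns covered by this component's reads
  std::vector<int> SN_star(m.N);
  {
    std::vector<char> covk(m.N, 0);
    for (int i : asgn)
      for (int n = 0; n < m.N; ++n) if (m.covered(i, n)) covk[n] = 1;
    for (int n = 0; n < m.N; ++n) SN_star[n] = covk[n] ? S_star[n] : 4;
  }

  std::vector<double> lw2(m.nt);
  for (int t = 0; t < m.nt; ++t)
    lw2[t] = beta * (m.lpR(t, k) + lp_seq_given_type(m, SN_star, t));
  double ZR_r = lse(lw2.data(), m.nt);

  double log_r = logZS(m, A, t_star, beta) - logZS(m, A, t_cur, beta)
    + beta * (lp_seq_given_type(m, SN_star, t_cur)
              - lp_seq_given_type(m, SN, t_star))
    + ZR_f - ZR_r;

  bool accepted = false;
  if (sample_move) {
    if (std::log(unif_rand()) < log_r) {
      accepted = true;
      st.R[k] = t_star;
      for (int n = 0; n < m.N; ++n) st.S[k + (size_t)m.K * n] = S_star[n];
    }
  }
  IntegerVector Sst(m.N);
  for (int n = 0; n < m.N; ++n) Sst[n] = S_star[n] + 1;
  return List::create(_["type_star"] = t_star + 1, _["S_star"] = Sst,
                      _["log_r"] = log_r, _["accepted"] = accepted);
}

// Decoy-swap proposal: exchange (type, sequence) between one sample slot and
// one decoy slot, redraw all indicators from their conditional under the
// swapped sequences, and accept with the exact marginalized ratio
// p(R*) Z_I(S*) / (p(R) Z_I(S)) where Z_I factorizes per read.
static List mh_swap(const ModelC &m, St &st, double beta, bool sample_move) {
  if (m.K <= 2)
    return List::create(_["log_r"] = NA_REAL, _["accepted"] = false);
  int k1 = (int)std::floor(unif_rand() * 2.0); if (k1 > 1) k1 = 1;
  int nd = m.K - 2;
  int k2 = 2 + (int)std::floor(unif_rand() * nd); if (k2 >= m.K) k2 = m.K - 1;

  // per-read log-likelihood against every component, current and swapped
  double ZI_cur = 0, ZI_new = 0;
  std::vector<double> wcur(m.K), wnew(m.K);
  std::vector<int> I_star(m.nr);
  std::vector<double> llik((size_t)m.nr * m.K);
  for (int i = 0; i < m.nr; ++i) {
    for (int k = 0; k < m.K; ++k) {
      double v = 0;
      for (int n = 0; n < m.N; ++n)
        if (m.covered(i, n)) v += m.ll(i, n, st.S[k + (size_t)m.K * n]);
      llik[i + (size_t)m.nr * k] = v;
    }
    for (int k = 0; k < m.K; ++k) {
      int ks = (k == k1) ? k2 : (k == k2 ? k1 : k);   // swapped sequences
      wcur[k] = beta * (m.log_ind[k] + llik[i + (size_t)m.nr * k]);
      wnew[k] = beta * (m.log_ind[k] + llik[i + (size_t)m.nr * ks]);
    }
    ZI_cur += lse(wcur.data(), m.K);
    ZI_new += lse(wnew.data(), m.K);
    I_star[i] = sample_cat(wnew.data(), m.K, 1.0);
  }
  double log_r = beta * (m.log_freq[st.R[k2]] - m.log_freq[st.R[k1]])
    + ZI_new - ZI_cur;

  bool accepted = false;
  if (sample_move && std::log(unif_rand()) < log_r) {
    accepted = true;
    std::swap(st.R[k1], st.R[k2]);
    for (int n = 0; n < m.N; ++n)
      std::swap(st.S[k1 + (size_t)m.K * n], st.S[k2 + (size_t)m.K * n]);
    st.I = I_star;
  }
  return List::create(_["k1"] = k1 + 1, _["k2"] = k2 + 1,
                      _["log_r"] = log_r, _["accepted"] = accepted);
}

static void copy_reference(const ModelC &m, St &st) {
  for (int k = 0; k < m.K; ++k) {
    int t = st.R[k];
    for (int n = 0; n < m.N; ++n)
      st.S[k + (size_t)m.K * n] = m.ref(t, n);
  }
}

// ---- exported single-step wrappers (unit-test surface) -----------------

// [[Rcpp::export]]
double cpp_log_posterior(List model, List state) {
  ModelC m = unpack(model);
  St st = state_in(state, m);
  return log_post(m, st);
}

// [[Rcpp::export]]
NumericVector cpp_cond_S(List model, List state, int k, int n) {
  ModelC m = unpack(model);
  St st = state_in(state, m);
  std::vector<int> asgn = assigned_reads(st, k - 1, m.nr);
  NumericVector w(6);
  int t = st.R[k - 1];
  int r = m.ref(t, n - 1), im = m.imp(t, n - 1);
  for (int s = 0; s < 6; ++s) w[s] = m.pr(s, r, im);
  for (int i : asgn)
    if (m.covered(i, n - 1))
      for (int s = 0; s < 6; ++s) w[s] += m.ll(i, n - 1, s);
  return w;
}

// [[Rcpp::export]]
NumericVector cpp_cond_R(List model, List state, int k) {
  ModelC m = unpack(model);
  St st = state_in(state, m);
  NumericVector w(m.nt);
  for (int t = 0; t < m.nt; ++t) {
    double v = m.lpR(t, k - 1);
    for (int n = 0; n < m.N; ++n)
      v += m.pr(st.S[(k - 1) + (size_t)m.K * n], m.ref(t, n), m.imp(t, n));
    w[t] = v;
  }
  return w;
}

// [[Rcpp::export]]
NumericVector cpp_cond_I(List model, List state, int i) {
  ModelC m = unpack(model);
  St st = state_in(state, m);
  NumericVector w(m.K);
  for (int k = 0; k < m.K; ++k) {
    double v = m.log_ind[k];
    for (int n = 0; n < m.N; ++n)
      if (m.covered(i - 1, n)) v += m.ll(i - 1, n, st.S[k + (size_t)m.K * n]);
    w[k] = v;
  }
  return w;
}

// [[Rcpp::export]]
IntegerVector cpp_build_SN(List model, List state, int k) {
  ModelC m = unpack(model);
  St st = state_in(state, m);
  std::vector<int> SN;
  build_SN(m, st, k - 1, SN);
  IntegerVector out(m.N);
  for (int n = 0; n < m.N; ++n) out[n] = SN[n] + 1;
  return out;
}

// [[Rcpp::export]]
List cpp_gibbs_update(List model, List state, double temperature,
                      std::string which) {
  ModelC m = unpack(model);
  St st = state_in(state, m);
  double beta = 1.0 / temperature;
  if (which == "S" || which == "all")
    for (int k = 0; k < m.K; ++k) gibbs_S(m, st, k, beta);
  if (which == "R" || which == "all")
    for (int k = 0; k < m.K; ++k) gibbs_R(m, st, k, beta);
  if (which == "I" || which == "all") gibbs_I(m, st, beta);
  return state_out(st, m);
}

// [[Rcpp::export]]
List cpp_mh_uncovered(List model, List state, int k, double temperature,
                      bool sample_move) {
  ModelC m = unpack(model);
  St st = state_in(state, m);
  List res = mh_uncovered(m, st, k - 1, 1.0 / temperature, sample_move);
  res["state"] = state_out(st, m);
  return res;
}

// [[Rcpp::export]]
List cpp_mh_decoy_swap(List model, List state, double temperature,
                       bool sample_move) {
  ModelC m = unpack(model);
  St st = state_in(state, m);
  List res = mh_swap(m, st, 1.0 / temperature, sample_move);
  res["state"] = state_out(st, m);
  return res;
}

// ---- full run ----------------------------------------------------------

// [[Rcpp::export]]
List cpp_run_mcmc(List model, List inits, NumericVector temps,
                  int n_burnin, int n_samples, int thin,
                  int mh_period, int copy_period) {
  ModelC m = unpack(model);
  const int nT = temps.size();
  std::vector<St> chains(nT);
  for (int c = 0; c < nT; ++c)
    chains[c] = state_in(inits[c % inits.size()], m);
  std::vector<double> beta(nT);
  for (int c = 0; c < nT; ++c) beta[c] = 1.0 / temps[c];

  const int total = n_burnin + n_samples * thin;
  NumericVector trace(total);
  int n_kept = (thin > 0) ? n_samples : 0;
  IntegerMatrix geno(std::max(n_kept, 0), 2);
  IntegerMatrix c1(m.N, 6), c2(m.N, 6);
  IntegerMatrix Icnt(m.nr, m.K);
  int kept = 0;
  int unc_prop = 0, unc_acc = 0, swp_prop = 0, swp_acc = 0;
  int tmp_prop = 0, tmp_acc = 0;

  std::vector<double> Aws;
  std::vector<double> lps(nT);
  for (int sweep = 1; sweep <= total; ++sweep) {
    for (int c = 0; c < nT; ++c) {
      St &st = chains[c];
      for (int k = 0; k < m.K; ++k) gibbs_S(m, st, k, beta[c], &Aws);
      for (int k = 0; k < m.K; ++k) gibbs_R(m, st, k, beta[c]);
      gibbs_I(m, st, beta[c]);
      if (mh_period > 0 && sweep % mh_period == 0) {
        for (int k = 0; k < 2; ++k) {
          List r = mh_uncovered(m, st, k, beta[c], true);
          if (c == 0) { ++unc_prop; if (as<bool>(r["accepted"])) ++unc_acc; }
        }
        if (m.K > 2) {
          List r = mh_swap(m, st, beta[c], true);
          if (c == 0) { ++swp_prop; if (as<bool>(r["accepted"])) ++swp_acc; }
        }
      }
      if (sweep <= n_burnin && copy_period > 0 && sweep % copy_period == 0)
        copy_reference(m, chains[c]);
      lps[c] = log_post(m, chains[c]);
    }
    // replica-exchange between adjacent temperatures (alternating parity)
    if (nT > 1) {
      int par = sweep % 2;
      for (int a = par; a + 1 < nT; a += 2) {
        double lacc = (beta[a] - beta[a + 1]) * (lps[a + 1] - lps[a]);
        ++tmp_prop;
        if (std::log(unif_rand()) < lacc) {
          std::swap(chains[a], chains[a + 1]);
          std::swap(lps[a], lps[a + 1]);
          ++tmp_acc;
        }
      }
    }
    trace[sweep - 1] = lps[0];
    if (sweep > n_burnin && (sweep - n_burnin) % thin == 0 &&
        kept < n_samples) {
      St &st = chains[0];
      int a = st.R[0], b = st.R[1];
      geno(kept, 0) = std::min(a, b) + 1;
      geno(kept, 1) = std::max(a, b) + 1;
      // greedy label matching of (S1, S2) against the running consensus
      long keep_sc = 0, swap_sc = 0;
      for (int n = 0; n < m.N; ++n) {
        int s1 = st.S[0 + (size_t)m.K * n], s2 = st.S[1 + (size_t)m.K * n];
        keep_sc += c1(n, s1) + c2(n, s2);
        swap_sc += c1(n, s2) + c2(n, s1);
      }
      bool flip = swap_sc > keep_sc;
      for (int n = 0; n < m.N; ++n) {
        int s1 = st.S[0 + (size_t)m.K * n], s2 = st.S[1 + (size_t)m.K * n];
        if (flip) std::swap(s1, s2);
        ++c1(n, s1); ++c2(n, s2);
      }
      for (int i = 0; i < m.nr; ++i) ++Icnt(i, st.I[i]);
      ++kept;
    }
  }

  List finals(nT);
  for (int c = 0; c < nT; ++c) finals[c] = state_out(chains[c], m);
  return List::create(
    _["genotypes"] = geno, _["n_kept"] = kept,
    _["seq_counts1"] = c1, _["seq_counts2"] = c2,
    _["I_counts"] = Icnt, _["trace"] = trace,
    _["accept"] = List::create(
      _["mh_uncovered"] = NumericVector::create(unc_acc, unc_prop),
      _["mh_decoy_swap"] = NumericVector::create(swp_acc, swp_prop),
      _["tempering"] = NumericVector::create(tmp_acc, tmp_prop)),
    _["final_states"] = finals);
}
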