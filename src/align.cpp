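#include <Rcpp.h>
using namespace Rcpp;

// Semi-global affine-gap alignment of a read against the ungapped sequence
// of one allele, maximizing the HLA-read (HR) score directly: every column
// carrying a read symbol earns the length reward beta; a mismatch of two
// concrete bases costs log(p/3) with p the quality-implied mismatch
// probability of that read base; an N opposite a concrete symbol costs
// alpha_N; read deletions/insertions pay affine open/extend penalties.
// The allele may be entered and left at any position for free (reads are
// fragments of the gene); the read must be fully consumed.
//
// Symbol codes: 1=A 2=C 3=G 4=T 5=N (no gaps on input).

static inline double col_score(int r, int t, double p, double aN,
                               double beta) {
  if (r == 5 || t == 5) return aN + beta;
  if (r == t) return beta;
  return std::log(p / 3.0) + beta;
}

// Score-only variant over a whole allele panel: two-row rolling DP, no
// traceback (used for HR scoring of every read against every allele; the
// accepted reads are re-aligned with cpp_align_read for projection).
// [[Rcpp::export]]
NumericVector cpp_score_db(IntegerVector read, NumericVector phat,
                           List alleles,
                           double a_do, double a_de, double a_io,
                           double a_ie, double a_N, double beta) {
  const int L = read.size();
  const int na = alleles.size();
  NumericVector out(na);
  std::vector<double> mm(L);             // log(p/3) per read base
  for (int i = 0; i < L; ++i) mm[i] = std::log(phat[i] / 3.0);

  for (int a = 0; a < na; ++a) {
    IntegerVector allele = alleles[a];
    const int M = allele.size();
    if (L == 0 || M == 0) { out[a] = R_NegInf; continue; }
    const double NEG = -1e30;
    std::vector<double> pM(M + 1, 0.0), pD(M + 1, NEG), pI(M + 1, NEG);
    std::vector<double> cM(M + 1), cD(M + 1), cI(M + 1);
    double best = NEG;
    for (int i = 1; i <= L; ++i) {
      const int ri = read[i - 1];
      const double sc_mm = mm[i - 1] + beta;
      const double sc_N = a_N + beta;
      cM[0] = NEG; cD[0] = NEG; cI[0] = NEG;
      for (int j = 1; j <= M; ++j) {
        const int tj = allele[j - 1];
        double d0 = pM[j - 1];
        if (pD[j - 1] > d0) d0 = pD[j - 1];
        if (pI[j - 1] > d0) d0 = pI[j - 1];
        cM[j] = d0 + ((ri == 5 || tj == 5) ? sc_N :
                      (ri == tj ? beta : sc_mm));
        double bo = cM[j - 1] > cI[j - 1] ? cM[j - 1] : cI[j - 1];
        double v = bo + a_do;
        if (cD[j - 1] + a_de > v) v = cD[j - 1] + a_de;
        cD[j] = v;
        if (i == 1) {
          cI[j] = NEG;      // leading insertions would leave the read
        } else {            // unanchored on the allele
          double bo2 = pM[j] > pD[j] ? pM[j] : pD[j];
          double v2 = bo2 + a_io;
          if (pI[j] + a_ie > v2) v2 = pI[j] + a_ie;
          cI[j] = v2 + beta;
        }
      }
      if (i == L)
        for (int j = 1; j <= M; ++j) {
          if (cM[j] > best) best = cM[j];
          if (cI[j] > best) best = cI[j];
        }
      std::swap(pM, cM); std::swap(pD, cD); std::swap(pI, cI);
    }
    out[a] = (best < NEG / 2) ? R_NegInf : best;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_align_read(IntegerVector read, NumericVector phat,
                    IntegerVector allele,
                    double a_do, double a_de, double a_io, double a_ie,
                    double a_N, double beta) {
  const int L = read.size(), M = allele.size();
  const double NEG = -1e30;
  if (L == 0 || M == 0)
    return List::create(_["score"] = R_NegInf);

  // dp[state][(i)*(M+1)+j], states 0=M(atch) 1=D(read gap) 2=I(nsertion)
  std::vector<double> dpM((L + 1) * (M + 1), NEG), dpD(dpM), dpI(dpM);
  std::vector<signed char> tbM(dpM.size(), -1), tbD(tbM), tbI(tbM);
  for (int j = 0; j <= M; ++j) dpM[j] = 0.0;   // free start anywhere

  for (int i = 1; i <= L; ++i) {
    const double pi = phat[i - 1];
    const int ri = read[i - 1];
    for (int j = 0; j <= M; ++j) {
      const size_t c = (size_t)i * (M + 1) + j, pu = c - (M + 1);
      if (j >= 1) {
        const size_t pd = pu - 1;
        // match/mismatch column
        double best = dpM[pd]; int from = 0;
        if (dpD[pd] > best) { best = dpD[pd]; from = 1; }
        if (dpI[pd] > best) { best = dpI[pd]; from = 2; }
        if (best > NEG / 2) {
          dpM[c] = best + col_score(ri, allele[j - 1], pi, a_N, beta);
          tbM[c] = (signed char)from;
        }
        // read gap consuming allele base j (deletion in read)
        const size_t pl = c - 1;
        double bo = std::max(dpM[pl], dpI[pl]);
        double v = std::max(bo + a_do, dpD[pl] + a_de);
        if (v > NEG / 2) {
          dpD[c] = v;
          tbD[c] = (dpD[pl] + a_de >= bo + a_do) ? 1 : (dpM[pl] >= dpI[pl] ? 0 : 2);
        }
        // read base as insertion after allele base j (not as the first
        // consumed base: the alignment must anchor on the allele)
        if (i > 1) {
          double bo2 = std::max(dpM[pu], dpD[pu]);
          double v2 = std::max(bo2 + a_io, dpI[pu] + a_ie);
          if (v2 > NEG / 2) {
            dpI[c] = v2 + beta;
            tbI[c] = (dpI[pu] + a_ie >= bo2 + a_io) ? 2 : (dpM[pu] >= dpD[pu] ? 0 : 1);
          }
        }
      }
    }
  }

  double best = NEG; int bj = -1, bs = -1;
  for (int j = 1; j <= M; ++j) {
    const size_t c = (size_t)L * (M + 1) + j;
    if (dpM[c] > best) { best = dpM[c]; bj = j; bs = 0; }
    if (dpI[c] > best) { best = dpI[c]; bj = j; bs = 2; }
  }
  if (bj < 0 || best < NEG / 2)
    return List::create(_["score"] = R_NegInf);

  // traceback: columns of (read index, allele index), 0 = gap
  std::vector<int> rcol, tcol;
  int i = L, j = bj, s = bs;
  while (i > 0) {
    const size_t c = (size_t)i * (M + 1) + j;
    if (s == 0) {
      rcol.push_back(i); tcol.push_back(j);
      s = tbM[c]; --i; --j;
    } else if (s == 1) {
      rcol.push_back(0); tcol.push_back(j);
      s = tbD[c]; --j;
    } else {
      rcol.push_back(i); tcol.push_back(0);
      s = tbI[c]; --i;
    }
  }
  std::reverse(rcol.begin(), rcol.end());
  std::reverse(tcol.begin(), tcol.end());
  int start_offset = 0;
  for (size_t c = 0; c < tcol.size(); ++c)
    if (tcol[c] > 0) { start_offset = tcol[c]; break; }
  return List::create(_["score"] = best,
                      _["read_idx"] = wrap(rcol),
                      _["allele_idx"] = wrap(tcol),
                      _["start_offset"] = start_offset);
}
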