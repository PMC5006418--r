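// Local (Smith-Waterman-entry/exit) profile-HMM dynamic programming.
//
// Layout: M match states with per-state emission log-odds vs the null;
// insert states emit at the null (log-odds 0).  trans row k (0-based)
// holds log transition probabilities out of layer k:
//   0 MM: M_k -> M_{k+1}   1 MI: M_k -> I_k    2 MD: M_k -> D_{k+1}
//   3 IM: I_k -> M_{k+1}   4 II: I_k -> I_k
//   5 DM: D_k -> M_{k+1}   6 DD: D_k -> D_{k+1}
// Alignment may enter at any match state (weight 1/M) and leave after any
// match state (weight 1/M); flanking residues are free (log-odds 0), so
// scores are directly comparable across window lengths.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double NEG = -1e300;

static inline double lse2(double a, double b) {
  if (a < b) std::swap(a, b);
  if (b <= NEG / 2) return a;
  return a + log1p(std::exp(b - a));
}

static inline double em_lookup(const NumericMatrix& memis, int k, int code) {
  return (code >= 4) ? 0.0 : memis(k, code);
}

// Forward log-likelihood (nats) of the local alignment model on
// codes[from,to).  Runs in scaled linear space (classic per-position HMM
// scaling, no transcendentals in the inner loop); emission/transition
// parameters are passed as linear-space raw arrays: em[k*5 + code]
// (code 4 = N, odds 1) and tr[k*7 + {MM,MI,MD,IM,II,DM,DD}].
static double forward_range_lin(const std::vector<int>& codes, int from, int to,
                                int M, const double* em, const double* tr) {
  const int L = to - from;
  if (L <= 0 || M <= 0) return NEG;
  const double entry = 1.0 / M, exitw = 1.0 / M;
  std::vector<double> Fm(M, 0.0), Fi(M, 0.0), Fd(M, 0.0);
  std::vector<double> Gm(M), Gi(M), Gd(M);
  double s = 0.0;       // log scale: absolute = value * exp(s)
  double total = NEG;   // log space accumulator
  for (int i = 1; i <= L; ++i) {
    int x = codes[from + i - 1];
    double pref = std::exp(-s);  // free-prefix weight (absolute 1), s >= 0
    double rowmax = pref;
    double rowsum_m = 0.0;
    for (int k = 0; k < M; ++k) {
      double acc = entry * pref;
      if (k > 0) {
        const double* t = tr + (size_t)(k - 1) * 7;
        acc += Fm[k - 1] * t[0] + Fi[k - 1] * t[3] + Fd[k - 1] * t[5];
      }
      Gm[k] = em[(size_t)k * 5 + x] * acc;
      const double* tk = tr + (size_t)k * 7;
      Gi[k] = Fm[k] * tk[1] + Fi[k] * tk[4];
      rowsum_m += Gm[k];
      if (Gm[k] > rowmax) rowmax = Gm[k];
      if (Gi[k] > rowmax) rowmax = Gi[k];
    }
    // D column uses the *current* position's M values
    Gd[0] = 0.0;
    for (int k = 1; k < M; ++k) {
      const double* t = tr + (size_t)(k - 1) * 7;
      Gd[k] = Gm[k - 1] * t[2] + Gd[k - 1] * t[6];
      if (Gd[k] > rowmax) rowmax = Gd[k];
    }
    if (rowsum_m > 0) {
      double t2 = std::log(rowsum_m * exitw) + s;
      total = lse2(total, t2);
    }
    // renormalise so the largest live value (or the prefix weight) is 1
    if (rowmax > 1e30 || rowmax < 1e-30) {
      double inv = 1.0 / rowmax;
      for (int k = 0; k < M; ++k) { Gm[k] *= inv; Gi[k] *= inv; Gd[k] *= inv; }
      s += std::log(rowmax);
      if (s < 0) {  // keep exp(-s) <= 1 so the prefix never overflows
        double corr = std::exp(s);
        for (int k = 0; k < M; ++k) { Gm[k] *= corr; Gi[k] *= corr; Gd[k] *= corr; }
        s = 0.0;
      }
    }
    Fm.swap(Gm); Fi.swap(Gi); Fd.swap(Gd);
  }
  return total;
}

// linear-space parameter tables from the log-odds matrices
static void lin_params(const NumericMatrix& memis, const NumericMatrix& trans,
                       std::vector<double>& em, std::vector<double>& tr) {
  const int M = memis.nrow();
  em.resize((size_t)M * 5);
  tr.assign((size_t)M * 7, 0.0);
  for (int k = 0; k < M; ++k) {
    for (int a = 0; a < 4; ++a) em[(size_t)k * 5 + a] = std::exp(memis(k, a));
    em[(size_t)k * 5 + 4] = 1.0;  // N: odds 1
    for (int t = 0; t < 7; ++t) {
      double v = trans(k, t);
      tr[(size_t)k * 7 + t] = (v <= NEG / 2) ? 0.0 : std::exp(v);
    }
  }
}

//' @noRd
// [[Rcpp::export]]
List cpp_phmm_dp(IntegerVector codes_, NumericMatrix memis, NumericMatrix trans,
                 bool want_post) {
  std::vector<int> codes(codes_.begin(), codes_.end());
  const int M = memis.nrow();
  const int L = (int)codes.size();
  const double lentry = -std::log((double)M), lexit = -std::log((double)M);
  std::vector<double> em_lin, tr_lin;
  lin_params(memis, trans, em_lin, tr_lin);
  double fwd = forward_range_lin(codes, 0, L, M, em_lin.data(), tr_lin.data());

  // Viterbi
  std::vector<double> vM((size_t)M * (L + 1), NEG), vI((size_t)M * (L + 1), NEG),
      vD((size_t)M * (L + 1), NEG);
  double vit = NEG;
  for (int i = 1; i <= L; ++i) {
    int x = codes[i - 1];
    for (int k = 0; k < M; ++k) {
      size_t idx = (size_t)k * (L + 1) + i;
      double acc = lentry;
      if (k > 0 && i > 1) {
        size_t pv = (size_t)(k - 1) * (L + 1) + (i - 1);
        acc = std::max(acc, vM[pv] + trans(k - 1, 0));
        acc = std::max(acc, vI[pv] + trans(k - 1, 3));
        acc = std::max(acc, vD[pv] + trans(k - 1, 5));
      }
      vM[idx] = em_lookup(memis, k, x) + acc;
      if (i > 1) {
        size_t pi = idx - 1;
        vI[idx] = std::max(vM[pi] + trans(k, 1), vI[pi] + trans(k, 4));
      }
      if (k > 0) {
        size_t pk = (size_t)(k - 1) * (L + 1) + i;
        vD[idx] = std::max(vM[pk] + trans(k - 1, 2), vD[pk] + trans(k - 1, 6));
      }
      vit = std::max(vit, vM[idx] + lexit);
    }
  }

  NumericVector post(L, 0.0);
  double bwd_total = NEG;
  if (want_post && L > 0) {
    // backward + forward recomputed with storage
    std::vector<double> fM((size_t)M * (L + 1), NEG), fI((size_t)M * (L + 1), NEG),
        fD((size_t)M * (L + 1), NEG);
    for (int i = 1; i <= L; ++i) {
      int x = codes[i - 1];
      for (int k = 0; k < M; ++k) {
        size_t idx = (size_t)k * (L + 1) + i;
        double acc = lentry;
        if (k > 0 && i > 1) {
          size_t pv = (size_t)(k - 1) * (L + 1) + (i - 1);
          acc = lse2(acc, fM[pv] + trans(k - 1, 0));
          acc = lse2(acc, fI[pv] + trans(k - 1, 3));
          acc = lse2(acc, fD[pv] + trans(k - 1, 5));
        }
        fM[idx] = em_lookup(memis, k, x) + acc;
        if (i > 1) {
          size_t pi = idx - 1;
          fI[idx] = lse2(fM[pi] + trans(k, 1), fI[pi] + trans(k, 4));
        }
        if (k > 0) {
          size_t pk = (size_t)(k - 1) * (L + 1) + i;
          fD[idx] = lse2(fM[pk] + trans(k - 1, 2), fD[pk] + trans(k - 1, 6));
        }
      }
    }
    std::vector<double> bM((size_t)M * (L + 2), NEG), bI((size_t)M * (L + 2), NEG),
        bD((size_t)M * (L + 2), NEG);
    for (int i = L; i >= 1; --i) {
      for (int k = M - 1; k >= 0; --k) {
        size_t idx = (size_t)k * (L + 2) + i;
        double accD = NEG, accI = NEG, accM = lexit;
        if (k < M - 1) {
          double emn = (i < L) ? em_lookup(memis, k + 1, codes[i]) : NEG;
          size_t nxt = (size_t)(k + 1) * (L + 2) + (i + 1);
          size_t nxtD = (size_t)(k + 1) * (L + 2) + i;
          if (i < L) {
            accD = lse2(accD, trans(k, 5) + emn + bM[nxt]);
            accI = lse2(accI, trans(k, 3) + emn + bM[nxt]);
            accM = lse2(accM, trans(k, 0) + emn + bM[nxt]);
          }
          accD = lse2(accD, trans(k, 6) + bD[nxtD]);
          accM = lse2(accM, trans(k, 2) + bD[nxtD]);
        }
        if (i < L) {
          size_t ni = (size_t)k * (L + 2) + (i + 1);
          accI = lse2(accI, trans(k, 4) + bI[ni]);
          accM = lse2(accM, trans(k, 1) + bI[ni]);
        }
        bD[idx] = accD; bI[idx] = accI; bM[idx] = accM;
        bwd_total = lse2(bwd_total, lentry + em_lookup(memis, k, codes[i - 1]) + bM[idx]);
      }
    }
    // bwd_total accumulated over all i,k is the backward total
    for (int i = 1; i <= L; ++i) {
      double acc = NEG;
      for (int k = 0; k < M; ++k) {
        size_t fidx = (size_t)k * (L + 1) + i;
        size_t bidx = (size_t)k * (L + 2) + i;
        acc = lse2(acc, fM[fidx] + bM[bidx]);
        acc = lse2(acc, fI[fidx] + bI[bidx]);
      }
      post[i - 1] = std::exp(acc - fwd);
    }
  }
  return List::create(_["forward"] = fwd, _["viterbi"] = vit,
                      _["backward"] = bwd_total, _["post"] = post);
}

//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_phmm_scan(IntegerVector codes_, NumericMatrix memis,
                            NumericMatrix trans, int win, int stride) {
  std::vector<int> codes(codes_.begin(), codes_.end());
  const int L = (int)codes.size();
  std::vector<int> starts;
  for (int s = 0; s < L; s += stride) {
    starts.push_back(s);
    if (s + win >= L) break;
  }
  NumericMatrix out((int)starts.size(), 2);
  std::vector<double> em_lin, tr_lin;
  lin_params(memis, trans, em_lin, tr_lin);
  const int M = memis.nrow();
  for (size_t w = 0; w < starts.size(); ++w) {
    int from = starts[w], to = std::min(L, starts[w] + win);
    out(w, 0) = from;
    out(w, 1) = forward_range_lin(codes, from, to, M, em_lin.data(), tr_lin.data());
  }
  return out;
}
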