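// CYK for a miniature covariance model (profile SCFG).
//
// The guide tree is passed as flat preorder arrays (parents before
// children); node kinds: 0 MATL, 1 MATR, 2 MATP, 3 BIF, 4 END.
// Emissions are log-odds vs the background null, so inserted residues
// cost only the insert transition.  V[k][i][j] is the best log-odds of
// generating the subsequence [i,j) from the subtree rooted at node k.
// Global in the model (every consensus position is matched or deleted),
// exhaustive in the sequence.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double NEG = -1e300;

//' @noRd
// [[Rcpp::export]]
List cpp_cyk(IntegerVector codes_, IntegerVector kind, IntegerVector child1,
             IntegerVector child2, NumericMatrix emL, NumericMatrix emP,
             NumericVector tM, NumericVector tD, NumericVector tIns) {
  std::vector<int> x(codes_.begin(), codes_.end());
  const int n = (int)x.size();
  const int nn = kind.size();
  const int n1 = n + 1;
  const size_t cells = (size_t)n1 * n1;
  // raw copies of the parameters (hot loop avoids Rcpp accessors)
  std::vector<double> eL((size_t)nn * 5), eP((size_t)nn * 17);
  std::vector<double> vtM(tM.begin(), tM.end()), vtD(tD.begin(), tD.end()),
      vtI(tIns.begin(), tIns.end());
  for (int k = 0; k < nn; ++k) {
    for (int a = 0; a < 4; ++a) eL[(size_t)k * 5 + a] = emL(k, a);
    eL[(size_t)k * 5 + 4] = 0.0;  // N at background
    for (int a = 0; a < 16; ++a) eP[(size_t)k * 17 + a] = emP(k, a);
    eP[(size_t)k * 17 + 16] = 0.0;
  }
  std::vector<double> Vbuf(cells * nn);
  std::vector<int> Cbuf(cells * nn);
  std::vector<double*> V(nn);
  std::vector<int*> C(nn);
  for (int k = 0; k < nn; ++k) { V[k] = Vbuf.data() + cells * (size_t)k;
                                 C[k] = Cbuf.data() + cells * (size_t)k; }
  for (int k = nn - 1; k >= 0; --k) {
    int kd = kind[k], c1k = child1[k], c2k = child2[k];
    double* Vk = V[k]; int* Ck = C[k];
    const double* V1 = (c1k >= 0) ? V[c1k] : NULL;
    const int* C1 = (c1k >= 0) ? C[c1k] : NULL;
    const double tMk = vtM[k], tDk = vtD[k], tIk = vtI[k];
    const double* eLk = eL.data() + (size_t)k * 5;
    const double* ePk = eP.data() + (size_t)k * 17;
    if (kd == 4) {  // END: remaining residues are inserts
      for (int len = 0; len <= n; ++len)
        for (int i = 0; i + len <= n; ++i) {
          size_t idx = (size_t)i * n1 + (i + len);
          Vk[idx] = len * tIk; Ck[idx] = 0;
        }
      continue;
    }
    if (kd == 3) {  // BIF
      const double* V2 = V[c2k]; const int* C2 = C[c2k];
      for (int len = 0; len <= n; ++len)
        for (int i = 0; i + len <= n; ++i) {
          int j = i + len;
          size_t idx = (size_t)i * n1 + j;
          double best = NEG; int bc = 0;
          const double* r1 = V1 + (size_t)i * n1;
          for (int m = i; m <= j; ++m) {
            double v = r1[m] + V2[(size_t)m * n1 + j];
            if (v > best) { best = v; bc = C1[(size_t)i * n1 + m] + C2[(size_t)m * n1 + j]; }
          }
          Vk[idx] = best; Ck[idx] = bc;
        }
      continue;
    }
    for (int len = 0; len <= n; ++len) {
      for (int i = 0; i + len <= n; ++i) {
        int j = i + len;
        size_t idx = (size_t)i * n1 + j;
        double best; int bc;
        // delete (skip the node's consensus positions)
        best = tDk + V1[idx]; bc = C1[idx];
        if (kd == 0) {
          if (len >= 1) {
            size_t ci = idx + n1;  // (i+1, j)
            double v = tMk + eLk[x[i]] + V1[ci];
            if (v > best) { best = v; bc = 1 + C1[ci]; }
            double w = tIk + Vk[ci];
            if (w > best) { best = w; bc = Ck[ci]; }
          }
        } else if (kd == 1) {
          if (len >= 1) {
            size_t ci = idx - 1;  // (i, j-1)
            double v = tMk + eLk[x[j - 1]] + V1[ci];
            if (v > best) { best = v; bc = 1 + C1[ci]; }
            double w = tIk + Vk[ci];
            if (w > best) { best = w; bc = Ck[ci]; }
          }
        } else {  // MATP
          if (len >= 2) {
            size_t ci = idx + n1 - 1;  // (i+1, j-1)
            int xi = x[i], xj = x[j - 1];
            double pe = (xi >= 4 || xj >= 4) ? 0.0 : ePk[xi * 4 + xj];
            double v = tMk + pe + V1[ci];
            if (v > best) { best = v; bc = 2 + C1[ci]; }
          }
          if (len >= 1) {
            size_t il = idx + n1;
            double w = tIk + Vk[il];
            if (w > best) { best = w; bc = Ck[il]; }
            size_t ir = idx - 1;
            double w2 = tIk + Vk[ir];
            if (w2 > best) { best = w2; bc = Ck[ir]; }
          }
        }
        Vk[idx] = best; Ck[idx] = bc;
      }
    }
  }
  // best root cell: global in the model, local in the sequence (flanking
  // residues outside the parse are free)
  int bi = 0, bj = n;
  {
    double best = NEG;
    for (int i = 0; i <= n; ++i)
      for (int j = i; j <= n; ++j) {
        double v = V[0][(size_t)i * (n + 1) + j];
        if (v > best) { best = v; bi = i; bj = j; }
      }
  }
  // traceback for the footprint of match-emitted residues
  int astart = n, aend = 0;
  {
    struct Frame { int k, i, j; };
    std::vector<Frame> stack;
    stack.push_back({0, bi, bj});
    const double tol = 1e-9;
    while (!stack.empty()) {
      Frame f = stack.back(); stack.pop_back();
      int k = f.k, i = f.i, j = f.j, len = j - i;
      size_t idx = (size_t)i * (n + 1) + j;
      double v = V[k][idx];
      if (v <= NEG / 2) break;
      int kd = kind[k], c1 = child1[k], c2 = child2[k];
      if (kd == 4) continue;
      if (kd == 3) {
        bool done = false;
        for (int m = i; m <= j && !done; ++m) {
          size_t i1 = (size_t)i * (n + 1) + m, i2 = (size_t)m * (n + 1) + j;
          if (std::fabs(V[c1][i1] + V[c2][i2] - v) < tol) {
            stack.push_back({c2, m, j});
            stack.push_back({c1, i, m});
            done = true;
          }
        }
        continue;
      }
      // mirror the preference order used when filling the tables
      if (kd == 0 && len >= 1) {
        size_t ci = (size_t)(i + 1) * (n + 1) + j;
        double e1 = eL[(size_t)k * 5 + x[i]];
        if (std::fabs(vtM[k] + e1 + V[c1][ci] - v) < tol) {
          if (i < astart) astart = i;
          if (i + 1 > aend) aend = i + 1;
          stack.push_back({c1, i + 1, j});
          continue;
        }
      } else if (kd == 1 && len >= 1) {
        size_t ci = (size_t)i * (n + 1) + (j - 1);
        double e1 = eL[(size_t)k * 5 + x[j - 1]];
        if (std::fabs(vtM[k] + e1 + V[c1][ci] - v) < tol) {
          if (j - 1 < astart) astart = j - 1;
          if (j > aend) aend = j;
          stack.push_back({c1, i, j - 1});
          continue;
        }
      } else if (kd == 2 && len >= 2) {
        size_t ci = (size_t)(i + 1) * (n + 1) + (j - 1);
        int xi = x[i], xj = x[j - 1];
        double pe = (xi >= 4 || xj >= 4) ? 0.0 : eP[(size_t)k * 17 + xi * 4 + xj];
        if (std::fabs(vtM[k] + pe + V[c1][ci] - v) < tol) {
          if (i < astart) astart = i;
          if (j > aend) aend = j;
          stack.push_back({c1, i + 1, j - 1});
          continue;
        }
      }
      if (std::fabs(vtD[k] + V[c1][idx] - v) < tol) {
        stack.push_back({c1, i, j});
        continue;
      }
      if (len >= 1 && (kd == 0 || kd == 2)) {
        size_t ii = (size_t)(i + 1) * (n + 1) + j;
        if (std::fabs(vtI[k] + V[k][ii] - v) < tol) {
          stack.push_back({k, i + 1, j});
          continue;
        }
      }
      if (len >= 1 && (kd == 1 || kd == 2)) {
        size_t ii = (size_t)i * (n + 1) + (j - 1);
        if (std::fabs(vtI[k] + V[k][ii] - v) < tol) {
          stack.push_back({k, i, j - 1});
          continue;
        }
      }
    }
  }
  size_t top = (size_t)0 * (n + 1) + n;
  size_t loc = (size_t)bi * (n + 1) + bj;
  double nats_global = V[0][top];
  double nats = V[0][loc];
  int matched = C[0][loc];
  if (matched == 0) { astart = 0; aend = 0; }
  return List::create(_["bits"] = nats / std::log(2.0),
                      _["bits_global"] = nats_global / std::log(2.0),
                      _["matched"] = matched,
                      _["align_start"] = astart, _["align_end"] = aend);
}
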