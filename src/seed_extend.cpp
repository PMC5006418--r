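// Word-seeded local alignment with affine gaps.
//
// Stages mirror classic nucleotide blast: exact W-mer seeding against a
// hashed query set, ungapped X-drop extension along the diagonal, and --
// for seeds whose ungapped segment reaches a trigger score -- a banded
// local Smith-Waterman in a window around the segment.  Scores are
// integer (match reward r > 0, mismatch penalty q < 0, gap of length k
// costs G + k*E).  N never seeds a word and always scores as a mismatch.
// The single-query and multi-query entry points share one core, so
// their results are identical.

#include <Rcpp.h>
#include <cstdint>
#include <set>
#include <tuple>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return 4;  // N / anything else: mismatch, never seeds
  }
}

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = base_code(s[i]);
  return v;
}

struct Hsp {
  int qs, qe, gs, ge;       // 0-based half-open
  int score, matches, cols;
};

// Band-compact local Smith-Waterman on query x subject[ws,we), `band`+1
// diagonals centred on diagonal dc (diagonal = g - q).  Offset
// o = j - (i + dcw - half) indexes the band; diag keeps o, up is o+1,
// left is o-1.  Buffers are reused across calls.
struct SwBuffers {
  std::vector<double> H, X, Y;
  std::vector<uint8_t> TH, TX, TY;
};

static bool banded_sw(const std::vector<int>& Q, const std::vector<int>& S,
                      int ws, int we, int dc, int band,
                      int r, int q, int G, int E, SwBuffers& buf, Hsp& out) {
  const int m = (int)Q.size();
  const int half = band / 2;
  const int wlen = we - ws;
  if (wlen <= 0) return false;
  const int BW = 2 * half + 3;  // band cells + sentinel column each side
  const double NEG = -1e18;
  const size_t need = (size_t)(m + 1) * BW;
  buf.H.assign(need, NEG);
  buf.X.assign(need, NEG);
  buf.Y.assign(need, NEG);
  buf.TH.assign(need, 0);
  buf.TX.assign(need, 0);
  buf.TY.assign(need, 0);
  const int dcw = dc - ws;
  const double gapOpen = -(double)(G + E), gapExt = -(double)E;
  double best = 0.0;
  int bi = -1, bo = -1;
  // row 0: fresh starts along the band where j is in range
  for (int o = 1; o <= BW - 2; ++o) {
    int j = 0 + dcw - half + (o - 1);
    if (j >= 0 && j <= wlen) buf.H[o] = 0.0;
  }
  for (int i = 1; i <= m; ++i) {
    size_t row = (size_t)i * BW, prow = row - BW;
    for (int o = 1; o <= BW - 2; ++o) {
      int j = i + dcw - half + (o - 1);
      if (j < 1 || j > wlen) continue;
      size_t idx = row + o;
      double hu = buf.H[prow + o + 1], xu = buf.X[prow + o + 1];
      double x = std::max(hu + gapOpen, xu + gapExt);
      buf.TX[idx] = (xu + gapExt >= hu + gapOpen) ? 1 : 0;
      buf.X[idx] = x;
      double hl = buf.H[row + o - 1], yl = buf.Y[row + o - 1];
      double y = std::max(hl + gapOpen, yl + gapExt);
      buf.TY[idx] = (yl + gapExt >= hl + gapOpen) ? 1 : 0;
      buf.Y[idx] = y;
      int qa = Q[i - 1], sb = S[ws + j - 1];
      double sc = (qa == sb && qa < 4) ? (double)r : (double)q;
      double d = buf.H[prow + o] + sc;
      double h = 0.0; uint8_t t = 0;
      if (d > h) { h = d; t = 1; }
      if (x > h) { h = x; t = 2; }
      if (y > h) { h = y; t = 3; }
      buf.H[idx] = h; buf.TH[idx] = t;
      if (h > best) { best = h; bi = i; bo = o; }
    }
  }
  if (bi < 0 || best <= 0.0) return false;
  // traceback
  int i = bi, o = bo, matches = 0, cols = 0;
  int qe = bi, ge = ws + (bi + dcw - half + (bo - 1));
  int state = 0;
  while (true) {
    size_t idx = (size_t)i * BW + o;
    int j = i + dcw - half + (o - 1);
    if (state == 0) {
      uint8_t t = buf.TH[idx];
      if (t == 0) break;
      if (t == 1) {
        ++cols;
        if (Q[i - 1] == S[ws + j - 1] && Q[i - 1] < 4) ++matches;
        --i;  // diag keeps o
      } else if (t == 2) state = 2;
      else state = 3;
    } else if (state == 2) {
      ++cols;
      uint8_t t = buf.TX[idx];
      --i; ++o;  // up
      if (t == 0) state = 0;
    } else {
      ++cols;
      uint8_t t = buf.TY[idx];
      --o;  // left
      if (t == 0) state = 0;
    }
  }
  int j = i + dcw - half + (o - 1);
  out.qs = i; out.qe = qe;
  out.gs = ws + j; out.ge = ge;
  out.score = (int)(best + 0.5);
  out.matches = matches; out.cols = cols;
  return true;
}

struct SeRow {
  int qid, qs, qe, gs, ge, score, matches, cols;
};

// Shared seed-and-extend core over a set of encoded queries.
static void seed_extend_core(const std::vector<std::vector<int> >& Qs,
                             const std::vector<int>& S,
                             int r, int q, int G, int E, int W,
                             double xdrop, int band, int trigger,
                             int min_report_score,
                             std::vector<SeRow>& rows) {
  const int n = (int)S.size();
  const int Q = (int)Qs.size();
  if (n < W) return;
  const uint32_t mask = (W >= 16) ? 0xFFFFFFFFu : ((1u << (2 * W)) - 1u);
  std::unordered_map<uint32_t, std::vector<uint32_t> > hash;
  for (int qi = 0; qi < Q; ++qi) {
    const std::vector<int>& Qv = Qs[qi];
    uint32_t key = 0; int valid = 0;
    for (int i = 0; i < (int)Qv.size(); ++i) {
      int c = Qv[i];
      if (c >= 4) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint32_t)c) & mask;
      if (++valid >= W)
        hash[key].push_back(((uint32_t)qi << 20) | (uint32_t)(i - W + 1));
    }
  }
  // per-query bookkeeping: gapped extensions already attempted (by
  // ungapped-segment anchor) and accepted HSP footprints (containment skip)
  std::vector<std::set<std::pair<int,int> > > attempted(Q);
  std::vector<std::vector<Hsp> > found(Q);
  std::vector<std::set<std::tuple<int,int,int,int> > > seen(Q);
  SwBuffers buf;
  uint32_t key = 0; int valid = 0;
  for (int j = 0; j < n; ++j) {
    int c = S[j];
    if (c >= 4) { valid = 0; key = 0; continue; }
    key = ((key << 2) | (uint32_t)c) & mask;
    if (++valid < W) continue;
    auto it = hash.find(key);
    if (it == hash.end()) continue;
    int gpos = j - W + 1;
    for (uint32_t packed : it->second) {
      int qi = (int)(packed >> 20);
      int qpos = (int)(packed & 0xFFFFFu);
      const std::vector<int>& Qv = Qs[qi];
      const int m = (int)Qv.size();
      // ungapped X-drop extension from the seed
      int bestu = W * r;
      int bqe = qpos + W, bge = gpos + W;
      {
        int i2 = bqe, j2 = bge, c2 = bestu, b2 = bestu;
        while (i2 < m && j2 < n) {
          c2 += (Qv[i2] == S[j2] && Qv[i2] < 4) ? r : q;
          ++i2; ++j2;
          if (c2 > b2) { b2 = c2; bqe = i2; bge = j2; }
          else if (b2 - c2 > xdrop) break;
        }
        bestu = b2;
      }
      int bqs = qpos, bgs = gpos;
      {
        int i2 = qpos - 1, j2 = gpos - 1, c2 = bestu, b2 = bestu;
        while (i2 >= 0 && j2 >= 0) {
          c2 += (Qv[i2] == S[j2] && Qv[i2] < 4) ? r : q;
          if (c2 > b2) { b2 = c2; bqs = i2; bgs = j2; }
          else if (b2 - c2 > xdrop) break;
          --i2; --j2;
        }
        bestu = b2;
      }
      if (bestu < trigger) continue;
      if (!attempted[qi].insert(std::make_pair(bqs, bgs)).second) continue;
      bool contained = false;
      for (const Hsp& h : found[qi]) {
        if (h.qs <= bqs && bqe <= h.qe && h.gs <= bgs && bge <= h.ge) {
          contained = true; break;
        }
      }
      if (contained) continue;
      int ws = std::max(0, bgs - m - 25);
      int we = std::min(n, bge + m + 25);
      Hsp h;
      if (!banded_sw(Qs[qi], S, ws, we, bgs - bqs, band, r, q, G, E, buf, h))
        continue;
      if (h.score < min_report_score) continue;
      auto sig = std::make_tuple(h.qs, h.qe, h.gs, h.ge);
      if (seen[qi].count(sig)) continue;
      seen[qi].insert(sig);
      found[qi].push_back(h);
      SeRow row;
      row.qid = qi; row.qs = h.qs; row.qe = h.qe; row.gs = h.gs; row.ge = h.ge;
      row.score = h.score; row.matches = h.matches; row.cols = h.cols;
      rows.push_back(row);
    }
  }
}

static DataFrame rows_to_df(const std::vector<SeRow>& rows, bool with_qid) {
  int n = (int)rows.size();
  IntegerVector qid(n), qs(n), qe(n), gs(n), ge(n), sc(n), ma(n), co(n);
  for (int i = 0; i < n; ++i) {
    qid[i] = rows[i].qid + 1;
    qs[i] = rows[i].qs; qe[i] = rows[i].qe;
    gs[i] = rows[i].gs; ge[i] = rows[i].ge;
    sc[i] = rows[i].score; ma[i] = rows[i].matches; co[i] = rows[i].cols;
  }
  if (with_qid)
    return DataFrame::create(_["query_index"] = qid,
                             _["qstart"] = qs, _["qend"] = qe,
                             _["gstart"] = gs, _["gend"] = ge,
                             _["score"] = sc, _["matches"] = ma,
                             _["length"] = co);
  return DataFrame::create(_["qstart"] = qs, _["qend"] = qe,
                           _["gstart"] = gs, _["gend"] = ge,
                           _["score"] = sc, _["matches"] = ma,
                           _["length"] = co);
}

//' @noRd
// [[Rcpp::export]]
DataFrame cpp_seed_extend(std::string query, std::string subject,
                          int r, int q, int G, int E, int W,
                          double xdrop, int band, int trigger,
                          int min_report_score) {
  std::vector<std::vector<int> > Qs(1, encode(query));
  std::vector<int> S = encode(subject);
  std::vector<SeRow> rows;
  if ((int)Qs[0].size() >= W)
    seed_extend_core(Qs, S, r, q, G, E, W, xdrop, band, trigger,
                     min_report_score, rows);
  return rows_to_df(rows, false);
}

//' @noRd
// [[Rcpp::export]]
DataFrame cpp_seed_extend_multi(std::vector<std::string> queries,
                                std::string subject,
                                int r, int q, int G, int E, int W,
                                double xdrop, int band, int trigger,
                                int min_report_score) {
  std::vector<std::vector<int> > Qs(queries.size());
  for (size_t i = 0; i < queries.size(); ++i) Qs[i] = encode(queries[i]);
  std::vector<int> S = encode(subject);
  std::vector<SeRow> rows;
  seed_extend_core(Qs, S, r, q, G, E, W, xdrop, band, trigger,
                   min_report_score, rows);
  return rows_to_df(rows, true);
}
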