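#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Affine-gap Needleman-Wunsch, end gaps charged (a gap of length L costs
// gap_open + L * gap_extend, mirroring the BLASTn cost model). 'N' mismatches
// everything, including another 'N'. Traceback preference: diagonal, then
// gap-in-b (consume a), then gap-in-a (consume b) -- fixed so results are
// deterministic.

static const double NEG_INF = -1e30;

struct Workspace {
  std::vector<double> M, X, Y;
  std::vector<unsigned char> tbM, tbX, tbY;
  void ensure(size_t cells) {
    if (M.size() < cells) {
      M.resize(cells); X.resize(cells); Y.resize(cells);
      tbM.resize(cells); tbX.resize(cells); tbY.resize(cells);
    }
  }
};

struct AlnResult {
  double score;
  int columns;
  int matches;
  std::string aligned_a;
  std::string aligned_b;
  std::vector<int> match_vec; // per a-position: 1 if aligned to identical base
};

static inline double subscore(char x, char y, double match, double mismatch) {
  if (x == 'N' || y == 'N') return mismatch;
  return (x == y) ? match : mismatch;
}

static void nw_align(const std::string &a, const std::string &b,
                     double match, double mismatch,
                     double gap_open, double gap_extend,
                     bool build_strings, Workspace &ws, AlnResult &res) {
  const int n = a.size(), m = b.size();
  const int W = m + 1;
  ws.ensure((size_t)(n + 1) * W);
  double *Mc = ws.M.data(), *Xc = ws.X.data(), *Yc = ws.Y.data();
  unsigned char *tbM = ws.tbM.data(), *tbX = ws.tbX.data(), *tbY = ws.tbY.data();

  Mc[0] = 0.0; Xc[0] = NEG_INF; Yc[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    Mc[j] = NEG_INF; Xc[j] = NEG_INF;
    Yc[j] = -(gap_open + j * gap_extend);
    tbY[j] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    const int row = i * W, prev = (i - 1) * W;
    Mc[row] = NEG_INF; Yc[row] = NEG_INF;
    Xc[row] = -(gap_open + i * gap_extend);
    tbX[row] = (i == 1) ? 0 : 1;
    const char ai = a[i - 1];
    const double go = gap_open + gap_extend, ge = gap_extend;
    for (int j = 1; j <= m; ++j) {
      const int c = row + j, d = prev + (j - 1), u = prev + j, l = c - 1;
      // M: diagonal step
      const double s = subscore(ai, b[j - 1], match, mismatch);
      double best = Mc[d]; unsigned char from = 0;
      if (Xc[d] > best) { best = Xc[d]; from = 1; }
      if (Yc[d] > best) { best = Yc[d]; from = 2; }
      Mc[c] = best + s; tbM[c] = from;
      // X: gap in b (consume a[i-1])
      double bestx = Mc[u] - go; unsigned char fx = 0;
      if (Xc[u] - ge > bestx) { bestx = Xc[u] - ge; fx = 1; }
      if (Yc[u] - go > bestx) { bestx = Yc[u] - go; fx = 2; }
      Xc[c] = bestx; tbX[c] = fx;
      // Y: gap in a (consume b[j-1])
      double besty = Mc[l] - go; unsigned char fy = 0;
      if (Yc[l] - ge > besty) { besty = Yc[l] - ge; fy = 2; }
      if (Xc[l] - go > besty) { besty = Xc[l] - go; fy = 1; }
      Yc[c] = besty; tbY[c] = fy;
    }
  }
  const int endc = n * W + m;
  double best = Mc[endc]; int layer = 0;
  if (Xc[endc] > best) { best = Xc[endc]; layer = 1; }
  if (Yc[endc] > best) { best = Yc[endc]; layer = 2; }
  res.score = best;
  res.columns = 0; res.matches = 0;
  res.aligned_a.clear(); res.aligned_b.clear();
  res.match_vec.assign(n, 0);

  std::string &ra = res.aligned_a, &rb = res.aligned_b;
  if (build_strings) { ra.reserve(n + m); rb.reserve(n + m); }
  int i = n, j = m, columns = 0;
  while (i > 0 || j > 0) {
    if (i == 0) layer = 2;
    else if (j == 0) layer = 1;
    if (layer == 0) {
      unsigned char from = tbM[i * W + j];
      const char ca = a[i - 1], cb = b[j - 1];
      if (build_strings) { ra.push_back(ca); rb.push_back(cb); }
      if (ca == cb && ca != 'N') { res.match_vec[i - 1] = 1; res.matches++; }
      --i; --j; ++columns;
      layer = from;
    } else if (layer == 1) { // X: gap in b
      unsigned char from = tbX[i * W + j];
      if (build_strings) { ra.push_back(a[i - 1]); rb.push_back('-'); }
      --i; ++columns;
      layer = from;
    } else { // Y: gap in a
      unsigned char from = tbY[i * W + j];
      if (build_strings) { ra.push_back('-'); rb.push_back(b[j - 1]); }
      --j; ++columns;
      layer = from;
    }
  }
  res.columns = columns;
  if (build_strings) {
    std::reverse(ra.begin(), ra.end());
    std::reverse(rb.begin(), rb.end());
  }
}

// [[Rcpp::export(name = ".nw_align_one")]]
List nw_align_one(std::string a, std::string b, double match, double mismatch,
                  double gap_open, double gap_extend) {
  Workspace ws; AlnResult r;
  nw_align(a, b, match, mismatch, gap_open, gap_extend, true, ws, r);
  LogicalVector mv(r.match_vec.size());
  for (size_t k = 0; k < r.match_vec.size(); ++k) mv[k] = r.match_vec[k] == 1;
  return List::create(
    _["score"] = r.score,
    _["identity_pct"] = r.columns > 0 ? 100.0 * r.matches / r.columns : NA_REAL,
    _["columns"] = r.columns,
    _["aligned_a"] = r.aligned_a,
    _["aligned_b"] = r.aligned_b,
    _["match"] = mv
  );
}

// batch: many queries against one target; returns per query the match vector
// (over query positions) and column identity, skipping string assembly
// [[Rcpp::export(name = ".nw_match_batch")]]
List nw_match_batch(CharacterVector queries, std::string target, double match,
                    double mismatch, double gap_open, double gap_extend) {
  const int nq = queries.size();
  List out(nq);
  Workspace ws; AlnResult r;
  for (int q = 0; q < nq; ++q) {
    std::string a = as<std::string>(queries[q]);
    nw_align(a, target, match, mismatch, gap_open, gap_extend, false, ws, r);
    LogicalVector mv(r.match_vec.size());
    for (size_t k = 0; k < r.match_vec.size(); ++k) mv[k] = r.match_vec[k] == 1;
    out[q] = List::create(
      _["match"] = mv,
      _["identity_pct"] = r.columns > 0 ? 100.0 * r.matches / r.columns : NA_REAL,
      _["score"] = r.score
    );
  }
  return out;
}

// ---- local (Smith-Waterman) and semi-global variants, same cost model ----

struct LocalResult {
  double score;
  int q_start, q_end, t_start, t_end; // 1-based inclusive; 0 when no hit
  int columns, matches;
  std::vector<int> match_vec; // per a-position: 1 if aligned to identical base
};

// affine local alignment; traceback from the best M cell to a zero start
static void sw_align(const std::string &a, const std::string &b,
                     double match, double mismatch,
                     double gap_open, double gap_extend,
                     Workspace &ws, LocalResult &res) {
  const int n = a.size(), m = b.size();
  const int W = m + 1;
  ws.ensure((size_t)(n + 1) * W);
  double *Mc = ws.M.data(), *Xc = ws.X.data(), *Yc = ws.Y.data();
  unsigned char *tbM = ws.tbM.data(), *tbX = ws.tbX.data(), *tbY = ws.tbY.data();
  const double go = gap_open + gap_extend, ge = gap_extend;

  for (int j = 0; j <= m; ++j) { Mc[j] = NEG_INF; Xc[j] = NEG_INF; Yc[j] = NEG_INF; }
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const int row = i * W, prev = (i - 1) * W;
    Mc[row] = NEG_INF; Xc[row] = NEG_INF; Yc[row] = NEG_INF;
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int c = row + j, d = prev + (j - 1), u = prev + j, l = c - 1;
      const double s = subscore(ai, b[j - 1], match, mismatch);
      double bm = 0.0; unsigned char from = 3; // 3 = fresh start
      if (Mc[d] > bm) { bm = Mc[d]; from = 0; }
      if (Xc[d] > bm) { bm = Xc[d]; from = 1; }
      if (Yc[d] > bm) { bm = Yc[d]; from = 2; }
      Mc[c] = bm + s; tbM[c] = from;
      double bestx = Mc[u] - go; unsigned char fx = 0;
      if (Xc[u] - ge > bestx) { bestx = Xc[u] - ge; fx = 1; }
      if (Yc[u] - go > bestx) { bestx = Yc[u] - go; fx = 2; }
      Xc[c] = bestx; tbX[c] = fx;
      double besty = Mc[l] - go; unsigned char fy = 0;
      if (Yc[l] - ge > besty) { besty = Yc[l] - ge; fy = 2; }
      if (Xc[l] - go > besty) { besty = Xc[l] - go; fy = 1; }
      Yc[c] = besty; tbY[c] = fy;
      if (Mc[c] > best) { best = Mc[c]; bi = i; bj = j; }
    }
  }
  res.score = best; res.columns = 0; res.matches = 0;
  res.q_start = res.q_end = res.t_start = res.t_end = 0;
  res.match_vec.assign(n, 0);
  if (best <= 0.0) return;
  res.q_end = bi; res.t_end = bj;
  int i = bi, j = bj, layer = 0, columns = 0, matches = 0;
  while (true) {
    if (layer == 0) {
      unsigned char from = tbM[i * W + j];
      if (a[i - 1] == b[j - 1] && a[i - 1] != 'N') {
        matches++;
        res.match_vec[i - 1] = 1;
      }
      ++columns; --i; --j;
      if (from == 3) break;
      layer = from;
    } else if (layer == 1) {
      unsigned char from = tbX[i * W + j];
      ++columns; --i; layer = from;
    } else {
      unsigned char from = tbY[i * W + j];
      ++columns; --j; layer = from;
    }
  }
  res.q_start = i + 1; res.t_start = j + 1;
  res.columns = columns; res.matches = matches;
}

// [[Rcpp::export(name = ".sw_align_one")]]
List sw_align_one(std::string a, std::string b, double match, double mismatch,
                  double gap_open, double gap_extend) {
  Workspace ws; LocalResult r;
  sw_align(a, b, match, mismatch, gap_open, gap_extend, ws, r);
  LogicalVector mv(r.match_vec.size());
  for (size_t k = 0; k < r.match_vec.size(); ++k) mv[k] = r.match_vec[k] == 1;
  return List::create(
    _["score"] = r.score,
    _["q_start"] = r.q_start, _["q_end"] = r.q_end,
    _["t_start"] = r.t_start, _["t_end"] = r.t_end,
    _["columns"] = r.columns, _["matches"] = r.matches,
    _["identity_pct"] = r.columns > 0 ? 100.0 * r.matches / r.columns : NA_REAL,
    _["match"] = mv
  );
}

// semi-global: pattern aligned end-to-end, free end gaps on the subject
// [[Rcpp::export(name = ".sg_align_one")]]
List sg_align_one(std::string a, std::string b, double match, double mismatch,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const int W = m + 1;
  Workspace ws;
  ws.ensure((size_t)(n + 1) * W);
  double *Mc = ws.M.data(), *Xc = ws.X.data(), *Yc = ws.Y.data();
  unsigned char *tbM = ws.tbM.data(), *tbX = ws.tbX.data(), *tbY = ws.tbY.data();
  const double go = gap_open + gap_extend, ge = gap_extend;
  // free subject prefix: row 0 is all zero starts
  for (int j = 0; j <= m; ++j) { Mc[j] = 0.0; Xc[j] = NEG_INF; Yc[j] = NEG_INF; }
  for (int i = 1; i <= n; ++i) {
    const int row = i * W, prev = (i - 1) * W;
    Mc[row] = NEG_INF; Yc[row] = NEG_INF;
    Xc[row] = -(gap_open + i * gap_extend);
    tbX[row] = (i == 1) ? 0 : 1;
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int c = row + j, d = prev + (j - 1), u = prev + j, l = c - 1;
      const double s = subscore(ai, b[j - 1], match, mismatch);
      double bm = Mc[d]; unsigned char from = 0;
      if (Xc[d] > bm) { bm = Xc[d]; from = 1; }
      if (Yc[d] > bm) { bm = Yc[d]; from = 2; }
      Mc[c] = bm + s; tbM[c] = from;
      double bestx = Mc[u] - go; unsigned char fx = 0;
      if (Xc[u] - ge > bestx) { bestx = Xc[u] - ge; fx = 1; }
      if (Yc[u] - go > bestx) { bestx = Yc[u] - go; fx = 2; }
      Xc[c] = bestx; tbX[c] = fx;
      double besty = Mc[l] - go; unsigned char fy = 0;
      if (Yc[l] - ge > besty) { besty = Yc[l] - ge; fy = 2; }
      if (Xc[l] - go > besty) { besty = Xc[l] - go; fy = 1; }
      Yc[c] = besty; tbY[c] = fy;
    }
  }
  // free subject suffix: best over last row, layers M and X
  double best = NEG_INF; int bj = 0, layer = 0;
  for (int j = 0; j <= m; ++j) {
    if (Mc[n * W + j] > best) { best = Mc[n * W + j]; bj = j; layer = 0; }
    if (Xc[n * W + j] > best) { best = Xc[n * W + j]; bj = j; layer = 1; }
  }
  // traceback for column stats
  int i = n, j = bj, columns = 0, matches = 0;
  int t_end = bj, t_start = 1;
  while (i > 0) {
    if (layer == 0) {
      unsigned char from = tbM[i * W + j];
      if (a[i - 1] == b[j - 1] && a[i - 1] != 'N') matches++;
      ++columns; --i; --j;
      layer = (i > 0 && j == 0) ? 1 : from;
    } else if (layer == 1) {
      unsigned char from = tbX[i * W + j];
      ++columns; --i;
      layer = from;
      if (i > 0 && j == 0) layer = 1;
    } else {
      unsigned char from = tbY[i * W + j];
      ++columns; --j; layer = from;
    }
  }
  t_start = j + 1;
  return List::create(
    _["score"] = best,
    _["t_start"] = t_start, _["t_end"] = t_end,
    _["columns"] = columns, _["matches"] = matches,
    _["identity_pct"] = columns > 0 ? 100.0 * matches / columns : NA_REAL
  );
}
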