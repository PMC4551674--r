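#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

typedef int64_t i64;

static inline void cross3(const i64 a[3], const i64 b[3], i64 out[3]) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

static inline i64 dot3(const i64 a[3], const i64 b[3]) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

static inline bool zero3(const i64 a[3]) {
  return a[0] == 0 && a[1] == 0 && a[2] == 0;
}

// Exact integer test: do closed segments p1-p2 and p3-p4 share a point
// that is more than a single common endpoint?
static bool segments_intersect_core(const i64 p1[3], const i64 p2[3],
                                    const i64 p3[3], const i64 p4[3]) {
  i64 d1[3], d2[3], r[3];
  for (int k = 0; k < 3; ++k) {
    d1[k] = p2[k] - p1[k];
    d2[k] = p4[k] - p3[k];
    r[k]  = p3[k] - p1[k];
  }
  if (zero3(d1) || zero3(d2)) {
    // degenerate segment: point-on-segment test
    const i64 *pt = zero3(d1) ? p1 : p3;
    const i64 *a  = zero3(d1) ? p3 : p1;
    const i64 *d  = zero3(d1) ? d2 : d1;
    if (zero3(d1) && zero3(d2)) {
      return p1[0] == p3[0] && p1[1] == p3[1] && p1[2] == p3[2];
    }
    i64 w[3] = { pt[0] - a[0], pt[1] - a[1], pt[2] - a[2] };
    i64 c[3]; cross3(w, d, c);
    if (!zero3(c)) return false;
    i64 t = dot3(w, d), den = dot3(d, d);
    return t >= 0 && t <= den; // a point touching counts as intersection
  }
  i64 c[3]; cross3(d1, d2, c);
  if (zero3(c)) {
    // parallel: collinear?
    i64 cr[3]; cross3(r, d1, cr);
    if (!zero3(cr)) return false;
    // collinear: overlap interval on the line of segment 1
    i64 den = dot3(d1, d1);
    i64 t3 = dot3(r, d1);
    i64 r4[3] = { p4[0] - p1[0], p4[1] - p1[1], p4[2] - p1[2] };
    i64 t4 = dot3(r4, d1);
    i64 lo = t3 < t4 ? t3 : t4, hi = t3 < t4 ? t4 : t3;
    if (lo < 0) lo = 0;
    if (hi > den) hi = den;
    // strict interior overlap required: a single shared point is at most
    // a shared endpoint for collinear segments
    return lo < hi;
  }
  // skew or crossing: coplanarity
  if (dot3(r, c) != 0) return false;
  i64 den = dot3(c, c);
  i64 rxd2[3]; cross3(r, d2, rxd2);
  i64 rxd1[3]; cross3(r, d1, rxd1);
  i64 tn = dot3(rxd2, c); // t = tn/den along segment 1
  i64 sn = dot3(rxd1, c); // s = sn/den along segment 2
  if (tn < 0 || tn > den || sn < 0 || sn > den) return false;
  bool t_end = (tn == 0 || tn == den);
  bool s_end = (sn == 0 || sn == den);
  if (t_end && s_end) return false; // single common endpoint only
  return true;
}

// [[Rcpp::export(name = "cppSegmentsIntersect")]]
bool cppSegmentsIntersect(IntegerVector p1, IntegerVector p2,
                          IntegerVector p3, IntegerVector p4) {
  i64 a[3], b[3], c[3], d[3];
  for (int k = 0; k < 3; ++k) {
    a[k] = p1[k]; b[k] = p2[k]; c[k] = p3[k]; d[k] = p4[k];
  }
  return segments_intersect_core(a, b, c, d);
}

// Check all conformation invariants on integer lattice positions.
// edges: columns from, to, length (1-based player ids).
// Returns "" when valid, otherwise a short reason.
static std::string violation_core(const IntegerMatrix &pos,
                                  const IntegerMatrix &edges) {
  int np = pos.nrow();
  // distinct player positions
  for (int i = 0; i < np; ++i)
    for (int j = i + 1; j < np; ++j)
      if (pos(i, 0) == pos(j, 0) && pos(i, 1) == pos(j, 1) &&
          pos(i, 2) == pos(j, 2))
        return "two players occupy the same lattice position";
  int ne = edges.nrow();
  std::vector<std::array<int, 3> > mids;
  std::vector<int> midedge;
  for (int e = 0; e < ne; ++e) {
    int a = edges(e, 0) - 1, b = edges(e, 1) - 1, len = edges(e, 2);
    int dx = pos(b, 0) - pos(a, 0);
    int dy = pos(b, 1) - pos(a, 1);
    int dz = pos(b, 2) - pos(a, 2);
    if (dx % len || dy % len || dz % len)
      return "edge displacement not a multiple of its length";
    int ux = dx / len, uy = dy / len, uz = dz / len;
    int n2 = ux * ux + uy * uy + uz * uz;
    bool fcc = (n2 == 2) &&
      ((ux == 0) + (uy == 0) + (uz == 0) == 1);
    if (!fcc)
      return "edge is not a straight FCC lattice segment";
    if (len == 2) {
      std::array<int, 3> m = { pos(a, 0) + ux, pos(a, 1) + uy,
                               pos(a, 2) + uz };
      mids.push_back(m);
      midedge.push_back(e);
    }
  }
  // midpoint of a length-2 edge vs player positions
  for (size_t m = 0; m < mids.size(); ++m)
    for (int i = 0; i < np; ++i)
      if (mids[m][0] == pos(i, 0) && mids[m][1] == pos(i, 1) &&
          mids[m][2] == pos(i, 2))
        return "edge passes through an occupied lattice position";
  // midpoint vs midpoint
  for (size_t m = 0; m < mids.size(); ++m)
    for (size_t q = m + 1; q < mids.size(); ++q)
      if (mids[m] == mids[q])
        return "two edges cross at a lattice position";
  // exact segment-pair intersection (covers collinear overlaps as well)
  for (int e = 0; e < ne; ++e) {
    int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    i64 p1[3] = { pos(a, 0), pos(a, 1), pos(a, 2) };
    i64 p2[3] = { pos(b, 0), pos(b, 1), pos(b, 2) };
    for (int f = e + 1; f < ne; ++f) {
      int c = edges(f, 0) - 1, d = edges(f, 1) - 1;
      i64 p3[3] = { pos(c, 0), pos(c, 1), pos(c, 2) };
      i64 p4[3] = { pos(d, 0), pos(d, 1), pos(d, 2) };
      if (segments_intersect_core(p1, p2, p3, p4))
        return "two edges of the graph intersect";
    }
  }
  return "";
}

// [[Rcpp::export(name = "cppConformationViolation")]]
String cppConformationViolation(IntegerMatrix pos, IntegerMatrix edges) {
  return violation_core(pos, edges);
}

// For each candidate direction (row of dirs), test whether placing
// `child` at pos[parent] + len*dir and rigidly translating `subtree`
// (1-based ids, child included) yields a valid conformation.
// [[Rcpp::export(name = "cppLegalDirs")]]
LogicalVector cppLegalDirs(IntegerMatrix pos, IntegerMatrix edges,
                           int parent, int child, int len,
                           IntegerVector subtree, IntegerMatrix dirs) {
  int nd = dirs.nrow();
  LogicalVector out(nd);
  IntegerMatrix work(pos.nrow(), 3);
  for (int d = 0; d < nd; ++d) {
    std::copy(pos.begin(), pos.end(), work.begin());
    int nx = pos(parent - 1, 0) + len * dirs(d, 0);
    int ny = pos(parent - 1, 1) + len * dirs(d, 1);
    int nz = pos(parent - 1, 2) + len * dirs(d, 2);
    int tx = nx - pos(child - 1, 0);
    int ty = ny - pos(child - 1, 1);
    int tz = nz - pos(child - 1, 2);
    for (int k = 0; k < subtree.size(); ++k) {
      int id = subtree[k] - 1;
      work(id, 0) += tx; work(id, 1) += ty; work(id, 2) += tz;
    }
    out[d] = violation_core(work, edges).empty();
  }
  return out;
}

// Evaluate one raw (un-normalized) pair score of the given form.
// params row layout: form, A, B, norm, ncomp, w1..w5, mu1..mu5, s1..s5
static double raw_score(double d, const NumericMatrix &params, int row) {
  int form = (int)params(row, 0);
  double A = params(row, 1), B = params(row, 2);
  switch (form) {
  case 1: { // LJ
    double q = B / d, q6 = q * q * q * q * q * q;
    return -A * (q6 * q6 - 2.0 * q6);
  }
  case 2: { // modified LJ
    double q = B / d, q6 = q * q * q * q * q * q;
    double v = -A * (q6 * q6 - 2.0 * q6);
    return v > 0.0 ? v : 0.0;
  }
  case 3: { // Gaussian mixture
    int ncomp = (int)params(row, 4);
    double s = 0.0;
    for (int k = 0; k < ncomp; ++k) {
      double w = params(row, 5 + k);
      double mu = params(row, 10 + k);
      double sg = params(row, 15 + k);
      double z = (d - mu) / sg;
      s += w / (sg * 2.5066282746310002) * std::exp(-0.5 * z * z);
    }
    return s;
  }
  case 4: // inverse square
    return 1.0 / (d * d);
  }
  return 0.0;
}

// Per-player sums of normalized pair scores over non-adjacent players.
// adj: p x p, 1 where the pair is excluded (adjacent or self).
// pairIdx: p x p 1-based row index into params.
// [[Rcpp::export(name = "cppPlayerScores")]]
NumericVector cppPlayerScores(IntegerMatrix pos, double step,
                              IntegerMatrix adj, IntegerMatrix pairIdx,
                              NumericMatrix params) {
  int p = pos.nrow();
  double unit = step / std::sqrt(2.0); // scale so one FCC step = step A
  NumericVector out(p);
  for (int i = 0; i < p; ++i) {
    for (int j = i + 1; j < p; ++j) {
      if (adj(i, j)) continue;
      double dx = (pos(i, 0) - pos(j, 0)) * unit;
      double dy = (pos(i, 1) - pos(j, 1)) * unit;
      double dz = (pos(i, 2) - pos(j, 2)) * unit;
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      int row = pairIdx(i, j) - 1;
      double v = raw_score(d, params, row) / params(row, 3);
      out[i] += v;
      out[j] += v;
    }
  }
  return out;
}

// Counterfactual score trace for player `player`: for each recorded
// turn (row of posHistory, flattened p x 3 column-major: x1..xp,y1..yp,
// z1..zp), re-place `child` at pos[player] + len*dir, translate the
// subtree, and return player's score.
// [[Rcpp::export(name = "cppCounterfactualScores")]]
NumericVector cppCounterfactualScores(IntegerMatrix posHistory,
                                      int player, int child, int len,
                                      IntegerVector subtree,
                                      IntegerVector dir, double step,
                                      IntegerMatrix adj,
                                      IntegerMatrix pairIdx,
                                      NumericMatrix params) {
  int T = posHistory.nrow();
  int p = posHistory.ncol() / 3;
  double unit = step / std::sqrt(2.0);
  NumericVector out(T);
  std::vector<double> x(p), y(p), z(p);
  for (int t = 0; t < T; ++t) {
    for (int i = 0; i < p; ++i) {
      x[i] = posHistory(t, i);
      y[i] = posHistory(t, p + i);
      z[i] = posHistory(t, 2 * p + i);
    }
    double nx = x[player - 1] + len * dir[0];
    double ny = y[player - 1] + len * dir[1];
    double nz = z[player - 1] + len * dir[2];
    double tx = nx - x[child - 1], ty = ny - y[child - 1],
           tz = nz - z[child - 1];
    for (int k = 0; k < subtree.size(); ++k) {
      int id = subtree[k] - 1;
      x[id] += tx; y[id] += ty; z[id] += tz;
    }
    double s = 0.0;
    int i = player - 1;
    for (int j = 0; j < p; ++j) {
      if (j == i || adj(i, j)) continue;
      double dx = (x[i] - x[j]) * unit;
      double dy = (y[i] - y[j]) * unit;
      double dz = (z[i] - z[j]) * unit;
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      int row = pairIdx(i, j) - 1;
      s += raw_score(d, params, row) / params(row, 3);
    }
    out[t] = s;
  }
  return out;
}
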