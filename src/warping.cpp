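#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <limits>

using namespace Rcpp;

// Predecessor codes shared by both DPs. Tie-break order among equal-cost
// predecessors: diagonal, then vertical (advance template index i), then
// horizontal (advance beat index j).
static const std::uint8_t P_NONE = 0, P_DIAG = 1, P_VERT = 2, P_HORZ = 3;

static inline double sqdiff(double a, double b) {
  double d = a - b;
  return d * d;
}

// Classic DTW with step pattern {(1,1),(1,0),(0,1)}, squared local cost,
// reported distance = sqrt(accumulated cost). Returns the optimal path as a
// 2-column 0-based index matrix (template index i, query index j).
// [[Rcpp::export(name = ".dtw_cpp")]]
List dtw_cpp(NumericVector x, NumericVector y) {
  const int m = x.size(), n = y.size();
  if (m < 1 || n < 1) stop("dtw: empty input");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> D((size_t)m * n, INF);
  std::vector<std::uint8_t> pred((size_t)m * n, P_NONE);

  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) {
      double c = sqdiff(x[i], y[j]);
      size_t id = (size_t)i * n + j;
      if (i == 0 && j == 0) {
        D[id] = c;
        continue;
      }
      double best = INF;
      std::uint8_t pb = P_NONE;
      // strict < with diag checked first encodes the diag > vert > horz
      // tie preference
      if (i > 0 && j > 0 && D[id - n - 1] < best) { best = D[id - n - 1]; pb = P_DIAG; }
      if (i > 0 && D[id - n] < best)              { best = D[id - n];     pb = P_VERT; }
      if (j > 0 && D[id - 1] < best)              { best = D[id - 1];     pb = P_HORZ; }
      D[id] = best + c;
      pred[id] = pb;
    }
  }

  // backtrack
  std::vector<int> pi, pj;
  int i = m - 1, j = n - 1;
  while (true) {
    pi.push_back(i);
    pj.push_back(j);
    std::uint8_t p = pred[(size_t)i * n + j];
    if (p == P_NONE) break;
    if (p == P_DIAG) { --i; --j; }
    else if (p == P_VERT) { --i; }
    else { --j; }
  }
  const int L = (int)pi.size();
  IntegerMatrix path(L, 2);
  for (int s = 0; s < L; ++s) {
    path(s, 0) = pi[L - 1 - s];
    path(s, 1) = pj[L - 1 - s];
  }
  return List::create(_["distance"] = std::sqrt(D[(size_t)m * n - 1]),
                      _["path"] = path);
}

// DTW under limited warping path length: minimize the same accumulated cost
// over monotone contiguous paths whose number of index pairs is <= max_len.
// DP over layers l = path length; state cost kept for two layers only,
// predecessor choices stored per (l, i, j) as one byte for backtracking.
// [[Rcpp::export(name = ".ldtw_cpp")]]
List ldtw_cpp(NumericVector x, NumericVector y, int max_len) {
  const int m = x.size(), n = y.size();
  if (m < 1 || n < 1) stop("ldtw: empty input");
  const int lmin = std::max(m, n), lmax_all = m + n - 1;
  if (max_len < lmin)
    stop("ldtw: max_length (%d) below minimum feasible path length (%d)",
         max_len, lmin);
  const int L = std::min(max_len, lmax_all);
  const double INF = std::numeric_limits<double>::infinity();
  const size_t mn = (size_t)m * n;

  std::vector<double> cur(mn, INF), nxt(mn, INF);
  std::vector<std::uint8_t> pred((size_t)L * mn, P_NONE);

  // layer l = 1 (one pair): only (0,0)
  cur[0] = sqdiff(x[0], y[0]);
  double bestEnd = (m == 1 && n == 1) ? cur[0] : INF;
  int bestLen = (m == 1 && n == 1) ? 1 : 0;

  for (int l = 2; l <= L; ++l) {
    std::fill(nxt.begin(), nxt.end(), INF);
    std::uint8_t *pl = &pred[(size_t)(l - 1) * mn];
    // a state (i,j) is reachable with exactly l pairs iff
    // max(i,j)+1 <= l <= i+j+1
    const int imax = std::min(m - 1, l - 1);
    for (int i = 0; i <= imax; ++i) {
      const double xi = x[i];
      const size_t row = (size_t)i * n;
      int jlo = std::max(l - 1 - i, i == 0 ? 1 : 0);
      int jhi = std::min(n - 1, l - 1);
      for (int j = jlo; j <= jhi; ++j) {
        size_t id = row + j;
        double best = INF;
        std::uint8_t pb = P_NONE;
        if (i > 0 && j > 0 && cur[id - n - 1] < best) { best = cur[id - n - 1]; pb = P_DIAG; }
        if (i > 0 && cur[id - n] < best)              { best = cur[id - n];     pb = P_VERT; }
        if (j > 0 && cur[id - 1] < best)              { best = cur[id - 1];     pb = P_HORZ; }
        if (pb == P_NONE) continue;
        nxt[id] = best + sqdiff(xi, y[j]);
        pl[id] = pb;
      }
      // (0,0) never revisited after layer 1 (monotone strict growth of i+j)
    }
    std::swap(cur, nxt);
    double end = cur[mn - 1];
    if (end < bestEnd) { bestEnd = end; bestLen = l; }
  }

  if (!(bestEnd < INF)) stop("ldtw: no feasible path (internal error)");

  // backtrack from (m-1, n-1) at layer bestLen
  std::vector<int> pi, pj;
  int i = m - 1, j = n - 1;
  for (int l = bestLen; l >= 1; --l) {
    pi.push_back(i);
    pj.push_back(j);
    if (l == 1) break;
    std::uint8_t p = pred[(size_t)(l - 1) * mn + (size_t)i * n + j];
    if (p == P_DIAG) { --i; --j; }
    else if (p == P_VERT) { --i; }
    else if (p == P_HORZ) { --j; }
    else stop("ldtw: backtrack failed (internal error)");
  }
  const int K = (int)pi.size();
  IntegerMatrix path(K, 2);
  for (int s = 0; s < K; ++s) {
    path(s, 0) = pi[K - 1 - s];
    path(s, 1) = pj[K - 1 - s];
  }
  return List::create(_["distance"] = std::sqrt(bestEnd),
                      _["path"] = path);
}
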