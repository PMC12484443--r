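#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Normalized Tobler hiking factor; must stay in lock-step with the R-side
// slope_factor() so walking costs agree between the two.
static inline double tobler(double s) {
  return std::exp(-3.5 * (std::fabs(s + 0.05) - 0.05));
}

// Multi-source Dijkstra travel-time accumulation over a gridded speed
// surface. speed: m/s, 0 = barrier. walking: slope factor applies.
// dem: elevation (m), may be all zero for flat terrain. sources: 0-based
// linear cell indices (column-major, R layout). connectivity: 8 or 16
// (queen moves, plus knight moves for 16). Returns seconds per cell,
// +Inf where unreachable.
// [[Rcpp::export]]
NumericMatrix grid_dijkstra(const NumericMatrix& speed,
                            const LogicalMatrix& walking,
                            const NumericMatrix& dem,
                            const IntegerVector& sources,
                            double cell_size,
                            int connectivity) {
  const int nr = speed.nrow(), nc = speed.ncol();
  const double inf = std::numeric_limits<double>::infinity();
  if (connectivity != 8 && connectivity != 16)
    stop("connectivity must be 8 or 16");

  std::vector<int> dr = {-1, -1, -1, 0, 0, 1, 1, 1};
  std::vector<int> dc = {-1, 0, 1, -1, 1, -1, 0, 1};
  if (connectivity == 16) {
    int kr[] = {-2, -2, -1, -1, 1, 1, 2, 2};
    int kc[] = {-1, 1, -2, 2, -2, 2, -1, 1};
    dr.insert(dr.end(), kr, kr + 8);
    dc.insert(dc.end(), kc, kc + 8);
  }
  const size_t nmove = dr.size();
  std::vector<double> dist_move(nmove);
  for (size_t m = 0; m < nmove; ++m)
    dist_move[m] = cell_size * std::sqrt(double(dr[m] * dr[m] + dc[m] * dc[m]));

  std::vector<double> tt(size_t(nr) * nc, inf);
  typedef std::pair<double, int> QN;
  std::priority_queue<QN, std::vector<QN>, std::greater<QN> > pq;

  for (int i = 0; i < sources.size(); ++i) {
    int s = sources[i];
    if (s < 0 || s >= nr * nc) stop("source index out of range");
    if (tt[s] > 0.0) { tt[s] = 0.0; pq.push(QN(0.0, s)); }
  }

  while (!pq.empty()) {
    QN top = pq.top(); pq.pop();
    double d = top.first;
    int u = top.second;
    if (d > tt[u]) continue;
    int ur = u % nr, uc = u / nr;
    double vu_base = speed[u];
    if (vu_base <= 0.0) continue;
    for (size_t m = 0; m < nmove; ++m) {
      int vr = ur + dr[m], vc = uc + dc[m];
      if (vr < 0 || vr >= nr || vc < 0 || vc >= nc) continue;
      int v = vc * nr + vr;
      double vv_base = speed[v];
      if (vv_base <= 0.0) continue;
      double dd = dist_move[m];
      double s = (dem[v] - dem[u]) / dd;  // signed, in direction of travel
      double vu = walking[u] ? vu_base * tobler(s) : vu_base;
      double vv = walking[v] ? vv_base * tobler(s) : vv_base;
      if (vu <= 0.0 || vv <= 0.0) continue;
      double w = dd * (0.5 / vu + 0.5 / vv);
      double nd = d + w;
      if (nd < tt[v]) { tt[v] = nd; pq.push(QN(nd, v)); }
    }
  }

  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr * nc; ++i) out[i] = tt[i];
  return out;
}
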