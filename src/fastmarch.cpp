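// Fast-marching solver for the Eikonal equation ||grad U|| = p on a
// 3D grid with anisotropic voxel spacing, first-order upwind quadratic
// update, 6-connected neighborhood, binary heap with lazy re-insertion.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// Solve sum_i ((u - a_i)/h_i)^2 = c^2 over the upwind subset of axes.
// a[i] may be INF (axis excluded); at least one must be finite.
static double upwind_solve(const double a[3], const double h[3], double c) {
  // collect finite (a, w = 1/h^2) pairs sorted by a ascending
  int ord[3], n = 0;
  for (int i = 0; i < 3; ++i) if (R_finite(a[i])) ord[n++] = i;
  for (int i = 1; i < n; ++i)
    for (int j = i; j > 0 && a[ord[j]] < a[ord[j - 1]]; --j)
      std::swap(ord[j], ord[j - 1]);
  double u = INF;
  for (int m = 1; m <= n; ++m) {
    double A = 0, B = 0, C = -c * c;
    for (int j = 0; j < m; ++j) {
      double w = 1.0 / (h[ord[j]] * h[ord[j]]);
      A += w;
      B -= 2.0 * w * a[ord[j]];
      C += w * a[ord[j]] * a[ord[j]];
    }
    double disc = B * B - 4.0 * A * C;
    if (disc < 0) break;               // inconsistent: keep previous m
    double cand = (-B + std::sqrt(disc)) / (2.0 * A);
    if (cand >= a[ord[m - 1]]) u = cand; else break;
  }
  return u;
}

// [[Rcpp::export(name = ".fm_local_update")]]
double fm_local_update(NumericVector neighbor_lo, NumericVector neighbor_hi,
                       double cost, NumericVector spacing) {
  if (cost <= 0) stop("cost must be positive");
  double a[3], h[3];
  bool any_finite = false;
  for (int i = 0; i < 3; ++i) {
    a[i] = std::min(neighbor_lo[i], neighbor_hi[i]);
    h[i] = spacing[i];
    if (R_finite(a[i])) any_finite = true;
  }
  if (!any_finite) stop("at least one neighbor value must be finite");
  return upwind_solve(a, h, cost);
}

struct HeapEntry {
  double u;
  int idx;
  long order;                          // insertion order breaks ties
  bool operator>(const HeapEntry& o) const {
    if (u != o.u) return u > o.u;
    return order > o.order;
  }
};

// [[Rcpp::export(name = ".fm_solve")]]
List fm_solve(NumericVector cost, IntegerVector dims, NumericVector spacing,
              IntegerVector source, IntegerVector stops_flat, int n_stops,
              double init_radius) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  const double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  NumericVector U(n, INF);
  LogicalVector alive(n, false);
  std::vector<char> state(n, 0);       // 0 FAR, 1 TRIAL, 2 ALIVE
  std::vector<char> fixed(n, 0);       // Dirichlet (source-ball) voxels

  std::vector<int> stop_idx(n_stops);
  std::vector<char> stop_done(n_stops, 0);
  for (int s = 0; s < n_stops; ++s) {
    int i = stops_flat[3 * s], j = stops_flat[3 * s + 1],
        k = stops_flat[3 * s + 2];
    stop_idx[s] = i + nx * (j + (long)ny * k);
  }
  int stops_left = n_stops;

  auto lin = [&](int i, int j, int k) { return i + nx * (j + (long)ny * k); };

  std::priority_queue<HeapEntry, std::vector<HeapEntry>,
                      std::greater<HeapEntry> > heap;
  long order = 0;

  int si = source[0], sj = source[1], sk = source[2];
  if (si < 0 || si >= nx || sj < 0 || sj >= ny || sk < 0 || sk >= nz)
    stop("source voxel out of bounds");
  int s0 = lin(si, sj, sk);
  U[s0] = 0.0;
  state[s0] = 1;
  fixed[s0] = 1;
  heap.push(HeapEntry{0.0, s0, order++});

  // exact-ball initialization: voxels within init_radius (mm) of the
  // source get the trapezoid line-integral value as Dirichlet data,
  // removing the large point-source discretization error of the
  // first-order scheme
  if (init_radius > 0) {
    double c0 = cost[s0];
    int ri = (int)std::ceil(init_radius / hx);
    int rj = (int)std::ceil(init_radius / hy);
    int rk = (int)std::ceil(init_radius / hz);
    for (int k = std::max(0, sk - rk); k <= std::min(nz - 1, sk + rk); ++k)
      for (int j = std::max(0, sj - rj); j <= std::min(ny - 1, sj + rj); ++j)
        for (int i = std::max(0, si - ri); i <= std::min(nx - 1, si + ri);
             ++i) {
          double dx = (i - si) * hx, dy = (j - sj) * hy, dz = (k - sk) * hz;
          double d = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (d > init_radius || d == 0) continue;
          int id = lin(i, j, k);
          U[id] = d * 0.5 * (c0 + cost[id]);
          state[id] = 1;
          fixed[id] = 1;
          heap.push(HeapEntry{U[id], id, order++});
        }
  }

  const int di[6] = {-1, 1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, -1, 1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, -1, 1};

  while (!heap.empty() && (n_stops == 0 || stops_left > 0)) {
    HeapEntry top = heap.top();
    heap.pop();
    int cur = top.idx;
    if (state[cur] == 2) continue;     // stale lazy entry
    state[cur] = 2;
    alive[cur] = true;
    for (int s = 0; s < n_stops; ++s)
      if (!stop_done[s] && stop_idx[s] == cur) { stop_done[s] = 1; --stops_left; }

    int ci = cur % nx, cj = (cur / nx) % ny, ck = cur / (nx * ny);
    for (int q = 0; q < 6; ++q) {
      int i = ci + di[q], j = cj + dj[q], k = ck + dk[q];
      if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) continue;
      long nb = lin(i, j, k);
      if (state[nb] == 2 || fixed[nb]) continue;
      double c = cost[nb];
      if (!(c > 0)) stop("cost must be strictly positive everywhere");
      // gather alive neighbor minima per axis
      double a[3] = {INF, INF, INF};
      double h[3] = {hx, hy, hz};
      if (i > 0 && state[lin(i - 1, j, k)] == 2)
        a[0] = U[lin(i - 1, j, k)];
      if (i < nx - 1 && state[lin(i + 1, j, k)] == 2)
        a[0] = std::min(a[0], U[lin(i + 1, j, k)]);
      if (j > 0 && state[lin(i, j - 1, k)] == 2)
        a[1] = U[lin(i, j - 1, k)];
      if (j < ny - 1 && state[lin(i, j + 1, k)] == 2)
        a[1] = std::min(a[1], U[lin(i, j + 1, k)]);
      if (k > 0 && state[lin(i, j, k - 1)] == 2)
        a[2] = U[lin(i, j, k - 1)];
      if (k < nz - 1 && state[lin(i, j, k + 1)] == 2)
        a[2] = std::min(a[2], U[lin(i, j, k + 1)]);
      double cand = upwind_solve(a, h, c);
      if (cand < U[nb]) {
        U[nb] = cand;
        state[nb] = 1;
        heap.push(HeapEntry{cand, (int)nb, order++});
      }
    }
  }

  // U is reported only where frozen
  for (long i = 0; i < n; ++i) if (!alive[i]) U[i] = INF;
  U[s0] = 0.0;
  alive[s0] = true;

  LogicalVector reached(n_stops);
  for (int s = 0; s < n_stops; ++s) reached[s] = stop_done[s] != 0;
  return List::create(_["U"] = U, _["alive"] = alive,
                      _["reached"] = reached);
}
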