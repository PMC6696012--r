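#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

// Pack a 3D integer cell into one 64-bit key (21 bits per axis, offset).
static inline int64_t cell_key(int ix, int iy, int iz) {
  const int64_t B = 1 << 20;
  return (((int64_t)(ix + B)) << 42) | (((int64_t)(iy + B)) << 21) |
         ((int64_t)(iz + B));
}

// Nearest reference point within `radius` for every query point, via a
// uniform grid hash with cell size = radius (27-cell search).
// Returns idx (1-based, 0 when none within radius) and dist.
// [[Rcpp::export]]
List cpp_nn1(NumericMatrix query, NumericMatrix ref, double radius) {
  const int nq = query.nrow(), nr = ref.nrow();
  std::unordered_map<int64_t, std::vector<int> > grid;
  grid.reserve((size_t)nr * 2);
  const double cs = radius;
  for (int i = 0; i < nr; ++i) {
    int ix = (int)std::floor(ref(i, 0) / cs);
    int iy = (int)std::floor(ref(i, 1) / cs);
    int iz = (int)std::floor(ref(i, 2) / cs);
    grid[cell_key(ix, iy, iz)].push_back(i);
  }
  IntegerVector idx(nq);
  NumericVector dist(nq);
  const double r2max = radius * radius;
  for (int q = 0; q < nq; ++q) {
    const double x = query(q, 0), y = query(q, 1), z = query(q, 2);
    const int ix = (int)std::floor(x / cs);
    const int iy = (int)std::floor(y / cs);
    const int iz = (int)std::floor(z / cs);
    double best = r2max;
    int besti = -1;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = grid.find(cell_key(ix + dx, iy + dy, iz + dz));
          if (it == grid.end()) continue;
          for (int i : it->second) {
            const double ddx = ref(i, 0) - x, ddy = ref(i, 1) - y,
                         ddz = ref(i, 2) - z;
            const double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
            if (d2 <= best) { best = d2; besti = i; }
          }
        }
    idx[q] = besti + 1;
    dist[q] = besti >= 0 ? std::sqrt(best) : NA_REAL;
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// Mean distance to the k nearest neighbors (excluding the point itself),
// brute force with a per-point bounded heap; fine at the cloud sizes this
// pipeline produces.
// [[Rcpp::export]]
NumericVector cpp_knn_mean_dist(NumericMatrix pts, int k) {
  const int n = pts.nrow();
  NumericVector out(n);
  std::vector<double> d2(n);
  for (int i = 0; i < n; ++i) {
    const double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    for (int j = 0; j < n; ++j) {
      const double dx = pts(j, 0) - x, dy = pts(j, 1) - y,
                   dz = pts(j, 2) - z;
      d2[j] = dx * dx + dy * dy + dz * dz;
    }
    d2[i] = std::numeric_limits<double>::infinity();
    const int kk = std::min(k, n - 1);
    std::vector<double> tmp(d2);
    std::nth_element(tmp.begin(), tmp.begin() + kk - 1, tmp.end());
    double s = 0.0;
    for (int j = 0; j < kk; ++j) s += std::sqrt(tmp[j]);
    out[i] = s / kk;
  }
  return out;
}
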