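#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// Grid-indexed DBSCAN over 3D points. Cells have side eps so all neighbours
// of a point lie in its 3x3x3 cell block; this keeps the expansion near
// O(N * k) for MLS-scale clouds instead of O(N^2).

namespace {

inline int64_t cell_key(int ix, int iy, int iz) {
  // 21 bits per axis, offset to stay positive; local scenes are far below
  // the ~2e6-cell-per-axis limit this implies.
  const int64_t off = 1 << 20;
  return (((int64_t)(ix + off)) << 42) | (((int64_t)(iy + off)) << 21) |
         (int64_t)(iz + off);
}

struct Grid {
  std::unordered_map<int64_t, std::vector<int>> cells;
  double eps;
  const double *x, *y, *z;
  int n;

  Grid(const NumericVector& xs, const NumericVector& ys,
       const NumericVector& zs, double eps_)
      : eps(eps_), x(xs.begin()), y(ys.begin()), z(zs.begin()), n(xs.size()) {
    cells.reserve(n);
    for (int i = 0; i < n; ++i) {
      cells[key_of(i)].push_back(i);
    }
  }

  inline int64_t key_of(int i) const {
    return cell_key((int)std::floor(x[i] / eps), (int)std::floor(y[i] / eps),
                    (int)std::floor(z[i] / eps));
  }

  void neighbours(int i, std::vector<int>& out) const {
    out.clear();
    const double e2 = eps * eps;
    const int ix = (int)std::floor(x[i] / eps);
    const int iy = (int)std::floor(y[i] / eps);
    const int iz = (int)std::floor(z[i] / eps);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = cells.find(cell_key(ix + dx, iy + dy, iz + dz));
          if (it == cells.end()) continue;
          for (int j : it->second) {
            const double ddx = x[i] - x[j], ddy = y[i] - y[j],
                         ddz = z[i] - z[j];
            if (ddx * ddx + ddy * ddy + ddz * ddz <= e2) out.push_back(j);
          }
        }
  }
};

}  // namespace

// [[Rcpp::export(name = ".dbscan_impl")]]
IntegerVector dbscan_impl(NumericVector x, NumericVector y, NumericVector z,
                          double eps, int min_pts) {
  const int n = x.size();
  IntegerVector labels(n, 0);  // 0 = noise/unvisited, clusters 1..k
  if (n == 0) return labels;

  Grid grid(x, y, z, eps);
  std::vector<char> visited(n, 0);
  std::vector<int> nb, seeds, nb2;
  int next_cluster = 0;

  for (int i = 0; i < n; ++i) {
    if (visited[i]) continue;
    visited[i] = 1;
    grid.neighbours(i, nb);
    if ((int)nb.size() < min_pts) continue;  // stays noise unless reached later
    ++next_cluster;
    labels[i] = next_cluster;
    seeds.assign(nb.begin(), nb.end());
    for (size_t s = 0; s < seeds.size(); ++s) {
      const int j = seeds[s];
      if (labels[j] == 0) labels[j] = next_cluster;  // border or new core
      if (visited[j]) continue;
      visited[j] = 1;
      grid.neighbours(j, nb2);
      if ((int)nb2.size() >= min_pts) {
        for (int q : nb2)
          if (!visited[q] || labels[q] == 0) seeds.push_back(q);
      }
    }
  }
  return labels;
}
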