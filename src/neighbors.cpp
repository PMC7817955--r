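// Grid-hash fixed-radius neighbour routines shared by the point-cloud
// filters, the cluster tracker and the stem-slab cleaner. All distances are
// 3-D Euclidean (pass a zero column for planar queries). Cells have edge
// equal to the query radius so only the 27 surrounding cells are scanned.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
#include <queue>

using namespace Rcpp;

typedef std::unordered_map<int64_t, std::vector<int> > CellMap;

static inline int64_t cell_key(int ix, int iy, int iz) {
  // pack three 21-bit signed cell indices into one 64-bit key
  const int64_t B = 1 << 20;
  return (((int64_t)(ix + B)) << 42) | (((int64_t)(iy + B)) << 21) |
         ((int64_t)(iz + B));
}

static inline int cell_of(double v, double h) {
  return (int)std::floor(v / h);
}

static CellMap build_grid(const NumericMatrix& X, double h) {
  CellMap grid;
  grid.reserve((size_t)X.nrow());
  for (int i = 0; i < X.nrow(); ++i) {
    grid[cell_key(cell_of(X(i, 0), h), cell_of(X(i, 1), h),
                  cell_of(X(i, 2), h))].push_back(i);
  }
  return grid;
}

static inline double dist2(const NumericMatrix& A, int i,
                           const NumericMatrix& B, int j) {
  double dx = A(i, 0) - B(j, 0);
  double dy = A(i, 1) - B(j, 1);
  double dz = A(i, 2) - B(j, 2);
  return dx * dx + dy * dy + dz * dz;
}

// [[Rcpp::export]]
IntegerVector cpp_count_within(NumericMatrix X, double radius) {
  const double r2 = radius * radius;
  CellMap grid = build_grid(X, radius);
  IntegerVector out(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) {
    int cx = cell_of(X(i, 0), radius), cy = cell_of(X(i, 1), radius),
        cz = cell_of(X(i, 2), radius);
    int n = 0;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          CellMap::const_iterator it =
              grid.find(cell_key(cx + dx, cy + dy, cz + dz));
          if (it == grid.end()) continue;
          const std::vector<int>& ids = it->second;
          for (size_t k = 0; k < ids.size(); ++k) {
            int j = ids[k];
            if (j != i && dist2(X, i, X, j) <= r2) ++n;
          }
        }
    out[i] = n;
  }
  return out;
}

// Greedy sequential thinning: keep a point iff it is at least d_min from
// every previously kept point, scanning in stored row order.
// [[Rcpp::export]]
LogicalVector cpp_greedy_subsample(NumericMatrix X, double d_min) {
  const double r2 = d_min * d_min;
  CellMap kept;
  LogicalVector keep(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) {
    int cx = cell_of(X(i, 0), d_min), cy = cell_of(X(i, 1), d_min),
        cz = cell_of(X(i, 2), d_min);
    bool ok = true;
    for (int dx = -1; dx <= 1 && ok; ++dx)
      for (int dy = -1; dy <= 1 && ok; ++dy)
        for (int dz = -1; dz <= 1 && ok; ++dz) {
          CellMap::const_iterator it =
              kept.find(cell_key(cx + dx, cy + dy, cz + dz));
          if (it == kept.end()) continue;
          const std::vector<int>& ids = it->second;
          for (size_t k = 0; k < ids.size(); ++k) {
            if (dist2(X, i, X, ids[k]) < r2) { ok = false; break; }
          }
        }
    keep[i] = ok;
    if (ok) kept[cell_key(cx, cy, cz)].push_back(i);
  }
  return keep;
}

// Nearest neighbour in `ref` for each row of `query`, capped at max_dist.
// Returns 1-based indices (0 when no neighbour within the cap) and distances
// (NA when none).
// [[Rcpp::export]]
List cpp_nn1(NumericMatrix query, NumericMatrix ref, double max_dist) {
  const double r2 = max_dist * max_dist;
  CellMap grid = build_grid(ref, max_dist);
  IntegerVector idx(query.nrow());
  NumericVector dist(query.nrow());
  for (int i = 0; i < query.nrow(); ++i) {
    int cx = cell_of(query(i, 0), max_dist),
        cy = cell_of(query(i, 1), max_dist),
        cz = cell_of(query(i, 2), max_dist);
    double best = r2;
    int best_j = -1;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          CellMap::const_iterator it =
              grid.find(cell_key(cx + dx, cy + dy, cz + dz));
          if (it == grid.end()) continue;
          const std::vector<int>& ids = it->second;
          for (size_t k = 0; k < ids.size(); ++k) {
            double d2 = dist2(query, i, ref, ids[k]);
            if (d2 <= best) { best = d2; best_j = ids[k]; }
          }
        }
    if (best_j < 0) {
      idx[i] = 0;
      dist[i] = NA_REAL;
    } else {
      idx[i] = best_j + 1;
      dist[i] = std::sqrt(best);
    }
  }
  return List::create(Named("index") = idx, Named("distance") = dist);
}

// Single-linkage connected components at the given linkage radius
// (breadth-first search over the grid index). Returns 1-based component
// labels, numbered by order of first point encountered.
// [[Rcpp::export]]
IntegerVector cpp_cluster_components(NumericMatrix X, double radius) {
  const double r2 = radius * radius;
  CellMap grid = build_grid(X, radius);
  IntegerVector label(X.nrow(), 0);
  int comp = 0;
  std::queue<int> q;
  for (int s = 0; s < X.nrow(); ++s) {
    if (label[s] != 0) continue;
    label[s] = ++comp;
    q.push(s);
    while (!q.empty()) {
      int i = q.front();
      q.pop();
      int cx = cell_of(X(i, 0), radius), cy = cell_of(X(i, 1), radius),
          cz = cell_of(X(i, 2), radius);
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            CellMap::const_iterator it =
                grid.find(cell_key(cx + dx, cy + dy, cz + dz));
            if (it == grid.end()) continue;
            const std::vector<int>& ids = it->second;
            for (size_t k = 0; k < ids.size(); ++k) {
              int j = ids[k];
              if (label[j] == 0 && dist2(X, i, X, j) <= r2) {
                label[j] = comp;
                q.push(j);
              }
            }
          }
    }
  }
  return label;
}
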