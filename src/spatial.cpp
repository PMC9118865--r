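#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Uniform hash grid over 3D points. Cell indices are packed into a 64-bit key
// (21 bits per axis after offsetting), which comfortably covers plot-scale
// scenes at centimetre cell sizes.

static inline int64_t pack_key(int64_t ix, int64_t iy, int64_t iz) {
  const int64_t B = 1 << 20;  // offset so indices are non-negative
  return ((ix + B) << 42) | ((iy + B) << 21) | (iz + B);
}

struct Grid {
  double h;
  std::unordered_map<int64_t, std::vector<int> > cells;

  Grid(const NumericMatrix& pts, double h_) : h(h_) {
    int n = pts.nrow();
    cells.reserve(n / 2 + 8);
    for (int i = 0; i < n; ++i) {
      int64_t ix = (int64_t)std::floor(pts(i, 0) / h);
      int64_t iy = (int64_t)std::floor(pts(i, 1) / h);
      int64_t iz = (int64_t)std::floor(pts(i, 2) / h);
      cells[pack_key(ix, iy, iz)].push_back(i);
    }
  }
};

// Mean distance from each point to its k nearest neighbours (self excluded).
// [[Rcpp::export]]
NumericVector cpp_knn_mean_dist(NumericMatrix pts, int k) {
  int n = pts.nrow();
  NumericVector out(n);
  if (n == 0) return out;

  // cell size aimed at ~k points per 3x3x3 neighbourhood; fall back to a
  // bbox-derived scale when points are (nearly) coincident
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf,
         zmin = R_PosInf, zmax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    xmin = std::min(xmin, pts(i, 0)); xmax = std::max(xmax, pts(i, 0));
    ymin = std::min(ymin, pts(i, 1)); ymax = std::max(ymax, pts(i, 1));
    zmin = std::min(zmin, pts(i, 2)); zmax = std::max(zmax, pts(i, 2));
  }
  double dx = std::max(xmax - xmin, 1e-9), dy = std::max(ymax - ymin, 1e-9),
         dz = std::max(zmax - zmin, 1e-9);
  double diam = std::sqrt(dx * dx + dy * dy + dz * dz);

  // cell size from the sampled nearest-neighbour spacing: TLS clouds are
  // surface-distributed, so the k-NN radius grows like spacing * sqrt(k)
  int n_samp = std::min(n, 200);
  int stride = std::max(1, n / n_samp);
  double spacing_acc = 0.0;
  int n_acc = 0;
  for (int i = 0; i < n; i += stride) {
    double best_d2 = R_PosInf;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double ddx = pts(j, 0) - pts(i, 0), ddy = pts(j, 1) - pts(i, 1),
             ddz = pts(j, 2) - pts(i, 2);
      double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
      if (d2 < best_d2) best_d2 = d2;
    }
    if (R_finite(best_d2)) { spacing_acc += std::sqrt(best_d2); ++n_acc; }
  }
  double spacing = n_acc > 0 ? spacing_acc / n_acc : 0.0;
  double h = spacing * std::sqrt((double)k) * 0.8;
  if (!(h > 0) || h > diam) h = diam / 4.0;
  if (!(h > 0)) h = 1.0;

  Grid grid(pts, h);

  for (int i = 0; i < n; ++i) {
    double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    int64_t ix = (int64_t)std::floor(px / h);
    int64_t iy = (int64_t)std::floor(py / h);
    int64_t iz = (int64_t)std::floor(pz / h);

    std::priority_queue<double> best;  // max-heap of the k smallest sq dists
    for (int s = 0;; ++s) {
      // cells on the Chebyshev shell at distance s
      for (int64_t ax = ix - s; ax <= ix + s; ++ax) {
        for (int64_t ay = iy - s; ay <= iy + s; ++ay) {
          for (int64_t az = iz - s; az <= iz + s; ++az) {
            if (std::max(std::llabs(ax - ix),
                         std::max(std::llabs(ay - iy), std::llabs(az - iz))) != s)
              continue;
            auto it = grid.cells.find(pack_key(ax, ay, az));
            if (it == grid.cells.end()) continue;
            for (int j : it->second) {
              if (j == i) continue;
              double ddx = pts(j, 0) - px, ddy = pts(j, 1) - py,
                     ddz = pts(j, 2) - pz;
              double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
              if ((int)best.size() < k) best.push(d2);
              else if (d2 < best.top()) { best.pop(); best.push(d2); }
            }
          }
        }
      }
      // shells 0..s are guaranteed to contain every point within s*h
      double covered = (double)s * h;
      if ((int)best.size() >= k && std::sqrt(best.top()) <= covered) break;
      if ((double)s * h > diam + h) break;  // exhausted the cloud
    }
    double acc = 0.0;
    int m = (int)best.size();
    while (!best.empty()) { acc += std::sqrt(best.top()); best.pop(); }
    out[i] = m > 0 ? acc / m : R_PosInf;
  }
  return out;
}

// Connected components of the graph linking points at distance <= tol.
// Returns 1-based component labels.
// [[Rcpp::export]]
IntegerVector cpp_cluster_labels(NumericMatrix pts, double tol) {
  int n = pts.nrow();
  IntegerVector labels(n, 0);
  if (n == 0) return labels;

  Grid grid(pts, tol);
  double tol2 = tol * tol;
  std::vector<int> stack;
  int comp = 0;

  for (int start = 0; start < n; ++start) {
    if (labels[start] != 0) continue;
    ++comp;
    labels[start] = comp;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      int i = stack.back();
      stack.pop_back();
      double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
      int64_t ix = (int64_t)std::floor(px / tol);
      int64_t iy = (int64_t)std::floor(py / tol);
      int64_t iz = (int64_t)std::floor(pz / tol);
      for (int64_t ax = ix - 1; ax <= ix + 1; ++ax) {
        for (int64_t ay = iy - 1; ay <= iy + 1; ++ay) {
          for (int64_t az = iz - 1; az <= iz + 1; ++az) {
            auto it = grid.cells.find(pack_key(ax, ay, az));
            if (it == grid.cells.end()) continue;
            for (int j : it->second) {
              if (labels[j] != 0) continue;
              double ddx = pts(j, 0) - px, ddy = pts(j, 1) - py,
                     ddz = pts(j, 2) - pz;
              if (ddx * ddx + ddy * ddy + ddz * ddz <= tol2) {
                labels[j] = comp;
                stack.push_back(j);
              }
            }
          }
        }
      }
    }
  }
  return labels;
}

// Indices (1-based) of points within `radius` of each query row, as a list.
// Used by moving-least-squares smoothing.
// [[Rcpp::export]]
List cpp_radius_neighbors(NumericMatrix pts, double radius) {
  int n = pts.nrow();
  List out(n);
  if (n == 0) return out;
  Grid grid(pts, radius);
  double r2 = radius * radius;
  std::vector<int> buf;
  for (int i = 0; i < n; ++i) {
    buf.clear();
    double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    int64_t ix = (int64_t)std::floor(px / radius);
    int64_t iy = (int64_t)std::floor(py / radius);
    int64_t iz = (int64_t)std::floor(pz / radius);
    for (int64_t ax = ix - 1; ax <= ix + 1; ++ax)
      for (int64_t ay = iy - 1; ay <= iy + 1; ++ay)
        for (int64_t az = iz - 1; az <= iz + 1; ++az) {
          auto it = grid.cells.find(pack_key(ax, ay, az));
          if (it == grid.cells.end()) continue;
          for (int j : it->second) {
            double ddx = pts(j, 0) - px, ddy = pts(j, 1) - py,
                   ddz = pts(j, 2) - pz;
            if (ddx * ddx + ddy * ddy + ddz * ddz <= r2)
              buf.push_back(j + 1);
          }
        }
    out[i] = IntegerVector(buf.begin(), buf.end());
  }
  return out;
}
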