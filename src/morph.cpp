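#include <Rcpp.h>
#include <cmath>
#include <queue>
using namespace Rcpp;

// Centres of the voxel faces where mask A and mask B are 6-adjacent, in
// continuous 0-based voxel coordinates (face centres sit half way between
// the two voxel centres). These faces define the liver-lung interface
// surface used for margin exclusion.
// [[Rcpp::export]]
NumericMatrix interface_face_centres(IntegerVector a, IntegerVector b,
                                     IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> fx, fy, fz;
  const int step[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int lin = i + nx * (j + ny * k);
        if (!a[lin] && !b[lin]) continue;
        for (int d = 0; d < 3; ++d) {
          const int i2 = i + step[d][0], j2 = j + step[d][1],
                    k2 = k + step[d][2];
          if (i2 >= nx || j2 >= ny || k2 >= nz) continue;
          const int lin2 = i2 + nx * (j2 + ny * k2);
          const bool ab = a[lin] && b[lin2];
          const bool ba = b[lin] && a[lin2];
          if (ab || ba) {
            fx.push_back(0.5 * (i + i2));
            fy.push_back(0.5 * (j + j2));
            fz.push_back(0.5 * (k + k2));
          }
        }
      }
  NumericMatrix out(fx.size(), 3);
  for (size_t m = 0; m < fx.size(); ++m) {
    out(m, 0) = fx[m];
    out(m, 1) = fy[m];
    out(m, 2) = fz[m];
  }
  return out;
}

// Minimum Euclidean distance from each query point to the point set
// (brute force; both in world mm coordinates).
// [[Rcpp::export]]
NumericVector min_distance_to_points(NumericMatrix query,
                                     NumericMatrix points) {
  const int nq = query.nrow(), np = points.nrow();
  NumericVector out(nq);
  for (int q = 0; q < nq; ++q) {
    double best = std::numeric_limits<double>::infinity();
    const double qx = query(q, 0), qy = query(q, 1), qz = query(q, 2);
    for (int p = 0; p < np; ++p) {
      const double dx = qx - points(p, 0), dy = qy - points(p, 1),
                   dz = qz - points(p, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[q] = std::sqrt(best);
  }
  return out;
}

// 6-connected flood fill of `selectable` starting from `seed0` (0-based
// linear index); returns a 0/1 mask of the connected component.
// [[Rcpp::export]]
IntegerVector flood_fill6(IntegerVector selectable, IntegerVector dims,
                          int seed0) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out(selectable.size(), 0);
  if (!selectable[seed0]) return out;
  std::queue<int> q;
  q.push(seed0);
  out[seed0] = 1;
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  while (!q.empty()) {
    const int lin = q.front();
    q.pop();
    const int i = lin % nx, j = (lin / nx) % ny, k = lin / (nx * ny);
    for (int d = 0; d < 6; ++d) {
      const int i2 = i + dx[d], j2 = j + dy[d], k2 = k + dz[d];
      if (i2 < 0 || j2 < 0 || k2 < 0 || i2 >= nx || j2 >= ny || k2 >= nz)
        continue;
      const int lin2 = i2 + nx * (j2 + ny * k2);
      if (selectable[lin2] && !out[lin2]) {
        out[lin2] = 1;
        q.push(lin2);
      }
    }
  }
  return out;
}
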