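#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Radial kernel lookup on a uniform bin-centre grid: linear between
// centres, 1/r^2 continuation inside the first centre, zero beyond
// support. Mirrors sirtvox::dpk_phi() exactly.
static inline double phi_lookup(const double* phi, int n, double r0,
                                double dr, double x) {
  if (x <= r0) {
    double xx = std::max(x, 1e-9);
    return phi[0] * (r0 / xx) * (r0 / xx);
  }
  double last = r0 + dr * (n - 1);
  if (x >= last) return 0.0;
  double pos = (x - r0) / dr;
  int i = (int)pos;
  double f = pos - i;
  return phi[i] * (1.0 - f) + phi[i + 1] * f;
}

// Triangular (tent) density of the difference of two uniform variables
// on [-v/2, v/2]: support [-v, v], peak 1/v, integrates to 1.
static inline double tent(double x, double v) {
  const double ax = std::fabs(x);
  return ax >= v ? 0.0 : (v - ax) / (v * v);
}

// Mean of Phi(|target - source|) for source uniform in the centre voxel
// and target uniform in the voxel offset by (di,dj,dk) voxels.
//
// Reduction: with u = target - source + offset, the density of u is the
// separable product of tents centred on the offset, so
//   value = int_0^Rmax Phi(r) * r^2 * avg_{S2}[ g(r*omega) ] * 4*pi dr.
// The r^2 factor cancels Phi's 1/r^2 near-singularity, so a plain
// midpoint radial rule converges fast; the spherical average uses a
// deterministic Fibonacci point set.
// [[Rcpp::export]]
double pair_dose_quadrature(NumericVector phi, double r0_mm, double dr_mm,
                            double voxel_mm, int di, int dj, int dk,
                            double dr_rad_mm = 0.01, int n_sphere = 3000) {
  const double* ph = phi.begin();
  const int n = phi.size();
  const double support = r0_mm + dr_mm * (n - 1);
  const double ox = di * voxel_mm, oy = dj * voxel_mm, oz = dk * voxel_mm;
  const double off = std::sqrt(ox * ox + oy * oy + oz * oz);
  const double rmax =
      std::min(support, off + voxel_mm * std::sqrt(3.0) + dr_rad_mm);
  const double rmin = std::max(0.0, off - voxel_mm * std::sqrt(3.0));
  if (rmin >= rmax) return 0.0;

  // Fibonacci sphere directions
  std::vector<double> wx(n_sphere), wy(n_sphere), wz(n_sphere);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int i = 0; i < n_sphere; ++i) {
    const double z = 1.0 - (2.0 * i + 1.0) / n_sphere;
    const double rho = std::sqrt(std::max(0.0, 1.0 - z * z));
    wx[i] = rho * std::cos(ga * i);
    wy[i] = rho * std::sin(ga * i);
    wz[i] = z;
  }

  const int nr = (int)std::ceil((rmax - rmin) / dr_rad_mm);
  const double h = (rmax - rmin) / nr;
  double sum = 0.0;
  for (int j = 0; j < nr; ++j) {
    const double r = rmin + (j + 0.5) * h;
    double gavg = 0.0;
    for (int i = 0; i < n_sphere; ++i) {
      const double gx = tent(r * wx[i] - ox, voxel_mm);
      if (gx == 0.0) continue;
      const double gy = tent(r * wy[i] - oy, voxel_mm);
      if (gy == 0.0) continue;
      gavg += gx * gy * tent(r * wz[i] - oz, voxel_mm);
    }
    gavg /= n_sphere;
    sum += phi_lookup(ph, n, r0_mm, dr_mm, r) * r * r * gavg;
  }
  return 4.0 * M_PI * sum * h;
}
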