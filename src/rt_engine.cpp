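#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Radiological-path-length transport engine.
//
// For each target voxel t the absorbed dose is the sum over neighbouring
// source voxels s of
//   N_s * K(offset * s_fac) * s_fac^3 * (rho_ref / rho_t)
// where s_fac = l_eff / l_geo, l_eff is the radiological path length
// (integral of rho / rho_ref along the segment between voxel centres,
// Siddon/Amanatides-Woo traversal) and K is the reference voxel kernel
// (Gy per decay at rho_ref), sampled by trilinear interpolation at the
// density-scaled offset. The self-voxel uses s_fac = rho_t / rho_ref, so
// its contribution is N_t * K(0) * (rho_t / rho_ref)^2.
//
// In a uniform medium of any density the pair sum telescopes to the
// density-scaled kernel, so interior dose matches local deposition.

struct Offset {
  int di, dj, dk;
  double lgeo_mm; // geometric centre distance
  int amax;       // max axis offset magnitude, voxels
};

// Trilinear sample of the (2*hw+1)^3 kernel at continuous voxel offset
// (x,y,z); zero outside the kernel box (boundary nodes are zero anyway
// because the box must contain the radial support).
static inline double kernel_tri(const double* K, int hw, double x, double y,
                                double z) {
  const int n = 2 * hw + 1;
  const double cx = x + hw, cy = y + hw, cz = z + hw;
  if (cx < 0 || cy < 0 || cz < 0 || cx > n - 1 || cy > n - 1 || cz > n - 1)
    return 0.0;
  int ix = (int)cx, iy = (int)cy, iz = (int)cz;
  if (ix == n - 1) ix--;
  if (iy == n - 1) iy--;
  if (iz == n - 1) iz--;
  const double fx = cx - ix, fy = cy - iy, fz = cz - iz;
  double out = 0.0;
  for (int a = 0; a < 2; ++a) {
    const double wa = a ? fx : 1 - fx;
    for (int b = 0; b < 2; ++b) {
      const double wb = b ? fy : 1 - fy;
      for (int c = 0; c < 2; ++c) {
        const double wc = c ? fz : 1 - fz;
        out += wa * wb * wc *
               K[(ix + a) + n * ((iy + b) + n * (iz + c))];
      }
    }
  }
  return out;
}

// Radiological path length (mm at rho_ref) between centres of voxels a
// and b, with early exit once `cap` is exceeded (returns a value > cap).
static double radiological_length(const double* rho, int nx, int ny, int nz,
                                  double spacing, double rho_ref, int ai,
                                  int aj, int ak, int bi, int bj, int bk,
                                  double cap) {
  const double di = bi - ai, dj = bj - aj, dk = bk - ak;
  const double L = std::sqrt(di * di + dj * dj + dk * dk); // voxel units
  const double Lmm = L * spacing;
  int ci = ai, cj = aj, ck = ak;
  const int si = (di > 0) - (di < 0), sj = (dj > 0) - (dj < 0),
            sk = (dk > 0) - (dk < 0);
  const double INF = std::numeric_limits<double>::infinity();
  // t parametrises [0,1]; boundaries of voxel (c) along axis at c +- 0.5
  double tdx = di != 0 ? 1.0 / std::fabs(di) : INF;
  double tdy = dj != 0 ? 1.0 / std::fabs(dj) : INF;
  double tdz = dk != 0 ? 1.0 / std::fabs(dk) : INF;
  double tmx = di != 0 ? 0.5 / std::fabs(di) : INF;
  double tmy = dj != 0 ? 0.5 / std::fabs(dj) : INF;
  double tmz = dk != 0 ? 0.5 / std::fabs(dk) : INF;
  double tprev = 0.0, leff = 0.0;
  while (true) {
    const double rho_c = rho[ci + nx * (cj + ny * ck)];
    const bool at_target = (ci == bi && cj == bj && ck == bk);
    double tnext;
    if (at_target) {
      tnext = 1.0;
    } else {
      tnext = tmx;
      if (tmy < tnext) tnext = tmy;
      if (tmz < tnext) tnext = tmz;
      if (tnext > 1.0) tnext = 1.0;
    }
    leff += (tnext - tprev) * Lmm * rho_c / rho_ref;
    if (at_target || tnext >= 1.0) return leff;
    if (leff > cap) return leff;
    if (tmx <= tmy && tmx <= tmz) {
      ci += si;
      tmx += tdx;
    } else if (tmy <= tmz) {
      cj += sj;
      tmy += tdy;
    } else {
      ck += sk;
      tmz += tdz;
    }
    tprev = tnext;
  }
}

// [[Rcpp::export]]
NumericVector rt_dose_targets(NumericVector n_decays, NumericVector rho,
                              IntegerVector dims, double spacing,
                              NumericVector kernel, int hw, double rho_ref,
                              IntegerVector target_idx0,
                              double max_reach_mm) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* N = n_decays.begin();
  const double* R = rho.begin();
  const double* K = kernel.begin();
  const double K0 = K[hw + (2 * hw + 1) * (hw + (2 * hw + 1) * hw)];

  // candidate source offsets within the geometric reach sphere
  const int rv = (int)std::ceil(max_reach_mm / spacing);
  std::vector<Offset> offs;
  offs.reserve((2 * rv + 1) * (2 * rv + 1) * (2 * rv + 1) / 2);
  for (int dk = -rv; dk <= rv; ++dk)
    for (int dj = -rv; dj <= rv; ++dj)
      for (int di = -rv; di <= rv; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        const double lg =
            spacing * std::sqrt((double)di * di + dj * dj + dk * dk);
        if (lg > max_reach_mm) continue;
        Offset o;
        o.di = di; o.dj = dj; o.dk = dk; o.lgeo_mm = lg;
        o.amax = std::max(std::abs(di), std::max(std::abs(dj), std::abs(dk)));
        offs.push_back(o);
      }

  const int nt = target_idx0.size();
  NumericVector out(nt);
  for (int q = 0; q < nt; ++q) {
    const int lin = target_idx0[q];
    const int ti = lin % nx, tj = (lin / nx) % ny, tk = lin / (nx * ny);
    const double rho_t = R[lin];
    const double inv_rho_t = rho_ref / rho_t;
    // self contribution
    double dose = N[lin] * K0 * (rho_t / rho_ref) * (rho_t / rho_ref);
    for (size_t m = 0; m < offs.size(); ++m) {
      const Offset& o = offs[m];
      const int si = ti + o.di, sj = tj + o.dj, sk = tk + o.dk;
      if (si < 0 || sj < 0 || sk < 0 || si >= nx || sj >= ny || sk >= nz)
        continue;
      const double Ns = N[si + nx * (sj + ny * sk)];
      if (Ns <= 0) continue;
      // beyond this radiological length the scaled offset leaves the
      // kernel box, so the contribution is identically zero
      const double cap = hw * o.lgeo_mm / o.amax;
      const double leff = radiological_length(R, nx, ny, nz, spacing,
                                              rho_ref, si, sj, sk, ti, tj,
                                              tk, cap);
      if (leff > cap) continue;
      const double s = leff / o.lgeo_mm;
      const double kv =
          kernel_tri(K, hw, o.di * s, o.dj * s, o.dk * s);
      if (kv <= 0) continue;
      dose += Ns * kv * s * s * s * inv_rho_t;
    }
    out[q] = dose;
  }
  return out;
}
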