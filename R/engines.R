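#' Convert reconstructed counts to activity by self-calibration
#'
#' The self-calibration factor is administered activity divided by total
#' counts, so the returned activity map sums exactly to the administered
#' activity regardless of the counts scale:
#' `A_ijk = C_ijk * administered / sum(C)`.
#'
#' @param counts a [voxel_grid] of reconstructed counts (non-negative,
#'   not all zero).
#' @param administered_Bq administered activity in Bq.
#' @return a [voxel_grid] of activity in Bq.
#' @export
counts_to_activity <- function(counts, administered_Bq) {
  stopifnot_grid(counts, "counts")
  if (administered_Bq <= 0) stop("administered activity must be positive")
  total <- sum(counts$values)
  if (total <= 0) stop("all-zero counts: self-calibration undefined")
  with_values(counts, counts$values * (administered_Bq / total))
}

#' Convert activity to total disintegrations per voxel
#'
#' Microspheres are permanent implants with no biological clearance, so
#' the cumulated activity is set by physical decay alone:
#' `N_ijk = A_ijk * T_half / ln(2)` with `T_half` = 64.1 h.
#'
#' @param a a [voxel_grid] of activity in Bq (non-negative).
#' @return a [voxel_grid] of disintegration counts.
#' @examples
#' n <- activity_to_disintegrations(voxel_grid(array(1, c(1, 1, 1))))
#' n$values[1] # 3.3292e5 decays per Bq
#' @export
activity_to_disintegrations <- function(a) {
  stopifnot_grid(a, "activity")
  if (any(a$values < 0)) stop("negative activity")
  pc <- y90_constants()
  with_values(a, a$values * (pc$T_half_h * 3600 / log(2)))
}

new_dose_map <- function(grid, engine, note = NULL) {
  attr(grid, "engine") <- engine
  if (!is.null(note)) attr(grid, "note") <- note
  grid
}

#' Local deposition (LD) dose engine
#'
#' All beta energy of a voxel's decays is deposited in that voxel:
#' `D_ijk = N_ijk * E_avg / (rho_ijk * dV)`, converted MeV/g to Gy. Exact
#' under charged-particle equilibrium; ignores transport entirely.
#'
#' @param n a [voxel_grid] of disintegrations.
#' @param rho a co-registered [voxel_grid] of density in g/cc; must be
#'   positive wherever `n > 0`.
#' @return a [voxel_grid] dose map in Gy with an `engine` attribute.
#' @export
dose_ld <- function(n, rho) {
  stopifnot_congruent(n, rho, "n and rho")
  if (any(rho$values <= 0 & n$values > 0))
    stop("zero density at an active voxel")
  pc <- y90_constants()
  dv_cc <- voxel_volume_cc(n)
  d <- ifelse(n$values > 0,
              n$values * pc$E_avg_MeV / (rho$values * dv_cc) *
                pc$gy_per_mev_per_g,
              0)
  new_dose_map(with_values(n, array(d, dim = dim(n$values))), "LD")
}

#' Soft-tissue kernel (SK) dose engine
#'
#' Convolves the disintegration map with the reference soft-tissue voxel
#' kernel: `D = N (*) K`. The convolution is FFT-based with zero padding
#' by at least the kernel half-width so no wrap-around occurs; negative
#' numerical residue is clamped to zero. SK assumes 1.04 g/cc everywhere,
#' so in a medium of density rho it is low by exactly `rho / 1.04`.
#'
#' @param n a [voxel_grid] of disintegrations on an isotropic grid whose
#'   spacing matches the kernel voxel size.
#' @param k a [build_voxel_kernel] kernel.
#' @return a [voxel_grid] dose map in Gy.
#' @export
dose_sk <- function(n, k) {
  stopifnot_grid(n, "n")
  if (!inherits(k, "voxel_kernel")) stop("k must be a voxel_kernel")
  stopifnot_isotropic(n, "the SK engine")
  if (abs(n$spacing[1] - k$voxel_mm) > 1e-6)
    stop(sprintf("voxel-size mismatch: grid %.4g mm vs kernel %.4g mm",
                 n$spacing[1], k$voxel_mm))
  d <- conv3d_fft(n$values, k$values)
  d[d < 0] <- 0
  new_dose_map(with_values(n, d), "SK")
}

#' Soft-tissue kernel with density correction (SKD) dose engine
#'
#' The SK dose rescaled voxelwise by the ratio of kernel density to voxel
#' density: `D = (N (*) K) * 1.04 / rho_ijk` (rho in g/cc). Restores the
#' correct equilibrium dose in uniform media of any density, but not the
#' range stretching across density interfaces.
#'
#' @inheritParams dose_sk
#' @param rho co-registered density [voxel_grid] in g/cc, strictly
#'   positive.
#' @return a [voxel_grid] dose map in Gy.
#' @export
dose_skd <- function(n, k, rho) {
  stopifnot_congruent(n, rho, "n and rho")
  if (any(rho$values <= 0)) stop("zero density in the compute region")
  sk <- dose_sk(n, k)
  if (!inherits(k, "voxel_kernel")) stop("k must be a voxel_kernel")
  new_dose_map(with_values(sk, sk$values * (k$rho_ref / rho$values)), "SKD")
}

#' Radiological-path-length transport (RT) reference engine
#'
#' The package's deterministic reference ("truth") engine. For each
#' target voxel the dose is summed over source voxels using the reference
#' voxel kernel evaluated at the density-scaled offset: the geometric
#' source-target segment is ray-traced through the density grid
#' (Siddon-type traversal) to obtain the radiological path length
#' `l_eff = integral of (rho / 1.04) dl`, and the pair contribution is
#' `N_s * K(offset * l_eff / l_geo) * (l_eff / l_geo)^3 * (1.04 / rho_t)`.
#' In any uniform medium this reduces exactly to the density-scaled
#' kernel, so interior dose equals local deposition; across the
#' liver-lung interface it reproduces the beta range stretching (11 mm in
#' soft tissue growing to 44 mm in 0.26 g/cc lung). It does not model
#' backscatter or lateral scatter redistribution.
#'
#' @inheritParams dose_skd
#' @param targets optional 0/1 mask [voxel_grid] (or logical array)
#'   selecting the voxels where dose is computed; `NULL` computes every
#'   voxel. Dose outside the targets is returned as 0.
#' @param max_reach_mm geometric search radius for source voxels. The
#'   default is the kernel support scaled by the inverse of the smallest
#'   density on the grid, with that density clamped below at
#'   `reach_floor_rho` so near-vacuum voxels cannot blow the radius up.
#' @param reach_floor_rho density floor (g/cc) for the default reach.
#' @return a [voxel_grid] dose map in Gy.
#' @export
dose_rt <- function(n, k, rho, targets = NULL, max_reach_mm = NULL,
                    reach_floor_rho = 0.2) {
  stopifnot_congruent(n, rho, "n and rho")
  if (!inherits(k, "voxel_kernel")) stop("k must be a voxel_kernel")
  stopifnot_isotropic(n, "the RT engine")
  if (abs(n$spacing[1] - k$voxel_mm) > 1e-6)
    stop(sprintf("voxel-size mismatch: grid %.4g mm vs kernel %.4g mm",
                 n$spacing[1], k$voxel_mm))
  if (any(rho$values <= 0)) stop("non-positive density")
  dims <- dim(n$values)
  tmask <- if (is.null(targets)) array(TRUE, dims)
           else if (is_voxel_grid(targets)) targets$values > 0
           else targets > 0
  if (!identical(dim(tmask), dims)) stop("targets mask dims mismatch")
  if (is.null(max_reach_mm)) {
    rho_min <- min(rho$values)
    if (rho_min < reach_floor_rho)
      warning(sprintf(
        "densities below %.3g g/cc present; RT reach capped accordingly",
        reach_floor_rho))
    max_reach_mm <- k$support_mm * k$rho_ref / max(rho_min, reach_floor_rho) +
      n$spacing[1]
  }
  idx0 <- which(tmask) - 1L
  dose_t <- rt_dose_targets(as.numeric(n$values), as.numeric(rho$values),
                            as.integer(dims), n$spacing[1],
                            as.numeric(k$values), as.integer(k$hw),
                            k$rho_ref, as.integer(idx0), max_reach_mm)
  d <- array(0, dims)
  d[tmask] <- dose_t
  out <- new_dose_map(with_values(n, d), "RT")
  attr(out, "targets_partial") <- !all(tmask)
  out
}

#' Global energy deposited by a dose map
#'
#' Conservation diagnostic: `sum(D * rho * dV)` converted to MeV. For LD
#' this equals `sum(N) * E_avg` algebraically; for SK/SKD/RT it matches
#' within quadrature tolerance whenever the activity is fully inside the
#' padded grid (and, for RT, the whole grid was computed).
#'
#' @param d dose map [voxel_grid] in Gy.
#' @param rho co-registered density [voxel_grid] in g/cc.
#' @return deposited energy in MeV.
#' @export
global_energy <- function(d, rho) {
  stopifnot_congruent(d, rho, "dose and rho")
  pc <- y90_constants()
  sum(d$values * rho$values) * voxel_volume_cc(d) / pc$gy_per_mev_per_g
}
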