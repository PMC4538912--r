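#' Specification of a synthetic SPECT/CT-like phantom "patient"
#'
#' A deterministic anthropomorphic-lite phantom: a liver ellipsoid
#' capped by the horizontal liver--lung interface plane, a lung
#' ellipsoid cap above the plane (0.26 g/cc), soft-tissue background
#' (1.04 g/cc), spherical tumors inside the liver with elevated uptake,
#' a lung shunt fraction LS of the administered activity spread
#' uniformly over the lung, and an imaging chain of Gaussian PSF blur
#' plus proportional counts (optional Poisson noise). All randomness is
#' controlled by `seed`.
#'
#' @param dims grid size per axis (default c(40, 40, 44)).
#' @param spacing_mm isotropic voxel size (default 4.8).
#' @param interface_z_mm world z of the liver--lung interface plane; must
#'   be a voxel boundary. Default 132.
#' @param liver_radii_mm ellipsoid semi-axes (x, y, z) of the liver.
#' @param lung_radii_mm semi-axes of the lung ellipsoid, centred on the
#'   interface plane (only the cap above the plane is lung).
#' @param tumors data.frame with columns `x_mm`, `y_mm`, `z_mm`,
#'   `radius_mm`, `uptake` (activity concentration ratio to non-tumoral
#'   liver); all spheres must lie inside the liver.
#' @param ls lung shunt fraction in `[0, 1]`.
#' @param administered_Bq administered activity (default 2.81 GBq, a
#'   typical glass-microsphere prescription).
#' @param psf_fwhm_mm imaging PSF FWHM (default 20, post-therapy
#'   bremsstrahlung SPECT resolution).
#' @param counts_scale counts per Bq before noise (arbitrary;
#'   self-calibration removes it).
#' @param poisson_noise logical; add Poisson counting noise.
#' @param seed RNG seed for the noise.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(40L, 40L, 44L), spacing_mm = 4.8,
                         interface_z_mm = 132,
                         liver_radii_mm = c(50, 50, 45),
                         lung_radii_mm = c(62, 62, 50),
                         tumors = data.frame(x_mm = 93.6, y_mm = 93.6,
                                             z_mm = 100, radius_mm = 18,
                                             uptake = 3),
                         ls = 0.05, administered_Bq = 2.81e9,
                         psf_fwhm_mm = 20, counts_scale = 1e-3,
                         poisson_noise = FALSE, seed = 1L) {
  if (ls < 0 || ls > 1) stop("LS must be within [0, 1]")
  if (any(liver_radii_mm <= 0) || any(lung_radii_mm <= 0))
    stop("radii must be positive")
  if (!is.null(tumors) && nrow(tumors) > 0 && any(tumors$radius_mm <= 0))
    stop("tumor radii must be positive")
  structure(list(dims = as.integer(dims), spacing_mm = spacing_mm,
                 interface_z_mm = interface_z_mm,
                 liver_radii_mm = liver_radii_mm,
                 lung_radii_mm = lung_radii_mm, tumors = tumors, ls = ls,
                 administered_Bq = administered_Bq,
                 psf_fwhm_mm = psf_fwhm_mm, counts_scale = counts_scale,
                 poisson_noise = poisson_noise, seed = as.integer(seed)),
            class = "phantom_spec")
}

ellipsoid_mask <- function(coords, centre, radii) {
  # coords: list of axis coordinate vectors; returns logical array
  q <- outer(((coords[[1]] - centre[1]) / radii[1])^2,
             ((coords[[2]] - centre[2]) / radii[2])^2, "+")
  outer(q, ((coords[[3]] - centre[3]) / radii[3])^2, "+") <= 1
}

#' Generate a synthetic phantom
#'
#' Builds density, true activity and VOI masks from a [phantom_spec].
#' The activity sums exactly to the administered activity: `(1 - LS)`
#' over the liver with tumor-to-NL concentration ratios as specified,
#' and `LS` uniform over the lung.
#'
#' @param spec a [phantom_spec].
#' @return list with [voxel_grid] elements `density`, `activity` and a
#'   `masks` list (`liver`, `nl`, `lung`, `tumors` = list of one mask
#'   per tumor), plus the `spec`.
#' @export
generate_phantom <- function(spec) {
  dims <- spec$dims; sp <- spec$spacing_mm
  coords <- lapply(1:3, function(a) (seq_len(dims[a]) - 1) * sp)
  zc <- coords[[3]]
  centre_xy <- c((dims[1] - 1) * sp / 2, (dims[2] - 1) * sp / 2)
  zif <- spec$interface_z_mm
  liver_centre <- c(centre_xy, zif - 0.55 * spec$liver_radii_mm[3])
  liver_full <- ellipsoid_mask(coords, liver_centre, spec$liver_radii_mm)
  below <- array(rep(zc < zif, each = dims[1] * dims[2]), dims)
  liver <- liver_full & below
  lung_full <- ellipsoid_mask(coords, c(centre_xy, zif), spec$lung_radii_mm)
  lung <- lung_full & !below
  tum_masks <- list()
  tum_all <- array(FALSE, dims)
  if (!is.null(spec$tumors) && nrow(spec$tumors) > 0) {
    for (t in seq_len(nrow(spec$tumors))) {
      tu <- spec$tumors[t, ]
      m <- ellipsoid_mask(coords, c(tu$x_mm, tu$y_mm, tu$z_mm),
                          rep(tu$radius_mm, 3))
      if (any(m & !liver)) stop(sprintf("tumor %d escapes the liver", t))
      tum_masks[[t]] <- m
      tum_all <- tum_all | m
    }
  }
  nl <- liver & !tum_all
  rho <- array(1.04, dims)
  rho[lung] <- 0.26
  act <- array(0, dims)
  weights <- array(0, dims)
  weights[nl] <- 1
  if (length(tum_masks))
    for (t in seq_along(tum_masks))
      weights[tum_masks[[t]]] <- spec$tumors$uptake[t]
  act[liver] <- weights[liver] *
    ((1 - spec$ls) * spec$administered_Bq / sum(weights))
  act[lung] <- spec$ls * spec$administered_Bq / sum(lung)
  g <- function(v) voxel_grid(v, sp, c(0, 0, 0))
  mk <- function(m) g(array(as.numeric(m), dims))
  list(density = g(rho), activity = g(act),
       masks = list(liver = mk(liver), nl = mk(nl), lung = mk(lung),
                    tumors = lapply(tum_masks, mk)),
       spec = spec)
}

#' Simulate the imaging chain: PSF blur and proportional counts
#'
#' Models the quantitative SPECT chain as an isotropic Gaussian PSF
#' followed by counts proportional to activity, with optional Poisson
#' counting noise. Attenuation, scatter and collimator response are not
#' modelled: self-calibration makes the absolute counts scale
#' irrelevant.
#'
#' @param true_activity [voxel_grid] of activity in Bq.
#' @param fwhm_mm PSF full width at half maximum in mm.
#' @param counts_scale counts per Bq (> 0).
#' @param poisson_noise logical; if `TRUE`, counts are Poisson sampled.
#' @param seed RNG seed used when `poisson_noise` is `TRUE`.
#' @return [voxel_grid] of counts.
#' @export
simulate_imaging <- function(true_activity, fwhm_mm = 20, counts_scale = 1e-3,
                             poisson_noise = FALSE, seed = 1L) {
  stopifnot_grid(true_activity, "true_activity")
  if (counts_scale <= 0) stop("counts_scale must be positive")
  counts <- blur_activity(true_activity, fwhm_mm)
  counts <- with_values(counts, counts$values * counts_scale)
  if (poisson_noise)
    counts <- with_values(counts, with_seed(seed, {
      array(as.numeric(rpois(length(counts$values),
                             as.numeric(counts$values))),
            dim = dim(counts$values))
    }))
  counts
}

#' Specification of a synthetic phantom cohort
#'
#' Cohort-level sampling ranges (uniform draws) mirroring a 17-case
#' post-therapy series: administered activity 1.13--5.21 GBq, lung shunt
#' 1--20%, 1--3 tumors per phantom with radii 10--30 mm and
#' tumor-to-liver uptake ratios 2--6, with the total tumor count across
#' the cohort fixed (default 31).
#'
#' @param n number of phantoms (default 17).
#' @param administered_GBq,ls,tumor_radius_mm,tumor_uptake,liver_rxy_mm,liver_rz_mm
#'   ranges (length-2 numeric) for the uniform per-phantom draws.
#' @param tumors_per_phantom integer range of tumors per phantom.
#' @param total_tumors total tumors across the cohort (counts are
#'   redistributed within `tumors_per_phantom` to hit this sum).
#' @param psf_fwhm_mm imaging resolution applied to every phantom.
#' @param poisson_noise logical, cohort-wide.
#' @param seed master seed; fixes every draw in the cohort.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 17L, administered_GBq = c(1.13, 5.21),
                        ls = c(0.01, 0.20), tumor_radius_mm = c(10, 30),
                        tumor_uptake = c(2, 6),
                        liver_rxy_mm = c(42, 55), liver_rz_mm = c(40, 50),
                        tumors_per_phantom = c(1L, 3L), total_tumors = 31L,
                        psf_fwhm_mm = 20, poisson_noise = FALSE, seed = 7L) {
  if (n < 1) stop("n must be >= 1")
  rng_ok <- function(r) length(r) == 2 && r[1] <= r[2]
  if (!all(vapply(list(administered_GBq, ls, tumor_radius_mm, tumor_uptake,
                       liver_rxy_mm, liver_rz_mm), rng_ok, logical(1))))
    stop("invalid sampling range")
  if (total_tumors < n * tumors_per_phantom[1] ||
      total_tumors > n * tumors_per_phantom[2])
    stop("total_tumors unreachable with the per-phantom range")
  structure(list(n = as.integer(n), administered_GBq = administered_GBq,
                 ls = ls, tumor_radius_mm = tumor_radius_mm,
                 tumor_uptake = tumor_uptake, liver_rxy_mm = liver_rxy_mm,
                 liver_rz_mm = liver_rz_mm,
                 tumors_per_phantom = as.integer(tumors_per_phantom),
                 total_tumors = as.integer(total_tumors),
                 psf_fwhm_mm = psf_fwhm_mm, poisson_noise = poisson_noise,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Draw per-phantom tumor counts within [lo, hi] summing to the target.
draw_tumor_counts <- function(n, lo, hi, total) {
  counts <- sample(lo:hi, n, replace = TRUE)
  while (sum(counts) != total) {
    if (sum(counts) > total) {
      i <- sample(which(counts > lo), 1)
      counts[i] <- counts[i] - 1L
    } else {
      i <- sample(which(counts < hi), 1)
      counts[i] <- counts[i] + 1L
    }
  }
  counts
}

# Place tumors by rejection sampling inside the clipped liver; shrinks a
# tumor that cannot be placed (rare at the default geometry).
place_tumors <- function(k, radii, uptakes, liver_centre, liver_radii,
                         zif, spacing) {
  out <- NULL
  if (k == 0) return(out)
  for (t in seq_len(k)) {
    r <- radii[t]
    repeat {
      placed <- FALSE
      for (try in 1:400) {
        u <- runif(3, -1, 1)
        if (sum(u^2) > 1) next
        cand <- liver_centre + u * pmax(liver_radii - r - spacing, 0)
        inside <- sum(((cand - liver_centre) / (liver_radii - r - spacing/2))^2) <= 1
        below <- cand[3] + r + spacing / 2 < zif
        clear <- is.null(out) ||
          all(sqrt(colSums((t(as.matrix(out[, 1:3])) - cand)^2)) >
                out$radius_mm + r + spacing)
        if (inside && below && clear) {
          out <- rbind(out, data.frame(x_mm = cand[1], y_mm = cand[2],
                                       z_mm = cand[3], radius_mm = r,
                                       uptake = uptakes[t]))
          placed <- TRUE
          break
        }
      }
      if (placed) break
      r <- 0.9 * r # shrink and retry
    }
  }
  out
}

#' Generate a deterministic cohort of synthetic phantoms
#'
#' Draws every phantom's parameters from the cohort ranges under the
#' master seed and builds the phantom volumes and simulated counts. The
#' same seed reproduces the cohort bit-identically.
#'
#' @param cspec a [cohort_spec].
#' @return list with `phantoms` (list of bundles as returned by
#'   [generate_phantom], each with an added `counts` [voxel_grid]) and
#'   `manifest` (data.frame of every drawn parameter; tumor geometry is
#'   recorded inside each phantom's spec).
#' @export
generate_cohort <- function(cspec) {
  if (!inherits(cspec, "cohort_spec")) stop("cspec must be a cohort_spec")
  with_seed(cspec$seed, {
    n <- cspec$n
    admin <- runif(n, cspec$administered_GBq[1], cspec$administered_GBq[2])
    ls <- runif(n, cspec$ls[1], cspec$ls[2])
    rxy <- runif(n, cspec$liver_rxy_mm[1], cspec$liver_rxy_mm[2])
    rz <- runif(n, cspec$liver_rz_mm[1], cspec$liver_rz_mm[2])
    ntum <- draw_tumor_counts(n, cspec$tumors_per_phantom[1],
                              cspec$tumors_per_phantom[2],
                              cspec$total_tumors)
    phantoms <- vector("list", n)
    manifest <- NULL
    for (i in seq_len(n)) {
      radii <- runif(ntum[i], cspec$tumor_radius_mm[1], cspec$tumor_radius_mm[2])
      uptakes <- runif(ntum[i], cspec$tumor_uptake[1], cspec$tumor_uptake[2])
      dims <- c(40L, 40L, 44L); sp <- 4.8; zif <- 132
      liver_radii <- c(rxy[i], rxy[i], rz[i])
      liver_centre <- c((dims[1] - 1) * sp / 2, (dims[2] - 1) * sp / 2,
                        zif - 0.55 * rz[i])
      tum <- place_tumors(ntum[i], radii, uptakes, liver_centre, liver_radii,
                          zif, sp)
      pspec <- phantom_spec(dims = dims, spacing_mm = sp,
                            interface_z_mm = zif,
                            liver_radii_mm = liver_radii,
                            tumors = tum, ls = ls[i],
                            administered_Bq = admin[i] * 1e9,
                            psf_fwhm_mm = cspec$psf_fwhm_mm,
                            poisson_noise = cspec$poisson_noise,
                            seed = cspec$seed + i)
      ph <- generate_phantom(pspec)
      ph$counts <- simulate_imaging(ph$activity, pspec$psf_fwhm_mm,
                                    pspec$counts_scale,
                                    pspec$poisson_noise, pspec$seed)
      phantoms[[i]] <- ph
      manifest <- rbind(manifest, data.frame(
        phantom = i, administered_GBq = admin[i], ls = ls[i],
        liver_rxy_mm = rxy[i], liver_rz_mm = rz[i], n_tumors = ntum[i],
        mean_tumor_radius_mm = if (ntum[i]) mean(tum$radius_mm) else NA,
        seed = pspec$seed))
    }
    list(phantoms = phantoms, manifest = manifest, spec = cspec)
  })
}
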