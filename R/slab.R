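#' Specification of the two-compartment liver--lung slab phantom
#'
#' The interface accuracy experiment uses a slab geometry: liver
#' (1.04 g/cc) fills the half-space at z <= 0 and lung (0.26 g/cc) the
#' half-space at z > 0, on an isotropic grid whose reported core is
#' `dims` voxels per axis. The grid is extended by `margin_voxels` of the
#' same pattern on every face so that the core is at charged-particle
#' equilibrium (the margin must exceed the 44 mm beta reach in lung plus
#' the blur extent); profiles and intervals are reported on the core
#' only.
#'
#' @param dims core grid size per axis (default 61).
#' @param spacing_mm isotropic voxel size (default 4.8).
#' @param total_activity_Bq total activity placed uniformly in one
#'   compartment (default 1: engines are then "per unit activity").
#' @param fwhm_mm Gaussian blur FWHMs to study, mm.
#' @param ls lung shunt fractions to study (activity fraction in lung).
#' @param margin_voxels equilibrium extension per face, voxels.
#' @return object of class `slab_spec`.
#' @export
slab_spec <- function(dims = 61L, spacing_mm = 4.8, total_activity_Bq = 1,
                      fwhm_mm = c(0, 10, 20), ls = c(0.01, 0.10, 0.20),
                      margin_voxels = 12L) {
  if (any(ls < 0 | ls > 1)) stop("ls must be within [0, 1]")
  if (any(fwhm_mm < 0)) stop("fwhm must be >= 0")
  margin_mm <- margin_voxels * spacing_mm
  need <- y90_constants()$R_max_soft_mm * 1.04 / 0.26
  if (margin_mm < need)
    stop(sprintf("margin %d voxels (%.1f mm) is smaller than the %.0f mm kernel support in lung",
                 margin_voxels, margin_mm, need))
  structure(list(dims = as.integer(dims), spacing_mm = spacing_mm,
                 total_activity_Bq = total_activity_Bq,
                 fwhm_mm = fwhm_mm, ls = ls,
                 margin_voxels = as.integer(margin_voxels)),
            class = "slab_spec")
}

#' Build the slab phantom volumes
#'
#' Uniform activity in the selected compartment (summing exactly to the
#' spec total) and the two-density map. Voxel centres sit at
#' z = ..., -7.2, -2.4, +2.4, +7.2, ... mm so the interface plane z = 0
#' is a voxel boundary; liver voxels have centres z < 0.
#'
#' @param spec a [slab_spec].
#' @param compartment `"liver"` or `"lung"`: which compartment holds the
#'   activity.
#' @return list with [voxel_grid] elements `activity` and `density`, plus
#'   `core` (index range of the reported core region per axis).
#' @export
make_slab <- function(spec, compartment = c("liver", "lung")) {
  compartment <- match.arg(compartment)
  m <- spec$margin_voxels
  n <- spec$dims + 2L * m
  sp <- spec$spacing_mm
  # core z indices m+1 .. m+dims (1-based); interface after core slice
  # ceiling(dims/2): for 61 core slices, 31 liver / 30 lung.
  n_liver_core <- as.integer(ceiling(spec$dims / 2))
  k_if <- m + n_liver_core # last liver slice (1-based, incl. margin below)
  zc <- (seq_len(n) - k_if) * sp - sp / 2 # voxel-centre z, interface at 0
  origin <- c(-(m + (spec$dims + 1) / 2 - 1) * sp,
              -(m + (spec$dims + 1) / 2 - 1) * sp,
              zc[1])
  rho <- array(rep(ifelse(zc < 0, 1.04, 0.26), each = n * n), dim = c(n, n, n))
  act <- array(0, c(n, n, n))
  sel <- if (compartment == "liver") zc < 0 else zc > 0
  n_act <- sum(sel) * n * n
  act[, , sel] <- spec$total_activity_Bq / n_act
  list(
    activity = voxel_grid(act, sp, origin),
    density = voxel_grid(rho, sp, origin),
    core = (m + 1L):(m + spec$dims)
  )
}

#' Superpose liver and lung dose components by lung shunt fraction
#'
#' Each component must be computed per unit total input activity in its
#' own compartment; the combination `D = (1 - ls) * liver + ls * lung`
#' then corresponds to a shunt fraction `ls` of the administered
#' activity.
#'
#' @param d_liver,d_lung co-registered dose maps (or profiles as returned
#'   by [extract_profile]).
#' @param ls lung shunt fraction in `[0, 1]`.
#' @return the combined dose map (or profile).
#' @export
combine_ls <- function(d_liver, d_lung, ls) {
  if (length(ls) != 1L || ls < 0 || ls > 1) stop("ls must be in [0, 1]")
  if (is_voxel_grid(d_liver)) {
    stopifnot_congruent(d_liver, d_lung, "LS components")
    return(with_values(d_liver, (1 - ls) * d_liver$values + ls * d_lung$values))
  }
  if (is.data.frame(d_liver)) {
    if (!isTRUE(all.equal(d_liver$position_mm, d_lung$position_mm)))
      stop("profile positions differ")
    out <- d_liver
    out$value <- (1 - ls) * d_liver$value + ls * d_lung$value
    return(out)
  }
  (1 - ls) * d_liver + ls * d_lung
}

#' Extract the central 1D dose profile along z
#'
#' One value per z slab: the mean over the central 7 x 7 voxels of each
#' x-y plane. Positions are voxel-centre z coordinates (mm, interface at
#' 0 for slab phantoms).
#'
#' @param d a dose map [voxel_grid] at least 7 voxels wide in x and y.
#' @param z_keep optional integer index range of z slices to report
#'   (e.g. the slab core); default all.
#' @return data.frame with columns `position_mm` and `value`.
#' @export
extract_profile <- function(d, z_keep = NULL) {
  stopifnot_grid(d, "dose")
  dims <- dim(d$values)
  if (dims[1] < 7L || dims[2] < 7L) stop("grid too small for a 7x7 column")
  cx <- floor((dims[1] - 1) / 2) + 1L
  cy <- floor((dims[2] - 1) / 2) + 1L
  xi <- (cx - 3L):(cx + 3L); yi <- (cy - 3L):(cy + 3L)
  val <- apply(d$values[xi, yi, , drop = FALSE], 3, mean)
  pos <- axis_coords(d, 3)
  if (!is.null(z_keep)) {
    val <- val[z_keep]; pos <- pos[z_keep]
  }
  data.frame(position_mm = pos, value = val)
}

#' Percent difference of a profile from a reference profile
#'
#' @param p,truth profiles from [extract_profile] on identical positions;
#'   `truth` must be strictly positive everywhere it is compared.
#' @return data.frame with `position_mm` and `value` = percent difference
#'   `100 * (p - truth) / truth`.
#' @export
percent_difference <- function(p, truth) {
  if (!isTRUE(all.equal(p$position_mm, truth$position_mm)))
    stop("profiles have different positions")
  if (any(truth$value <= 0))
    stop("zero or negative truth value at a compared position")
  data.frame(position_mm = p$position_mm,
             value = 100 * (p$value - truth$value) / truth$value)
}

#' Agreement intervals of a percent-difference profile
#'
#' Interpolates |percent difference| linearly onto a 1 mm grid and
#' returns the maximal intervals where it stays within the threshold.
#' An outermost compliant interval whose end touches the profile boundary
#' is extended to +/-Inf (the slab is at equilibrium there).
#'
#' @param pd percent-difference profile (from [percent_difference]).
#' @param threshold agreement threshold in percent (default 10).
#' @return object of class `agreement_intervals`: a data.frame with
#'   columns `lower_mm`, `upper_mm` (possibly infinite), plus attributes
#'   `threshold` and `grid_mm`.
#' @export
agreement_intervals <- function(pd, threshold = 10) {
  if (nrow(pd) == 0) stop("empty profile")
  if (threshold <= 0) stop("threshold must be positive")
  pos <- pd$position_mm
  if (min(pos) >= 0 || max(pos) <= 0)
    stop("profile must cover both sides of the interface")
  grid <- seq(ceiling(min(pos)), floor(max(pos)), by = 1)
  a <- approx(pos, abs(pd$value), xout = grid, ties = "ordered")$y
  ok <- a <= threshold
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  iv <- data.frame(lower_mm = numeric(0), upper_mm = numeric(0))
  for (i in seq_along(runs$values)) {
    if (!runs$values[i]) next
    lo <- grid[starts[i]]; hi <- grid[ends[i]]
    if (starts[i] == 1L) lo <- -Inf
    if (ends[i] == length(grid)) hi <- Inf
    iv <- rbind(iv, data.frame(lower_mm = lo, upper_mm = hi))
  }
  structure(iv, threshold = threshold, grid_mm = 1, class = c("agreement_intervals", "data.frame"))
}

#' @export
print.agreement_intervals <- function(x, ...) {
  fmt <- function(v) ifelse(is.infinite(v), ifelse(v > 0, "∞", "-∞"),
                            format(v, trim = TRUE))
  if (nrow(x) == 0) cat("(no compliant interval)\n")
  else cat(paste(sprintf("(%s, %s)", fmt(x$lower_mm), fmt(x$upper_mm)),
                 collapse = " U "), "\n")
  invisible(x)
}

# Deepest non-compliant position on each side of the interface, from a
# percent-difference profile interpolated to 1 mm: the "agreement beyond
# x mm" boundary. Liver side reported as a positive depth.
compliance_boundaries <- function(pd, threshold = 10) {
  pos <- pd$position_mm
  grid <- seq(ceiling(min(pos)), floor(max(pos)), by = 1)
  a <- approx(pos, abs(pd$value), xout = grid, ties = "ordered")$y
  bad <- grid[a > threshold]
  list(
    liver_mm = if (any(bad < 0)) -min(bad[bad < 0]) else 0,
    lung_mm = if (any(bad > 0)) max(bad[bad > 0]) else 0
  )
}

#' Run the full liver--lung interface accuracy study
#'
#' For each compartment (liver-source, lung-source) the uniform activity
#' is blurred at every FWHM in the spec; the four engines are run per
#' unit compartment activity; central 7x7 z-profiles are extracted over
#' the core; components are superposed for every lung shunt fraction;
#' percent differences are taken against the truth (the RT engine on the
#' unblurred activity at the same LS) and reduced to +/-10% agreement
#' intervals. The RT engine is evaluated on the central 7x7 column only
#' (the profile region). Fully deterministic.
#'
#' @param spec a [slab_spec].
#' @param kernel voxel kernel from [build_voxel_kernel]; must match the
#'   spec spacing.
#' @param threshold agreement threshold in percent.
#' @return list with data.frames `profiles` (`engine`, `fwhm_mm`, `ls`,
#'   `position_mm`, `dose`, `pct_diff`), `intervals` (one row per
#'   engine/fwhm/ls with an `intervals` list column), and `boundaries`
#'   (`engine`, `fwhm_mm`, `ls`, `liver_mm`, `lung_mm`).
#' @export
run_interface_study <- function(spec, kernel, threshold = 10) {
  engines <- c("LD", "SK", "SKD", "RT")
  comps <- c("liver", "lung")
  slabs <- lapply(setNames(comps, comps), function(cp) make_slab(spec, cp))
  rho <- slabs$liver$density
  core <- slabs$liver$core
  dims <- dim(rho$values)
  # RT target mask: the central 7x7 column through all z
  cx <- floor((dims[1] - 1) / 2) + 1L
  tmask <- array(FALSE, dims)
  tmask[(cx - 3L):(cx + 3L), (cx - 3L):(cx + 3L), ] <- TRUE

  # per-compartment, per-fwhm engine profiles
  prof <- list()
  for (cp in comps) {
    for (fw in unique(c(0, spec$fwhm_mm))) {
      act <- blur_activity(slabs[[cp]]$activity, fw)
      n <- activity_to_disintegrations(act)
      d <- list(
        LD = dose_ld(n, rho),
        SK = dose_sk(n, kernel),
        SKD = dose_skd(n, kernel, rho),
        RT = dose_rt(n, kernel, rho, targets = tmask)
      )
      for (eng in engines)
        prof[[paste(cp, fw, eng, sep = "|")]] <-
          extract_profile(d[[eng]], z_keep = core)
    }
  }

  profiles <- NULL
  intervals <- NULL
  boundaries <- NULL
  for (fw in spec$fwhm_mm) for (l in spec$ls) {
    truth <- combine_ls(prof[["liver|0|RT"]], prof[["lung|0|RT"]], l)
    for (eng in engines) {
      p <- combine_ls(prof[[paste("liver", fw, eng, sep = "|")]],
                      prof[[paste("lung", fw, eng, sep = "|")]], l)
      pd <- percent_difference(p, truth)
      profiles <- rbind(profiles, data.frame(
        engine = eng, fwhm_mm = fw, ls = l,
        position_mm = p$position_mm, dose = p$value, pct_diff = pd$value))
      iv <- agreement_intervals(pd, threshold)
      intervals <- rbind(intervals, data.frame(
        engine = eng, fwhm_mm = fw, ls = l,
        intervals = I(list(iv))))
      b <- compliance_boundaries(pd, threshold)
      boundaries <- rbind(boundaries, data.frame(
        engine = eng, fwhm_mm = fw, ls = l,
        liver_mm = b$liver_mm, lung_mm = b$lung_mm))
    }
  }
  list(profiles = profiles, intervals = intervals, boundaries = boundaries)
}

#' Worst-case agreement boundary over engines and shunt fractions
#'
#' Reduces an interface-study boundary table to the deepest distance at
#' which any selected engine/LS combination still disagrees with truth,
#' on one side of the interface.
#'
#' @param boundaries the `boundaries` element of [run_interface_study].
#' @param side `"liver"` or `"lung"`.
#' @param fwhm_mm blur level to report.
#' @param engines engines included in the worst case.
#' @return depth in mm (positive on both sides).
#' @export
worst_boundary <- function(boundaries, side = c("liver", "lung"), fwhm_mm,
                           engines = c("LD", "SK", "SKD", "RT")) {
  side <- match.arg(side)
  sel <- boundaries$fwhm_mm == fwhm_mm & boundaries$engine %in% engines
  if (!any(sel)) stop("no matching study rows")
  col <- if (side == "liver") "liver_mm" else "lung_mm"
  max(boundaries[[col]][sel])
}
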