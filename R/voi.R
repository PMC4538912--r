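#' Mean absorbed dose over a VOI
#'
#' @param d dose map [voxel_grid] in Gy.
#' @param mask 0/1 [voxel_grid] (or logical array) on the same grid;
#'   must be non-empty.
#' @return mean dose in Gy over the masked voxels.
#' @export
mean_dose <- function(d, mask) {
  stopifnot_grid(d, "dose")
  m <- mask_values(mask, dim(d$values))
  if (!any(m)) stop("empty mask")
  mean(d$values[m])
}

mask_values <- function(mask, dims) {
  m <- if (is_voxel_grid(mask)) mask$values > 0 else mask > 0
  if (!identical(dim(m), dims)) stop("mask dims do not match the dose grid")
  m
}

#' Cumulative dose-volume histogram
#'
#' The fraction of the VOI receiving at least each dose level: starts at
#' 1 at 0 Gy, is non-increasing, and reaches 0 above the maximum dose.
#' The integral of the curve over dose equals the mean dose (within half
#' a bin).
#'
#' @inheritParams mean_dose
#' @param bin_width_Gy histogram bin width (default 0.5 Gy).
#' @return object of class `dvh`: data.frame with columns `dose_Gy` (bin
#'   edges) and `fraction` (volume fraction with dose >= edge).
#' @export
dvh <- function(d, mask, bin_width_Gy = 0.5) {
  stopifnot_grid(d, "dose")
  if (bin_width_Gy <= 0) stop("bin_width_Gy must be positive")
  m <- mask_values(mask, dim(d$values))
  if (!any(m)) stop("empty mask")
  x <- d$values[m]
  edges <- seq(0, (floor(max(x) / bin_width_Gy) + 1) * bin_width_Gy,
               by = bin_width_Gy)
  frac <- vapply(edges, function(e) mean(x >= e), numeric(1))
  structure(data.frame(dose_Gy = edges, fraction = frac),
            bin_width_Gy = bin_width_Gy, class = c("dvh", "data.frame"))
}

#' Mean dose implied by a DVH
#'
#' Trapezoidal integral of the cumulative curve; agrees with
#' [mean_dose] within half a bin.
#'
#' @param h a [dvh].
#' @return mean dose in Gy.
#' @export
dvh_mean <- function(h) {
  if (!inherits(h, "dvh")) stop("h must be a dvh")
  w <- attr(h, "bin_width_Gy")
  sum((h$fraction[-1] + h$fraction[-nrow(h)]) / 2) * w
}

#' Remainder VOIs by excluding a margin around the liver--lung interface
#'
#' The interface surface is the set of voxel faces where the liver and
#' lung masks are 6-adjacent. A voxel is excluded when the Euclidean
#' distance from its centre to the nearest face centre is within the
#' margin; the remainder masks keep the rest. On a planar interface with
#' 4.8 mm voxels a 30 mm margin excludes exactly the 6 voxel layers with
#' centres at 2.4 ... 28.8 mm on each side.
#'
#' @param liver_mask,lung_mask disjoint 0/1 [voxel_grid] masks.
#' @param margin_mm exclusion margin in mm (>= 0).
#' @return list of [voxel_grid] masks: `remainder_liver`,
#'   `remainder_lung`, `excluded_liver`, `excluded_lung`. A warning is
#'   issued when the masks are nowhere adjacent (empty exclusion).
#' @export
interface_exclusion <- function(liver_mask, lung_mask, margin_mm) {
  stopifnot_grid(liver_mask, "liver_mask")
  stopifnot_congruent(liver_mask, lung_mask, "masks")
  if (margin_mm < 0) stop("margin must be >= 0")
  dims <- dim(liver_mask$values)
  lv <- liver_mask$values > 0
  lg <- lung_mask$values > 0
  if (any(lv & lg)) stop("liver and lung masks overlap")
  faces <- interface_face_centres(as.integer(lv), as.integer(lg),
                                  as.integer(dims))
  out_mask <- function(keep) with_values(liver_mask, array(as.numeric(keep), dims))
  if (nrow(faces) == 0L) {
    warning("liver and lung masks are nowhere adjacent: empty exclusion")
    return(list(remainder_liver = out_mask(lv), remainder_lung = out_mask(lg),
                excluded_liver = out_mask(lv & FALSE),
                excluded_lung = out_mask(lg & FALSE)))
  }
  sp <- liver_mask$spacing
  faces_mm <- sweep(faces, 2, sp, "*")
  near <- function(m) {
    idx <- which(m, arr.ind = TRUE)
    q <- sweep(idx - 1, 2, sp, "*")
    d <- min_distance_to_points(q, faces_mm)
    excl <- logical(length(m)); dim(excl) <- dims
    excl[idx[d <= margin_mm, , drop = FALSE]] <- TRUE
    excl
  }
  ex_lv <- near(lv); ex_lg <- near(lg)
  list(remainder_liver = out_mask(lv & !ex_lv),
       remainder_lung = out_mask(lg & !ex_lg),
       excluded_liver = out_mask(ex_lv),
       excluded_lung = out_mask(ex_lg))
}

#' Sensitivity of original VOI mean dose to interface exclusion
#'
#' Ordinary least squares of the original VOI mean doses (y) on the
#' remainder VOI mean doses (x) across a cohort, as used to quantify how
#' strongly a VOI's reported mean dose depends on segmentation near the
#' liver--lung interface; also reports the mean percent change of the
#' remainder relative to the original.
#'
#' @param originals,remainders equal-length numeric vectors (>= 2) of
#'   mean doses in Gy.
#' @return object of class `sensitivity_fit`: list with `slope`,
#'   `intercept`, `r_squared`, `mean_pct_change`, `n`.
#' @export
sensitivity_fit <- function(originals, remainders) {
  if (length(originals) != length(remainders))
    stop("originals and remainders must have equal length")
  if (length(originals) < 2L) stop("need at least 2 samples")
  if (sd(remainders) == 0) stop("degenerate remainder variance")
  fit <- lm(originals ~ remainders)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((originals - mean(originals))^2)
  structure(list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
    mean_pct_change = mean(100 * (remainders - originals) / originals),
    n = length(originals)
  ), class = "sensitivity_fit")
}

#' @export
print.sensitivity_fit <- function(x, ...) {
  cat(sprintf(
    "<sensitivity_fit> n=%d: original = %.3f * remainder + %.3f (R^2 %.3f); mean change %+.1f%%\n",
    x$n, x$slope, x$intercept, x$r_squared, x$mean_pct_change))
  invisible(x)
}

#' Segment a lung-like region by threshold-connected region growing
#'
#' Returns the 6-connected component of voxels with density at or below
#' the threshold that contains the seed; a lightweight stand-in for
#' interactive region-growing lung segmentation.
#'
#' @param density a [voxel_grid] in g/cc.
#' @param seed_voxel integer c(i, j, k) (1-based) inside the
#'   below-threshold region.
#' @param threshold density threshold in g/cc (default 0.7, the upper
#'   lung bound of the default material ranges).
#' @return a 0/1 [voxel_grid] mask.
#' @export
segment_lung_by_threshold <- function(density, seed_voxel, threshold = 0.7) {
  stopifnot_grid(density, "density")
  dims <- dim(density$values)
  s <- as.integer(seed_voxel)
  if (length(s) != 3L || any(s < 1L) || any(s > dims))
    stop("seed voxel out of bounds")
  if (density$values[s[1], s[2], s[3]] > threshold)
    stop("seed voxel is above the density threshold")
  sel <- as.integer(density$values <= threshold)
  seed0 <- (s[3] - 1L) * dims[1] * dims[2] + (s[2] - 1L) * dims[1] + s[1] - 1L
  lab <- flood_fill6(sel, as.integer(dims), seed0)
  with_values(density, array(as.numeric(lab), dims))
}
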