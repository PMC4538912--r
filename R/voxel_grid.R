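#' Construct a voxel grid
#'
#' The shared container for all 3D scalar fields in the package: activity
#' (Bq), counts, disintegrations, density (g/cc), material labels, dose
#' (Gy) and binary masks. A grid is a 3D array plus an isotropic-or-not
#' spacing in mm and the world coordinate (mm) of the centre of voxel
#' `(1,1,1)`. Indices are interpreted so that the world position of voxel
#' `(i,j,k)` (1-based in R) is `origin + (c(i,j,k) - 1) * spacing`.
#'
#' @param values numeric 3D array.
#' @param spacing voxel spacing in mm; scalar (isotropic) or length 3.
#' @param origin world coordinate (mm) of the first voxel centre; length 3.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(array(0, c(4, 4, 4)), spacing = 4.8)
#' dim(g$values)
#' @export
voxel_grid <- function(values, spacing = 4.8, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("not a 3D volume: `values` must be a 3D array")
  if (any(dim(values) < 1L)) stop("all dims must be positive")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 1 or 3 positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values (mm)")
  structure(
    list(values = values, spacing = as.numeric(spacing),
         origin = as.numeric(origin)),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_grid> %d x %d x %d, spacing %s mm, origin (%s) mm\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = " x "),
              paste(signif(x$origin, 4), collapse = ", ")))
  rng <- range(x$values)
  cat(sprintf("  values in [%.6g, %.6g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$values)

is_voxel_grid <- function(x) inherits(x, "voxel_grid")

stopifnot_grid <- function(x, what = "input") {
  if (!is_voxel_grid(x)) stop(sprintf("%s must be a voxel_grid", what))
  invisible(x)
}

#' Test whether a grid has isotropic spacing
#'
#' Kernel-based engines require isotropic voxels (the voxel kernel is built
#' on a cubic lattice); they check this rather than assume it.
#'
#' @param grid a [voxel_grid].
#' @param tol relative tolerance on spacing differences.
#' @return logical scalar.
#' @export
is_isotropic <- function(grid, tol = 1e-6) {
  stopifnot_grid(grid)
  s <- grid$spacing
  diff(range(s)) <= tol * mean(s)
}

stopifnot_isotropic <- function(grid, engine = "this engine") {
  if (!is_isotropic(grid))
    stop(sprintf("%s requires an isotropic grid; spacing is (%s) mm",
                 engine, paste(signif(grid$spacing, 6), collapse = ", ")))
  invisible(grid)
}

stopifnot_congruent <- function(a, b, what = "grids") {
  stopifnot_grid(a); stopifnot_grid(b)
  if (!identical(dim(a$values), dim(b$values)))
    stop(sprintf("%s are not co-registered: dims differ", what))
  if (max(abs(a$spacing - b$spacing)) > 1e-6)
    stop(sprintf("%s are not co-registered: spacing differs", what))
  invisible(TRUE)
}

#' Voxel volume in cubic centimetres
#'
#' @param grid a [voxel_grid].
#' @return scalar voxel volume in cc (spacing is mm, so `prod(spacing)/1000`).
#' @export
voxel_volume_cc <- function(grid) {
  stopifnot_grid(grid)
  prod(grid$spacing) / 1000
}

#' World coordinates of voxel centres along one axis
#'
#' @param grid a [voxel_grid].
#' @param axis 1, 2 or 3.
#' @return numeric vector of mm positions of voxel centres along `axis`.
#' @export
axis_coords <- function(grid, axis) {
  stopifnot_grid(grid)
  n <- dim(grid$values)[axis]
  grid$origin[axis] + (seq_len(n) - 1) * grid$spacing[axis]
}

#' Replace the values of a grid, keeping its geometry
#'
#' @param grid a [voxel_grid].
#' @param values array with the same dimensions.
#' @return a new [voxel_grid].
#' @export
with_values <- function(grid, values) {
  stopifnot_grid(grid)
  if (!identical(dim(values), dim(grid$values)))
    stop("replacement values must match grid dims")
  voxel_grid(values, grid$spacing, grid$origin)
}
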