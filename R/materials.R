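#' CT-number to density lookup table
#'
#' A piecewise-linear map from CT numbers (HU) to mass density in g/cc.
#' The scanner- and technique-specific table used clinically is built from
#' electron-density phantom scans; the default shipped here is a generic
#' two-segment table (air at -1000 HU, water-like tissue at 0 HU, dense
#' bone at 3000 HU) intended for synthetic data and testing, and should be
#' replaced with a measured table for real scanners.
#'
#' @param hu numeric vector of CT numbers, strictly increasing.
#' @param density matching densities in g/cc, all non-negative.
#' @return an object of class `density_lut`.
#' @examples
#' lut <- default_density_lut()
#' hu_to_density(voxel_grid(array(0, c(2, 2, 2))), lut)$values[1]
#' @export
density_lut <- function(hu, density) {
  if (length(hu) < 2L) stop("empty or degenerate lut: need at least 2 knots")
  if (length(hu) != length(density)) stop("hu and density lengths differ")
  if (any(diff(hu) <= 0)) stop("CT numbers must be strictly increasing")
  if (any(density < 0)) stop("densities must be non-negative")
  structure(list(hu = as.numeric(hu), density = as.numeric(density)),
            class = "density_lut")
}

#' @rdname density_lut
#' @export
default_density_lut <- function() {
  density_lut(hu = c(-1000, 0, 3000), density = c(0.001, 1.000, 2.90))
}

#' Convert a CT volume to density via a piecewise-linear LUT
#'
#' CT numbers outside the table are clamped to its end knots, so the
#' output is always within the table's density range (and hence >= 0).
#'
#' @param ct a [voxel_grid] of CT numbers.
#' @param lut a [density_lut]; defaults to [default_density_lut()].
#' @return a [voxel_grid] of densities in g/cc.
#' @export
hu_to_density <- function(ct, lut = default_density_lut()) {
  stopifnot_grid(ct, "ct")
  if (!inherits(lut, "density_lut")) stop("lut must be a density_lut")
  rho <- approx(lut$hu, lut$density, xout = as.numeric(ct$values),
                rule = 2, ties = "ordered")$y
  with_values(ct, array(rho, dim = dim(ct$values)))
}

#' Material thresholds for the four-material density mapping
#'
#' Boundaries of the contiguous half-open density ranges
#' `[0, air_lung) -> air`, `[air_lung, lung_soft) -> lung`,
#' `[lung_soft, soft_bone) -> soft_tissue`, `[soft_bone, Inf) -> bone`.
#' The defaults bracket the reference lung (0.26 g/cc) and soft-tissue
#' (1.04 g/cc) densities used everywhere else in the package.
#'
#' @param air_lung,lung_soft,soft_bone boundary densities in g/cc,
#'   strictly increasing.
#' @return a named numeric vector of class `material_thresholds`.
#' @export
material_thresholds <- function(air_lung = 0.05, lung_soft = 0.70,
                                soft_bone = 1.50) {
  b <- c(air_lung = air_lung, lung_soft = lung_soft, soft_bone = soft_bone)
  if (any(!is.finite(b)) || any(b <= 0) || any(diff(b) <= 0))
    stop("thresholds must be positive, finite and strictly increasing")
  structure(b, class = "material_thresholds")
}

#' Map a density volume to the four dosimetry materials
#'
#' Every voxel is assigned exactly one of `air`, `lung`, `soft_tissue` or
#' `bone` by the half-open density ranges in `thresholds`; the mapping is
#' total on `[0, Inf)`.
#'
#' @param rho a [voxel_grid] of densities in g/cc (non-negative).
#' @param thresholds a [material_thresholds] object.
#' @return a [voxel_grid] whose values are integer codes 1:4 with a
#'   `materials` attribute naming them; use [material_labels] for the
#'   character form.
#' @export
density_to_material <- function(rho, thresholds = material_thresholds()) {
  stopifnot_grid(rho, "rho")
  if (!inherits(thresholds, "material_thresholds"))
    stop("thresholds must come from material_thresholds()")
  v <- rho$values
  if (any(!is.finite(v)) || any(v < 0))
    stop("densities must be finite and non-negative")
  code <- array(findInterval(v, c(0, unname(thresholds))), dim = dim(v))
  out <- with_values(rho, code)
  attr(out, "materials") <- c("air", "lung", "soft_tissue", "bone")
  class(out) <- c("material_map", class(out))
  out
}

#' Material labels of a material map
#'
#' @param m a material map from [density_to_material].
#' @return character array of labels, same dims as the map.
#' @export
material_labels <- function(m) {
  if (!inherits(m, "material_map")) stop("m must be a material_map")
  array(attr(m, "materials")[m$values], dim = dim(m$values))
}

#' Read materials and density-LUT configuration from YAML or JSON
#'
#' Recognised sections: `materials:` with keys `air_lung`, `lung_soft`,
#' `soft_bone` (g/cc) and `density_lut:` with parallel lists `hu` and
#' `density`.
#'
#' @param path configuration file (`.yaml`/`.yml`/`.json`).
#' @return list with elements `thresholds` ([material_thresholds]) and
#'   `lut` ([density_lut]); missing sections fall back to defaults.
#' @export
read_materials_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file does not exist: %s", path))
  cfg <- if (grepl("\\.json$", tolower(path))) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  thresholds <- if (!is.null(cfg$materials))
    do.call(material_thresholds, cfg$materials[c("air_lung", "lung_soft", "soft_bone")])
  else material_thresholds()
  lut <- if (!is.null(cfg$density_lut))
    density_lut(unlist(cfg$density_lut$hu), unlist(cfg$density_lut$density))
  else default_density_lut()
  list(thresholds = thresholds, lut = lut)
}
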