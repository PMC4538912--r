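#' Physical constants for yttrium-90 dosimetry
#'
#' Decay and transport constants used throughout the package. All engines
#' share this single set so that unit conversions happen in exactly one
#' place.
#'
#' @return A list with components:
#' \describe{
#'   \item{E_avg_MeV}{mean beta energy per disintegration, 0.937 MeV.}
#'   \item{T_half_h}{physical half-life, 64.1 h.}
#'   \item{E_max_MeV}{beta endpoint energy, 2.28 MeV.}
#'   \item{R_max_soft_mm}{maximum beta range in reference soft tissue, 11 mm.}
#'   \item{rho_ref}{reference soft-tissue density, 1.04 g/cc.}
#'   \item{rho_lung_ref}{reference lung density, 0.26 g/cc.}
#'   \item{gy_per_mev_per_g}{1 MeV/g expressed in Gy, 1.602176e-10.}
#' }
#' @examples
#' y90_constants()$E_avg_MeV
#' @export
y90_constants <- function() {
  list(
    E_avg_MeV = 0.937,
    T_half_h = 64.1,
    E_max_MeV = 2.28,
    R_max_soft_mm = 11,
    rho_ref = 1.04,
    rho_lung_ref = 0.26,
    gy_per_mev_per_g = 1.602176e-10
  )
}

#' Maximum beta range in a medium of given density
#'
#' The beta range scales inversely with density: a maximum range of 11 mm
#' in reference soft tissue (1.04 g/cc) stretches to 44 mm in lung at
#' 0.26 g/cc.
#'
#' @param rho density in g/cc (positive scalar or vector).
#' @return range in mm.
#' @examples
#' y90_range_mm(1.04) # 11
#' y90_range_mm(0.26) # 44
#' @export
y90_range_mm <- function(rho) {
  if (any(rho <= 0)) stop("density must be positive")
  pc <- y90_constants()
  pc$R_max_soft_mm * pc$rho_ref / rho
}
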