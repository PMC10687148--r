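#' Physical constants and unit conversions
#'
#' Single source of physical constants used throughout the package.
#' Internal units are nm, ps, K and bar; compressibilities are reported in
#' Pa^-1 (SI) and bar^-1.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant, 1.380649e-23 J/K (exact, SI).}
#'   \item{nm3_to_m3}{Volume conversion nm^3 -> m^3, 1e-27.}
#'   \item{per_nm3_to_per_m3}{Number-density conversion nm^-3 -> m^-3, 1e27.}
#'   \item{Pa_per_bar}{Pressure conversion, 1 bar = 1e5 Pa.}
#' }
#' @export
fluct_constants <- list(
  kB = 1.380649e-23,
  nm3_to_m3 = 1e-27,
  per_nm3_to_per_m3 = 1e27,
  Pa_per_bar = 1e5
)
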