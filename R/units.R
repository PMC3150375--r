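#' Unit conversion helpers
#'
#' The package computes internally in SI (m, s, mol, Pa) but all public
#' interfaces accept and report the units conventional in microfluidic cell
#' culture: micrometres for chamber dimensions, microlitres per hour for flow
#' rates, cm^2/s for diffusivities, M^-1 s^-1 for association rates and
#' dyn/cm^2 for shear stress. These converters are exported so that scripts
#' can stay in reporting units throughout.
#'
#' @param x numeric value(s) in the source unit.
#' @return numeric value(s) in the destination unit.
#' @name units
NULL

#' @rdname units
#' @export
um_to_m <- function(x) x * 1e-6

#' @rdname units
#' @export
m_to_mm <- function(x) x * 1e3

#' @rdname units
#' @export
ul_per_hr_to_m3_per_s <- function(x) x * 1e-9 / 3600

#' @rdname units
#' @export
cm2_per_s_to_m2_per_s <- function(x) x * 1e-4

#' @rdname units
#' @export
per_M_s_to_m3_per_mol_s <- function(x) x * 1e-3

#' @rdname units
#' @export
pa_to_dyn_per_cm2 <- function(x) x * 10

#' Avogadro constant (mol^-1), CODATA exact value.
#' @export
N_AVOGADRO <- 6.02214076e23

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
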