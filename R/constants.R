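# Physical constants (CODATA 2018) and the pinned atomic-weight table.
# All user-facing energies are molar (J/mol); per-molecule conversions are
# internal and always go through these constants.

#' Physical constants used throughout
#'
#' @format A list with elements:
#' \describe{
#'   \item{R}{molar gas constant, J mol^-1 K^-1}
#'   \item{kB}{Boltzmann constant, J K^-1}
#'   \item{N_A}{Avogadro constant, mol^-1}
#' }
#' @export
sk_constants <- list(
  R  = 8.314462618,
  kB = 1.380649e-23,
  N_A = 6.02214076e23
)

# IUPAC 2021 standard atomic weights, abridged to 5 significant figures.
# Covers the elements of common organic / pharmaceutical solids.
.atomic_weights <- c(
  H = 1.008,   He = 4.0026, Li = 6.94,   Be = 9.0122, B = 10.81,
  C = 12.011,  N = 14.007,  O = 15.999,  F = 18.998,  Ne = 20.180,
  Na = 22.990, Mg = 24.305, Al = 26.982, Si = 28.085, P = 30.974,
  S = 32.06,   Cl = 35.45,  Ar = 39.95,  K = 39.098,  Ca = 40.078,
  Fe = 55.845, Cu = 63.546, Zn = 65.38,  Br = 79.904, I = 126.90
)

# temperature helpers ---------------------------------------------------

#' Convert a temperature to kelvin
#'
#' Temperatures are accepted with an explicit unit tag; there is no
#' autodetection of degrees Celsius versus kelvin.
#'
#' @param x numeric temperature(s)
#' @param unit `"K"` or `"C"`
#' @return temperature in kelvin
#' @examples
#' as_kelvin(25.2, "C")
#' @export
as_kelvin <- function(x, unit = c("K", "C")) {
  unit <- match.arg(unit)
  if (unit == "C") x + 273.15 else x
}

# internal validators ---------------------------------------------------

.check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be finite and strictly positive", name),
         call. = FALSE)
  }
  invisible(x)
}

.check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("`%s` must be finite and non-negative", name), call. = FALSE)
  }
  invisible(x)
}
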