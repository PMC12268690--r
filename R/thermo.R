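# Closed-form thermodynamic and kinetic-coefficient relations:
# supersaturation, van 't Hoff fitting, Gibbs-energy/solubility
# interconversion, equilibrium kink density, 2D-nucleation barrier, and the
# face growth rate R = h v / l.
#
# Conventions (documented prominently):
#  * Crystallization sign convention: quantities describe solution -> crystal,
#    so a soluble compound that releases heat on crystallizing has
#    ΔH°cryst < 0 and (here) ΔS°cryst < 0.
#  * Equilibrium constant on the molarity scale with unit activity
#    coefficients: Kcryst = 1/Ce, hence ΔG°cryst = RT ln Ce.
#  * All user-facing energies are molar (J/mol).

#' Dimensionless crystallization driving force
#'
#' The driving force for crystallization is the excess chemical potential of
#' the solute over its equilibrium value, \eqn{\Delta\mu/k_BT = \ln(C/C_e)}.
#' Positive for supersaturation, zero at equilibrium, negative for
#' undersaturation.
#'
#' @param C solute concentration, mol/L
#' @param Ce equilibrium concentration (solubility), mol/L
#' @return dimensionless driving force \eqn{\ln(C/C_e)}
#' @examples
#' supersaturation(16.7e-3, 13.5e-3)
#' @export
supersaturation <- function(C, Ce) {
  .check_positive(C, "C")
  .check_positive(Ce, "Ce")
  log(C / Ce)
}

#' Construct a table of solubility observations
#'
#' @param temperature_K temperatures, kelvin
#' @param solubility_mol_per_L equilibrium concentrations, mol/L
#' @param sd optional measurement standard deviations, mol/L
#' @return a `data.frame` of class `solubility_points`
#' @export
solubility_points <- function(temperature_K, solubility_mol_per_L, sd = NULL) {
  .check_positive(temperature_K, "temperature_K")
  .check_positive(solubility_mol_per_L, "solubility_mol_per_L")
  if (length(temperature_K) != length(solubility_mol_per_L)) {
    stop("temperature and solubility must have equal length", call. = FALSE)
  }
  if (!is.null(sd)) .check_nonneg(sd, "sd")
  out <- data.frame(temperature_K = temperature_K,
                    solubility_mol_per_L = solubility_mol_per_L)
  out$sd <- if (is.null(sd)) NA_real_ else sd
  class(out) <- c("solubility_points", "data.frame")
  out
}

#' Van 't Hoff analysis of solubility versus temperature
#'
#' Fits \eqn{\ln C_e} against \eqn{1/T} by (optionally weighted) ordinary
#' least squares. Under the molarity-scale ideal-solution convention
#' \eqn{K_{cryst} = C_e^{-1}} and van 't Hoff's law
#' \eqn{\partial \ln C_e / \partial(1/T) = \Delta H^\circ_{cryst}/R}, the
#' slope times the gas constant is the crystallization enthalpy and the
#' intercept is \eqn{-\Delta S^\circ_{cryst}/R}.
#'
#' @param points a `solubility_points` table (or data.frame with columns
#'   `temperature_K`, `solubility_mol_per_L`, optionally `sd`)
#' @param weighted if `TRUE` and `sd` is available, weight by
#'   \eqn{1/\sigma^2_{\ln Ce}} with \eqn{\sigma_{\ln Ce} = sd/Ce}
#' @param reference_temperature_K temperature at which the fitted
#'   \eqn{\Delta G^\circ} is reported (default 298.15 K)
#' @return an object of class `thermo_params`: list with `enthalpy_J_mol`,
#'   `entropy_J_mol_K`, standard errors, `gibbs_J_mol` at the reference
#'   temperature, `r_squared`, `residuals`
#' @examples
#' pts <- gen_solubility(seed = 1, rel_noise = 0)
#' fit_vant_hoff(pts)
#' @export
fit_vant_hoff <- function(points, weighted = FALSE,
                          reference_temperature_K = 298.15) {
  T_K <- points$temperature_K
  Ce <- points$solubility_mol_per_L
  .check_positive(T_K, "temperature_K")
  .check_positive(Ce, "solubility_mol_per_L")
  if (length(unique(T_K)) < 2) {
    stop("van 't Hoff fit needs at least 2 distinct temperatures",
         call. = FALSE)
  }
  w <- NULL
  if (weighted) {
    if (is.null(points$sd) || any(is.na(points$sd)) || any(points$sd <= 0)) {
      stop("weighted fit requested but no positive `sd` column present",
           call. = FALSE)
    }
    w <- (Ce / points$sd)^2  # var(ln Ce) ~ (sd/Ce)^2
  }
  df <- data.frame(y = log(Ce), x = 1 / T_K)
  fit <- if (is.null(w)) lm(y ~ x, data = df) else lm(y ~ x, data = df, weights = w)
  sm <- suppressWarnings(summary(fit))  # noiseless data: benign perfect-fit warning
  cf <- sm$coefficients
  Rgas <- sk_constants$R
  dH <- cf["x", "Estimate"] * Rgas
  dS <- -cf["(Intercept)", "Estimate"] * Rgas
  out <- list(
    enthalpy_J_mol = dH,
    entropy_J_mol_K = dS,
    enthalpy_se = cf["x", "Std. Error"] * Rgas,
    entropy_se = cf["(Intercept)", "Std. Error"] * Rgas,
    reference_temperature_K = reference_temperature_K,
    gibbs_J_mol = dH - reference_temperature_K * dS,
    r_squared = sm$r.squared,
    residuals = unname(stats::residuals(fit)),
    n = length(T_K),
    weighted = weighted
  )
  class(out) <- "thermo_params"
  out
}

#' @export
print.thermo_params <- function(x, ...) {
  cat("Van 't Hoff crystallization thermodynamics (molarity scale)\n")
  cat(sprintf("  dH0cryst = %.2f +/- %.2f kJ/mol\n",
              x$enthalpy_J_mol / 1e3, x$enthalpy_se / 1e3))
  cat(sprintf("  dS0cryst = %.2f +/- %.2f J/mol/K\n",
              x$entropy_J_mol_K, x$entropy_se))
  cat(sprintf("  dG0cryst(%.2f K) = %.2f kJ/mol\n",
              x$reference_temperature_K, x$gibbs_J_mol / 1e3))
  cat(sprintf("  n = %d, R^2 = %.5f\n", x$n, x$r_squared))
  invisible(x)
}

#' Crystallization Gibbs energy from solubility
#'
#' \eqn{\Delta G^\circ_{cryst} = -RT \ln K_{cryst} = RT \ln C_e} on the
#' molarity scale with unit activity coefficients.
#'
#' @param Ce solubility, mol/L
#' @param T_K temperature, kelvin
#' @return Gibbs energy of crystallization, J/mol (negative for Ce < 1 M)
#' @examples
#' gibbs_from_solubility(13.5e-3, as_kelvin(25.2, "C")) / 1e3  # kJ/mol
#' @export
gibbs_from_solubility <- function(Ce, T_K) {
  .check_positive(Ce, "Ce")
  .check_positive(T_K, "T_K")
  sk_constants$R * T_K * log(Ce)
}

#' Gibbs energy from enthalpy and entropy
#'
#' @param dH_J_mol enthalpy, J/mol
#' @param dS_J_mol_K entropy, J/mol/K
#' @param T_K temperature, kelvin
#' @return \eqn{\Delta H - T \Delta S}, J/mol
#' @export
gibbs_from_hs <- function(dH_J_mol, dS_J_mol_K, T_K) {
  .check_positive(T_K, "T_K")
  dH_J_mol - T_K * dS_J_mol_K
}

#' Solubility from crystallization enthalpy and entropy
#'
#' Inverse of [gibbs_from_solubility()]:
#' \eqn{C_e = \exp[(\Delta H - T\Delta S)/(RT)]}.
#'
#' @inheritParams gibbs_from_hs
#' @return solubility, mol/L
#' @export
solubility_from_thermo <- function(dH_J_mol, dS_J_mol_K, T_K) {
  .check_positive(T_K, "T_K")
  expo <- (dH_J_mol - T_K * dS_J_mol_K) / (sk_constants$R * T_K)
  if (any(expo > 700)) {
    stop("solubility overflow: exponent exceeds numerical range", call. = FALSE)
  }
  exp(expo)
}

#' Equilibrium kink density of a step (restricted solid-on-solid)
#'
#' For a step whose column height differences are restricted to
#' \{-1, 0, +1\}, the equilibrium density of kinks per molecular site is
#' \deqn{\bar n_k^{-1} = \frac{2}{\exp(\omega/k_BT) + 2},}
#' where \eqn{\omega} is the kink formation energy. The density lies in
#' (0, 2/3]; the zero-energy limit is 2/3 and it decreases monotonically
#' with \eqn{\omega}.
#'
#' @param omega_J_mol kink energy, J/mol (molar convention; must be >= 0)
#' @param T_K temperature, kelvin
#' @return kinks per molecular site, in (0, 2/3]
#' @examples
#' equilibrium_kink_density(4e3, 298.15)  # ~0.285, below the 0.3 entropic cap
#' @export
equilibrium_kink_density <- function(omega_J_mol, T_K) {
  .check_nonneg(omega_J_mol, "omega_J_mol")
  .check_positive(T_K, "T_K")
  2 / (exp(omega_J_mol / (sk_constants$R * T_K)) + 2)
}

#' Kink density of an explicit step configuration
#'
#' Counts kinks (unit height changes between adjacent step sites) per site of
#' a discrete step profile. The zero-entropy alternating configuration
#' (two molecules, two vacancies) counts to exactly 0.5.
#'
#' @param heights integer column heights along the step
#' @param periodic treat the profile as periodic (default `TRUE`)
#' @return kinks per site
#' @examples
#' profile_kink_density(rep(c(1L, 1L, 0L, 0L), 8))  # 0.5
#' @export
profile_kink_density <- function(heights, periodic = TRUE) {
  if (length(heights) < 2) stop("need at least 2 sites", call. = FALSE)
  d <- diff(heights)
  if (periodic) d <- c(d, heights[1] - heights[length(heights)])
  sum(abs(d)) / length(heights)
}

#' Free-energy barrier for 2D nucleation of a new layer
#'
#' \deqn{\Delta G^*_{2D} = \pi \Omega h \gamma^2 / \Delta\mu,}
#' the barrier for nucleating a disk-shaped island of thickness `h` with
#' edge free energy \eqn{\gamma} at per-molecule driving force
#' \eqn{\Delta\mu}. The formula is dimensionally consistent with
#' \eqn{\gamma} expressed per unit edge *area* (J/m^2); a per-unit-length
#' edge energy (J/m) may be supplied instead via `gamma_unit`, in which case
#' it is converted by dividing by the layer thickness.
#'
#' @param molecular_volume_A3 molecular volume \eqn{\Omega}, cubic angstrom
#' @param layer_thickness_nm layer thickness `h`, nm
#' @param edge_free_energy edge free energy \eqn{\gamma}; J/m^2 by default
#' @param driving_force_J per-molecule driving force \eqn{\Delta\mu}, J
#'   (must be > 0; no barrier is defined at or below equilibrium)
#' @param gamma_unit `"per_area"` (J/m^2, default) or `"per_length"` (J/m)
#' @return barrier height, J (per nucleus)
#' @export
nucleation_barrier_2d <- function(molecular_volume_A3, layer_thickness_nm,
                                  edge_free_energy, driving_force_J,
                                  gamma_unit = c("per_area", "per_length")) {
  gamma_unit <- match.arg(gamma_unit)
  .check_positive(molecular_volume_A3, "molecular_volume_A3")
  .check_positive(layer_thickness_nm, "layer_thickness_nm")
  .check_positive(edge_free_energy, "edge_free_energy")
  if (any(driving_force_J <= 0)) {
    stop("`driving_force_J` must be > 0: no 2D nucleation barrier is defined at or below equilibrium",
         call. = FALSE)
  }
  Omega <- molecular_volume_A3 * 1e-30   # m^3
  h <- layer_thickness_nm * 1e-9         # m
  gamma <- if (gamma_unit == "per_length") edge_free_energy / h else edge_free_energy
  pi * Omega * h * gamma^2 / driving_force_J
}

#' Face growth rate from step flow
#'
#' \eqn{R = h v / l}: a face advances by step height `h` each time a step
#' sweeps past, at step velocity `v` and inter-step separation `l`
#' (\eqn{l^{-1}} is the step density).
#'
#' @param h_nm step height, nm
#' @param v_nm_s step velocity, nm/s
#' @param l_nm inter-step separation, nm
#' @return face growth rate, nm/s
#' @examples
#' face_growth_rate(2.413, 1.0, 241.3)
#' @export
face_growth_rate <- function(h_nm, v_nm_s, l_nm) {
  .check_positive(h_nm, "h_nm")
  .check_positive(l_nm, "l_nm")
  if (!is.numeric(v_nm_s) || any(!is.finite(v_nm_s))) {
    stop("`v_nm_s` must be finite", call. = FALSE)
  }
  h_nm * v_nm_s / l_nm
}
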