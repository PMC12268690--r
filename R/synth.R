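# Seeded generators emulating every measured input of the study: solubility
# versus temperature series, AFM height-map series with full and half steps,
# step velocity versus concentration tables, absorbance series with optional
# dimerization, and groove-etched lattices for healing runs.
#
# Every generator is a pure function of (parameters, seed) and emits ground
# truth alongside the data (as attributes or a `manifest`), so recovery
# tests can close the loop. Noise models: lognormal multiplicative for
# concentrations/solubilities, Gaussian additive for heights and velocities.
# Default parameters mimic the scales of the emulated experiment (Ce near
# 13.5 mM at room temperature, velocities 0.1-10 nm/s, steps 2.413/1.2065
# nm) and are synthetic throughout.

#' Generate solubility-versus-temperature observations
#'
#' \eqn{C_e(T) = \exp[(\Delta H - T\Delta S)/RT]} times lognormal
#' multiplicative noise. Default temperatures emulate measurement batches at
#' 10, 15, 20 and 27 degrees Celsius.
#'
#' @param dH_J_mol generating crystallization enthalpy, J/mol
#' @param dS_J_mol_K generating entropy, J/mol/K
#' @param temperatures_K observation temperatures, kelvin
#' @param rel_noise relative (lognormal sigma) noise; 0 for noiseless
#' @param n_rep replicate measurements per temperature
#' @param seed RNG seed (mandatory)
#' @return a [solubility_points()] table with attributes `truth` (list of
#'   generating parameters) and per-temperature `sd` when `n_rep > 1`
#' @export
gen_solubility <- function(dH_J_mol = -20.5e3, dS_J_mol_K = -34.0,
                           temperatures_K = as_kelvin(c(10, 15, 20, 27), "C"),
                           rel_noise = 0.03, n_rep = 5, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  .check_nonneg(rel_noise, "rel_noise")
  set.seed(seed)
  truth <- solubility_from_thermo(dH_J_mol, dS_J_mol_K, temperatures_K)
  obs <- vapply(seq_along(temperatures_K), function(i) {
    reps <- truth[i] * exp(rnorm(n_rep, 0, rel_noise))
    c(mean(reps), sd(reps))
  }, numeric(2))
  out <- solubility_points(temperatures_K, obs[1, ],
                           sd = if (n_rep > 1 && rel_noise > 0) obs[2, ] else NULL)
  attr(out, "truth") <- list(dH_J_mol = dH_J_mol, dS_J_mol_K = dS_J_mol_K,
                             Ce_true = truth, seed = seed)
  out
}

#' Generate an AFM-style height-map series with advancing steps
#'
#' Builds frames of a staircase surface: terraces separated by risers of
#' full (`a_nm`) or half (`a_nm/2`) height at positions advancing with
#' per-step velocities, plus Gaussian pixel noise and optional uniform
#' lateral drift. Heights are constant along image rows; the profile
#' direction (perpendicular to the steps) runs along columns.
#'
#' @param step_positions_nm initial riser positions, nm (increasing)
#' @param step_classes `"full"` or `"half"` per riser
#' @param velocities_nm_s advance velocity per riser, nm/s
#' @param a_nm full step height, nm
#' @param n_rows,n_cols frame dimensions, pixels
#' @param pixel_size_nm pixel size, nm
#' @param frame_times_s frame timestamps, s
#' @param noise_sd_nm Gaussian pixel noise, nm
#' @param drift_nm_s lateral drift of the whole image, nm/s
#' @param seed RNG seed (mandatory)
#' @return a [height_map_series()]; attribute `manifest` holds the ground
#'   truth (per-frame riser positions, classes, velocities)
#' @export
gen_height_series <- function(step_positions_nm, step_classes,
                              velocities_nm_s, a_nm = 2.413,
                              n_rows = 32L, n_cols = 256L,
                              pixel_size_nm = 4,
                              frame_times_s = seq(0, 90, by = 10),
                              noise_sd_nm = 0.05, drift_nm_s = 0, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  k <- length(step_positions_nm)
  stopifnot(length(step_classes) == k, length(velocities_nm_s) == k)
  if (!all(step_classes %in% c("full", "half"))) {
    stop("step classes must be 'full' or 'half'", call. = FALSE)
  }
  if (is.unsorted(step_positions_nm, strictly = TRUE)) {
    stop("initial step positions must be strictly increasing", call. = FALSE)
  }
  heights <- ifelse(step_classes == "full", a_nm, a_nm / 2)
  set.seed(seed)
  width_nm <- (n_cols - 1) * pixel_size_nm
  x <- (seq_len(n_cols) - 1) * pixel_size_nm
  truth <- vector("list", length(frame_times_s))
  frames <- vector("list", length(frame_times_s))
  for (f in seq_along(frame_times_s)) {
    t <- frame_times_s[f]
    pos <- step_positions_nm + velocities_nm_s * t + drift_nm_s * t
    if (k > 1 && any(diff(pos) <= 2 * pixel_size_nm)) {
      stop(sprintf("generator error: steps collide by frame %d", f),
           call. = FALSE)
    }
    if (any(pos < 4 * pixel_size_nm) || any(pos > width_nm - 4 * pixel_size_nm)) {
      stop(sprintf("generator error: step leaves the frame by frame %d", f),
           call. = FALSE)
    }
    # staircase descending toward larger x: height drops by `heights[j]`
    # after passing riser j
    prof <- rowSums(outer(x, pos, `<`) * rep(heights, each = n_cols))
    frame <- matrix(rep(prof, each = n_rows), nrow = n_rows)
    if (noise_sd_nm > 0) {
      frame <- frame + matrix(rnorm(n_rows * n_cols, 0, noise_sd_nm),
                              n_rows, n_cols)
    }
    frames[[f]] <- frame
    truth[[f]] <- data.frame(frame = f, time_s = t, position_nm = pos,
                             class = step_classes,
                             velocity_nm_s = velocities_nm_s)
  }
  out <- height_map_series(frames, pixel_size_nm, frame_times_s,
                           metadata = list(seed = seed, a_nm = a_nm))
  attr(out, "manifest") <- do.call(rbind, truth)
  out
}

#' Generate a step velocity versus concentration dataset
#'
#' \eqn{v = \beta (C/C_e - 1)^m} plus additive Gaussian noise with standard
#' deviation `rel_noise` times the true velocity.
#'
#' @param beta kinetic coefficient, nm/s
#' @param m kinetic order (1 linear, 2 kink-limited)
#' @param Ce solubility, mol/L
#' @param C_grid concentrations, mol/L
#' @param rel_noise relative noise level
#' @param seed RNG seed (mandatory)
#' @return a [vc_dataset()] with attribute `truth`
#' @export
gen_vc <- function(beta = 2.5, m = 1, Ce = 13.5e-3,
                   C_grid = Ce * c(1.05, 1.1, 1.2, 1.3, 1.4, 1.5, 1.7, 2.0),
                   rel_noise = 0.05, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  .check_nonneg(rel_noise, "rel_noise")
  set.seed(seed)
  x <- pmax(C_grid / Ce - 1, 0)
  v_true <- beta * x^m
  v <- v_true + rnorm(length(v_true), 0, rel_noise * abs(v_true))
  out <- vc_dataset(C_grid, v, Ce,
                    sd = if (rel_noise > 0) rel_noise * abs(v_true) else NULL,
                    direction_label = "synthetic")
  attr(out, "truth") <- list(beta = beta, m = m, Ce = Ce, seed = seed)
  out
}

#' Generate an absorbance-versus-concentration series
#'
#' Beer-Lambert absorbance of the monomer plus, when a dimerization constant
#' is given, a monomer-dimer speciation solved by mass balance
#' (\eqn{M + 2K M^2 = C}); monomers bound in dimers absorb with relative
#' strength `eta`.
#'
#' @param epsilon_l molar absorptivity times path length, AU/(mol/L)
#' @param C_grid total concentrations, mol/L
#' @param K_dimer dimerization constant \eqn{[D]/[M]^2}, L/mol (0 = none)
#' @param eta relative absorbance of a dimer-bound monomer
#' @param rel_noise relative Gaussian noise on absorbances
#' @param wavelength_nm metadata
#' @param seed RNG seed (mandatory)
#' @return an [absorbance_series()] with attribute `truth`
#' @export
gen_absorbance <- function(epsilon_l = 50, C_grid = seq(1e-3, 20e-3, by = 1e-3),
                           K_dimer = 0, eta = 0.6, rel_noise = 0.005,
                           wavelength_nm = 270, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  set.seed(seed)
  M <- vapply(C_grid, .monomer_conc, numeric(1), K = K_dimer)
  A_true <- epsilon_l * (M + eta * (C_grid - M))
  A <- A_true * (1 + rnorm(length(A_true), 0, rel_noise))
  out <- absorbance_series(C_grid, A, wavelength_nm)
  attr(out, "truth") <- list(epsilon_l = epsilon_l, K_dimer = K_dimer,
                             eta = eta, seed = seed,
                             dimer_fraction_max = (max(C_grid) -
                                                     .monomer_conc(max(C_grid), K_dimer)) / max(C_grid))
  out
}

#' Generate a groove-etched lattice fixture for healing runs
#'
#' A fully occupied lattice with a rectangular groove cleared by
#' [etch_groove()]; the manifest records the footprint and vacancy count.
#'
#' @param nrow,ncol lattice dimensions, sites
#' @param orientation groove long-axis direction, `"[001]"` or `"[010]"`
#' @param width groove width, sites
#' @param length groove length, sites (default spans the lattice)
#' @return list with `lattice` (etched, with footprint attribute) and
#'   `manifest` (orientation, width, length, vacancy count)
#' @export
gen_groove_fixture <- function(nrow = 64L, ncol = 64L,
                               orientation = c("[001]", "[010]"),
                               width = 6L, length = NULL) {
  orientation <- match.arg(orientation)
  full <- matrix(1L, nrow, ncol)
  etched <- etch_groove(full, orientation, width, length)
  fp <- attr(etched, "footprint")
  list(lattice = etched,
       manifest = list(orientation = orientation,
                       width = width,
                       length = base::length(fp$rows) * base::length(fp$cols) / width,
                       vacancies = sum(etched == 0)))
}
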