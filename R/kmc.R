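# Seeded wrappers around the rejection-free KMC engines, the
# detailed-balance audit, and the groove etch/heal experiments.
#
# The step-edge model is restricted solid-on-solid (|dh| <= 1) specifically
# because its equilibrium kink density is exactly 2/[exp(omega/kBT) + 2];
# the unrestricted model gives 2/[exp(omega/kBT) + 1] instead and is
# rejected. Direct incorporation is modeled as a constant attachment rate at
# every admissible edge site (3D supply abundance). All simulations work in
# lattice units; the physical mapping (site = b or c spacing, layer = a/2)
# is recorded only in metadata.

#' Configuration for a step-edge simulation
#'
#' @param edge_length periodic edge length, sites (>= 32)
#' @param omega_J_mol kink energy, J/mol
#' @param saturation_ratio C/Ce (1 = equilibrium)
#' @param temperature_K temperature, kelvin
#' @param attempt_frequency attempt frequency nu, 1/s
#' @param n_events number of KMC events
#' @param burn_frac fraction of events discarded as burn-in
#' @param boundary `"periodic"` (default; no ends, used for growth runs) or
#'   `"free"` (open-ended edge). Equilibrium kink statistics use free ends:
#'   on a periodic ring the winding constraint only admits kinks in +/-
#'   pairs, which suppresses the kink density below the thermodynamic
#'   formula whenever `edge_length * exp(-omega/RT)` is not large, whereas a
#'   free edge realizes the independent-bond ensemble of the formula exactly.
#' @param seed RNG seed (mandatory)
#' @return list of class `step_sim_config`
#' @export
step_sim_config <- function(edge_length = 128L, omega_J_mol = 4e3,
                            saturation_ratio = 1, temperature_K = 298.15,
                            attempt_frequency = 1, n_events = 2e5,
                            burn_frac = 0.25,
                            boundary = c("periodic", "free"), seed) {
  boundary <- match.arg(boundary)
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (edge_length < 32) stop("edge_length must be >= 32", call. = FALSE)
  .check_nonneg(omega_J_mol, "omega_J_mol")
  .check_nonneg(saturation_ratio, "saturation_ratio")
  .check_positive(n_events, "n_events")
  structure(list(edge_length = as.integer(edge_length),
                 omega_J_mol = omega_J_mol,
                 saturation_ratio = saturation_ratio,
                 temperature_K = temperature_K,
                 attempt_frequency = attempt_frequency,
                 n_events = n_events, burn_frac = burn_frac,
                 boundary = boundary, seed = as.integer(seed)),
            class = "step_sim_config")
}

#' Audit detailed balance of the step-edge rate catalog
#'
#' Enumerates all nine local configurations (left and right height
#' differences in \{-1, 0, +1\}) and checks that, for every admissible
#' attach move, the forward/backward rate ratio equals
#' \eqn{(C/C_e)\exp(-\Delta E/k_BT)} with \eqn{\Delta E} the edge bond-energy
#' change. Failure is an internal inconsistency of the move table and is
#' always fatal.
#'
#' @param omega_J_mol kink energy, J/mol
#' @param saturation_ratio C/Ce
#' @param temperature_K kelvin
#' @param tol relative tolerance
#' @return invisibly `TRUE`; errors on violation
#' @export
audit_detailed_balance <- function(omega_J_mol, saturation_ratio = 1,
                                   temperature_K = 298.15, tol = 1e-12) {
  okT <- omega_J_mol / (sk_constants$R * temperature_K)
  S <- saturation_ratio
  for (sl in -1:1) {       # h_i - h_left before the move
    for (sr in -1:1) {     # h_right - h_i before the move
      # attach h_i -> h_i + 1 admissible?
      if (abs(sl + 1) > 1 || abs(sr - 1) > 1) next
      E_before <- okT * (abs(sl) + abs(sr))
      E_after <- okT * (abs(sl + 1) + abs(sr - 1))
      dE <- E_after - E_before
      r_fwd <- S * 1
      # reverse detach from the post-attach configuration
      r_bwd <- exp(-(E_before - E_after))
      ratio <- r_fwd / r_bwd
      expect <- S * exp(-dE)
      if (abs(ratio - expect) > tol * max(1, abs(expect))) {
        stop(sprintf(
          "detailed-balance audit failed at (sl=%d, sr=%d): ratio %.15g != %.15g",
          sl, sr, ratio, expect), call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Simulate a growing step edge (restricted solid-on-solid KMC)
#'
#' Rejection-free KMC of a periodic step edge with height-difference
#' restriction |dh| <= 1. Attachment at rate \eqn{\nu C/C_e} at every
#' admissible site; detachment at \eqn{\nu\exp(-\Delta E/RT)} with
#' \eqn{\Delta E} from the lateral bond count (a kink pair costs
#' \eqn{2\omega}). At \eqn{C/C_e = 1} the chain satisfies detailed balance
#' and the time-averaged kink density converges to
#' \eqn{2/[\exp(\omega/RT) + 2]}.
#'
#' @param config a [step_sim_config()]
#' @return object of class `sim_result`: list with `velocity` (sites/s,
#'   positive for growth), `velocity_se`, `kink_density`, `kink_density_se`
#'   (batch-mean standard errors), `roughness` (sites), event counts, elapsed
#'   simulated `time`, the final `heights`, and a `config` echo with the seed
#' @examples
#' cfg <- step_sim_config(edge_length = 64, omega_J_mol = 0,
#'                        n_events = 2e4, seed = 7)
#' simulate_step_edge(cfg)$kink_density  # ~2/3
#' @export
simulate_step_edge <- function(config) {
  stopifnot(inherits(config, "step_sim_config"))
  audit_detailed_balance(config$omega_J_mol, config$saturation_ratio,
                         config$temperature_K)
  okT <- config$omega_J_mol / (sk_constants$R * config$temperature_K)
  L <- config$edge_length
  set.seed(config$seed)
  # Warm start from the analytic bond distribution (z, 1, z)/(1 + 2z): for
  # kink-poor edges a flat start would take prohibitively long to nucleate
  # its equilibrium kink population; starting at the analytic law and
  # burning in makes the measurement a stationarity check of the dynamics.
  z <- exp(-okT)
  s <- sample(c(-1L, 0L, 1L), L - 1, replace = TRUE,
              prob = c(z, 1, z) / (1 + 2 * z))
  if (config$boundary == "periodic") {
    # a periodic edge must wind to zero: pair up +1 and -1 increments
    npair <- min(sum(s == 1), sum(s == -1))
    s <- sample(c(rep(1L, npair), rep(-1L, npair),
                  rep(0L, L - 1 - 2 * npair)))
  }
  h0 <- c(0L, cumsum(s))
  raw <- .kmc_step_edge_cpp(L, okT, config$saturation_ratio,
                            config$attempt_frequency,
                            config$n_events, config$burn_frac, 20L,
                            config$boundary == "periodic", h0)
  keep <- raw$time_batch > 0
  kd_b <- raw$kink_batch[keep] / raw$time_batch[keep]
  v_b <- raw$net_batch[keep] / (L * raw$time_batch[keep])
  out <- c(raw[c("velocity", "kink_density", "roughness", "n_attach",
                 "n_detach", "time", "heights")],
           list(velocity_se = .batch_se(v_b),
                kink_density_se = .batch_se(kd_b),
                config = unclass(config)))
  class(out) <- "sim_result"
  out
}

# standard error of a batch-mean series with AR(1) autocorrelation inflation
.batch_se <- function(x) {
  n <- length(x)
  if (n < 3) return(NA_real_)
  se <- sd(x) / sqrt(n)
  r1 <- suppressWarnings(stats::cor(x[-1], x[-n]))
  if (is.finite(r1) && r1 > 0 && r1 < 0.99) {
    se <- se * sqrt((1 + r1) / (1 - r1))
  }
  se
}

#' @export
print.sim_result <- function(x, ...) {
  cat("KMC step-edge result\n")
  cat(sprintf("  velocity     = %.4g +/- %.2g sites/s\n",
              x$velocity, x$velocity_se))
  cat(sprintf("  kink density = %.4f +/- %.4f\n",
              x$kink_density, x$kink_density_se))
  cat(sprintf("  roughness    = %.3f sites; %d attach / %d detach; seed %d\n",
              x$roughness, as.integer(x$n_attach), as.integer(x$n_detach),
              x$config$seed))
  invisible(x)
}

#' Simulated step velocity versus saturation curve
#'
#' Runs [simulate_step_edge()] at each saturation-grid point with seeds
#' derived from the config seed, and assembles a [vc_dataset()] (in lattice
#' units, Ce = 1) consumable by the kinetic-law fits.
#'
#' @param config a [step_sim_config()]; its `saturation_ratio` is ignored
#' @param saturation_grid C/Ce values (length > 1)
#' @return a [vc_dataset()] with `concentration = saturation_ratio`
#' @export
velocity_curve <- function(config, saturation_grid) {
  stopifnot(inherits(config, "step_sim_config"))
  if (length(saturation_grid) < 2) {
    stop("saturation grid must have more than one point", call. = FALSE)
  }
  res <- lapply(seq_along(saturation_grid), function(i) {
    cfg <- config
    cfg$saturation_ratio <- saturation_grid[i]
    cfg$seed <- config$seed + i
    simulate_step_edge(cfg)
  })
  vc_dataset(concentration_mol_per_L = saturation_grid,
             velocity_nm_s = vapply(res, `[[`, numeric(1), "velocity"),
             Ce = 1,
             sd = vapply(res, `[[`, numeric(1), "velocity_se"),
             direction_label = "simulated")
}

#' Configuration for a (200)-layer lattice-gas simulation
#'
#' Bond energies are binding magnitudes along [010] (pi-pi stacking), [001]
#' (in-plane vdW) and the [011] diagonal (H-bond chains). The first matrix
#' index runs along [010], the second along [001].
#'
#' @param nrow,ncol lattice dimensions, sites (>= 64 each)
#' @param E_010_J_mol,E_001_J_mol,E_011_J_mol bond energies, J/mol
#' @param dmu_J_mol chemical-potential offset, J/mol
#' @param temperature_K kelvin
#' @param attempt_frequency nu, 1/s
#' @param n_events number of KMC events
#' @param seed RNG seed (mandatory)
#' @return list of class `surface_sim_config`
#' @export
surface_sim_config <- function(nrow = 64L, ncol = 64L,
                               E_010_J_mol, E_001_J_mol, E_011_J_mol = 0,
                               dmu_J_mol = 0, temperature_K = 298.15,
                               attempt_frequency = 1, n_events = 1e5, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (nrow < 64 || ncol < 64) {
    stop("lattice dimensions must be >= 64 x 64", call. = FALSE)
  }
  .check_nonneg(c(E_010_J_mol, E_001_J_mol, E_011_J_mol), "bond energies")
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 E_010_J_mol = E_010_J_mol, E_001_J_mol = E_001_J_mol,
                 E_011_J_mol = E_011_J_mol, dmu_J_mol = dmu_J_mol,
                 temperature_K = temperature_K,
                 attempt_frequency = attempt_frequency,
                 n_events = n_events, seed = as.integer(seed)),
            class = "surface_sim_config")
}

#' Simulate the anisotropic lattice gas of a (200) molecular layer
#'
#' Occupancy KMC with attachment rate
#' \eqn{\nu\exp((\Delta\mu + \mu_{coex})/RT)} at every vacant site and
#' detachment rate \eqn{\nu\exp(-\Sigma_{bonds}/RT)} at every occupied site,
#' where \eqn{\mu_{coex} = -(E_{010} + E_{001} + E_{011})} is the bulk
#' coexistence chemical potential (half the full-coordination bond sum per
#' molecule). Referencing \eqn{\Delta\mu} to coexistence makes
#' \eqn{\Delta\mu = 0} the true equilibrium: a half-filled interface shows
#' no net growth, and isolated adatoms are strongly unstable, so growth at
#' \eqn{\Delta\mu > 0} proceeds by step flow at kink sites rather than by
#' random deposition. Detailed balance holds with respect to the
#' grand-canonical lattice-gas measure. Periodic boundaries.
#'
#' @param config a [surface_sim_config()]
#' @param lattice optional starting occupancy matrix (0/1) of the configured
#'   dimensions; defaults to an empty lattice
#' @return list with the final `lattice`, event counts, elapsed `time`, and
#'   a `config` echo
#' @export
simulate_surface <- function(config, lattice = NULL) {
  stopifnot(inherits(config, "surface_sim_config"))
  if (is.null(lattice)) {
    lattice <- matrix(0L, config$nrow, config$ncol)
  }
  if (!is.matrix(lattice) || nrow(lattice) != config$nrow ||
      ncol(lattice) != config$ncol) {
    stop("starting lattice does not match configured dimensions", call. = FALSE)
  }
  RT <- sk_constants$R * config$temperature_K
  mu_coex <- -(config$E_010_J_mol + config$E_001_J_mol + config$E_011_J_mol)
  set.seed(config$seed)
  raw <- .kmc_surface_cpp(lattice,
                          config$E_010_J_mol / RT, config$E_001_J_mol / RT,
                          config$E_011_J_mol / RT,
                          (config$dmu_J_mol + mu_coex) / RT,
                          config$attempt_frequency, config$n_events)
  c(raw, list(config = unclass(config)))
}

#' Etch a rectangular groove into an occupancy lattice
#'
#' Clears occupancy in a rectangular footprint centered on the lattice. The
#' surface model is a single molecular layer, so grooves are one layer deep
#' (`depth = 1`).
#'
#' @param lattice occupancy matrix (0/1); rows along [010], columns along
#'   [001]
#' @param orientation `"[001]"` for a groove elongated along [001] (long
#'   axis across columns) or `"[010]"` (long axis across rows)
#' @param width groove width, sites (across the short axis)
#' @param length groove length, sites; default spans the lattice
#' @param depth layers; only 1 is supported by the single-layer model
#' @return the etched lattice, with attribute `footprint` (row/col index
#'   ranges)
#' @export
etch_groove <- function(lattice, orientation = c("[001]", "[010]"),
                        width, length = NULL, depth = 1) {
  orientation <- match.arg(orientation)
  stopifnot(is.matrix(lattice))
  if (depth != 1) {
    stop("the surface model is a single molecular layer: only depth = 1 grooves are supported",
         call. = FALSE)
  }
  .check_positive(width, "width")
  nr <- nrow(lattice); nc <- ncol(lattice)
  if (orientation == "[001]") {
    len <- if (is.null(length)) nc else length
    if (width > nr || len > nc) stop("groove footprint out of bounds", call. = FALSE)
    r0 <- floor((nr - width) / 2) + 1
    c0 <- floor((nc - len) / 2) + 1
    rows <- r0:(r0 + width - 1)
    cols <- c0:(c0 + len - 1)
  } else {
    len <- if (is.null(length)) nr else length
    if (width > nc || len > nr) stop("groove footprint out of bounds", call. = FALSE)
    r0 <- floor((nr - len) / 2) + 1
    c0 <- floor((nc - width) / 2) + 1
    rows <- r0:(r0 + len - 1)
    cols <- c0:(c0 + width - 1)
  }
  lattice[rows, cols] <- 0L
  attr(lattice, "footprint") <- list(rows = rows, cols = cols,
                                     orientation = orientation)
  lattice
}

#' Count connected vacancy clusters
#'
#' 4-connected components of vacant sites under periodic boundaries; used as
#' the quantitative stand-in for "voids and crevices" after healing.
#'
#' @param lattice occupancy matrix (0/1)
#' @return number of vacancy clusters
#' @export
vacancy_clusters <- function(lattice) {
  .vacancy_clusters_cpp(lattice)
}

#' Heal an etched groove by supersaturated regrowth
#'
#' Runs the lattice-gas KMC from the etched state at driving force
#' `dmu_J_mol` and reports how completely the groove refilled.
#'
#' @param lattice an etched lattice from [etch_groove()] (must carry its
#'   `footprint` attribute)
#' @param config a [surface_sim_config()]; its `dmu_J_mol`, bond energies and
#'   `n_events` drive the healing run
#' @return list with `healed_fraction` (refilled/etched sites inside the
#'   footprint), `void_count` (vacancy clusters remaining inside the groove
#'   footprint),
#'   `interface_roughness` (occupied-vacant neighbor pairs per lattice row),
#'   and the final `lattice`
#' @export
heal <- function(lattice, config) {
  fp <- attr(lattice, "footprint")
  if (is.null(fp)) stop("lattice has no groove footprint: etch first", call. = FALSE)
  if (config$dmu_J_mol < 0) stop("healing requires dmu >= 0", call. = FALSE)
  etched <- sum(lattice[fp$rows, fp$cols] == 0)
  res <- simulate_surface(config, lattice = lattice)
  final <- res$lattice
  remaining <- sum(final[fp$rows, fp$cols] == 0)
  healed_fraction <- if (etched > 0) (etched - remaining) / etched else NA_real_
  # voids: vacancy clusters inside the groove footprint (an occupied pad
  # ring suppresses spurious periodic wrap-around joins)
  sub <- final[fp$rows, fp$cols, drop = FALSE]
  padded <- rbind(1L, cbind(1L, sub, 1L), 1L)
  # boundary length: horizontal + vertical occupied/vacant neighbor pairs
  hpairs <- sum(final[, -1] != final[, -ncol(final)])
  vpairs <- sum(final[-1, ] != final[-nrow(final), ])
  list(healed_fraction = healed_fraction,
       void_count = vacancy_clusters(padded),
       interface_roughness = (hpairs + vpairs) / nrow(final),
       lattice = final,
       n_attach = res$n_attach, n_detach = res$n_detach,
       config = res$config)
}
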