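# Step-kinetic laws on v(C) data: linear quasi-first-order (kinks saturated
# at the equilibrium density), free-exponent power law, and the fixed
# quadratic kink-limited regime; AICc model selection; anisotropy ratios;
# and the absorbance-linearity speciation screen.
#
# All fits use x = C/Ce - 1 as the regressor, pinning v(Ce) = 0.

#' Construct a step velocity versus concentration dataset
#'
#' @param concentration_mol_per_L solute concentrations, mol/L
#' @param velocity_nm_s step velocities, nm/s
#' @param Ce equilibrium concentration, mol/L
#' @param sd optional velocity standard deviations, nm/s
#' @param direction_label crystallographic direction of step advance
#' @return data.frame of class `vc_dataset` with attributes `Ce` and
#'   `direction_label`
#' @export
vc_dataset <- function(concentration_mol_per_L, velocity_nm_s, Ce,
                       sd = NULL, direction_label = NA_character_) {
  .check_positive(concentration_mol_per_L, "concentration_mol_per_L")
  .check_positive(Ce, "Ce")
  if (length(concentration_mol_per_L) != length(velocity_nm_s)) {
    stop("concentration and velocity must have equal length", call. = FALSE)
  }
  out <- data.frame(concentration_mol_per_L = concentration_mol_per_L,
                    velocity_nm_s = velocity_nm_s)
  out$sd <- if (is.null(sd)) NA_real_ else sd
  attr(out, "Ce") <- Ce
  attr(out, "direction_label") <- direction_label
  class(out) <- c("vc_dataset", "data.frame")
  out
}

.vc_xy <- function(data, min_points, require_above = TRUE) {
  Ce <- attr(data, "Ce")
  if (is.null(Ce)) stop("dataset lacks a `Ce` attribute", call. = FALSE)
  x <- data$concentration_mol_per_L / Ce - 1
  keep <- if (require_above) x > 0 else rep(TRUE, length(x))
  if (sum(keep) < min_points) {
    stop(sprintf("need at least %d points with C > Ce", min_points),
         call. = FALSE)
  }
  w <- if (all(is.na(data$sd)) || any(data$sd <= 0, na.rm = TRUE)) {
    rep(1, length(x))  # unweighted when uncertainties are absent or degenerate
  } else {
    1 / data$sd^2
  }
  list(x = x[keep], y = data$velocity_nm_s[keep], w = w[keep], Ce = Ce)
}

# Gaussian AICc from a weighted RSS; k counts mean-model parameters + sigma
.aicc <- function(rss, n, k_mean) {
  k <- k_mean + 1
  aic <- n * log(rss / n) + 2 * k
  if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n - k - 1) else Inf
}

.kinetic_fit <- function(model, beta, order_m, ses, rss, n, k_mean,
                         residuals, data) {
  structure(list(model = model, beta = beta, order_m = order_m,
                 parameter_ses = ses, rss = rss, n = n,
                 aicc = .aicc(rss, n, k_mean), residuals = residuals,
                 Ce = attr(data, "Ce"),
                 direction_label = attr(data, "direction_label"),
                 data = data),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("kinetic fit [%s]: v = %.4g * (C/Ce - 1)^%.3g nm/s\n",
              x$model, x$beta, x$order_m))
  cat(sprintf("  n = %d, AICc = %.2f\n", x$n, x$aicc))
  invisible(x)
}

#' Predicted step velocity from a kinetic fit
#'
#' @param object a `kinetic_fit`
#' @param C concentrations, mol/L
#' @param ... unused
#' @return velocities, nm/s (zero at or below Ce)
#' @export
predict_velocity <- function(object, C, ...) {
  x <- pmax(C / object$Ce - 1, 0)
  object$beta * x^object$order_m
}

#' Fit the linear quasi-first-order step-kinetic law
#'
#' \eqn{v = \beta (C/C_e - 1)} with the intercept pinned at \eqn{v(C_e)=0}:
#' the rate law of a reversible first-order incorporation reaction when the
#' kink density sits at its equilibrium value independent of supersaturation.
#' Velocity uncertainties, when present, act as inverse-variance weights.
#'
#' @param data a [vc_dataset()]
#' @return object of class `kinetic_fit`
#' @export
fit_linear_bcf <- function(data) {
  v <- .vc_xy(data, 2)
  beta <- sum(v$w * v$y * v$x) / sum(v$w * v$x^2)
  res <- v$y - beta * v$x
  rss <- sum(v$w * res^2)
  dof <- length(v$x) - 1
  se <- if (dof > 0) sqrt(sum(v$w * res^2) / dof / sum(v$w * v$x^2)) else NA_real_
  .kinetic_fit("linear_bcf", beta, 1, c(beta = se), rss, length(v$x), 1,
               res, data)
}

#' Fit a free-exponent power-law step-kinetic law
#'
#' \eqn{v = \beta (C/C_e - 1)^m} with \eqn{m \ge 1}, fitted by
#' Levenberg-Marquardt nonlinear least squares with multi-start over
#' \eqn{m \in \{1, 1.5, 2, 3\}}. A stand-in for the superlinear v(C)
#' predicted by 1D row-nucleation models of kink generation, whose exact
#' analytic form is model-dependent.
#'
#' @param data a [vc_dataset()]
#' @return object of class `kinetic_fit`
#' @export
fit_power_law <- function(data) {
  v <- .vc_xy(data, 3)
  df <- data.frame(x = v$x, y = v$y, w = v$w)
  best <- NULL
  for (m0 in c(1, 1.5, 2, 3)) {
    b0 <- max(sum(v$w * v$y * v$x^m0) / sum(v$w * v$x^(2 * m0)), 1e-8)
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nlsLM(y ~ beta * x^m, data = df, weights = df$w,
                          start = list(beta = b0, m = m0),
                          lower = c(beta = 0, m = 1),
                          control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(v$w * stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    stop("power-law fit failed to converge from any start (m in 1, 1.5, 2, 3)",
         call. = FALSE)
  }
  cf <- coef(best$fit)
  ses <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                  error = function(e) c(beta = NA_real_, m = NA_real_))
  .kinetic_fit("power_law", unname(cf["beta"]), unname(cf["m"]), ses,
               best$rss, length(v$x), 2,
               unname(stats::residuals(best$fit)), data)
}

#' Fit the kink-limited quadratic step-kinetic law
#'
#' \eqn{v = \beta (C/C_e - 1)^2}: the second-order regime in which the kink
#' density itself grows with driving force (1D nucleation of new rows), so
#' the kink-solute reaction appears second order in solute.
#'
#' @param data a [vc_dataset()]
#' @return object of class `kinetic_fit`, including a `residual_trend_p`
#'   element (runs-test style sign diagnostic; small values flag a
#'   systematic trend, e.g. when the data are really linear)
#' @export
fit_kink_limited <- function(data) {
  v <- .vc_xy(data, 3)
  x2 <- v$x^2
  beta <- sum(v$w * v$y * x2) / sum(v$w * x2^2)
  res <- v$y - beta * x2
  rss <- sum(v$w * res^2)
  dof <- length(v$x) - 1
  se <- if (dof > 0) sqrt(rss / dof / sum(v$w * x2^2)) else NA_real_
  out <- .kinetic_fit("quadratic_kink_limited", beta, 2, c(beta = se), rss,
                      length(v$x), 1, res, data)
  # sign-runs diagnostic: ordered residuals of a wrong-order fit trend
  s <- sign(res[order(v$x)])
  s <- s[s != 0]
  if (length(s) >= 4) {
    runs <- 1 + sum(diff(s) != 0)
    n1 <- sum(s > 0); n2 <- sum(s < 0); n <- n1 + n2
    mu <- 1 + 2 * n1 * n2 / n
    sig2 <- if (n > 1) 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1)) else 0
    out$residual_trend_p <- if (sig2 > 0) {
      stats::pnorm((runs - mu) / sqrt(sig2))  # few runs -> small p -> trend
    } else {
      NA_real_
    }
  } else {
    out$residual_trend_p <- NA_real_
  }
  out
}

#' Rank kinetic fits by small-sample corrected AIC
#'
#' Fits must come from the same dataset. Ties (delta AICc < 1e-8) are broken
#' toward the lower-order model.
#'
#' @param fits list of `kinetic_fit` objects on the same data
#' @return data.frame ranking with columns `model`, `order_m`, `aicc`,
#'   `delta_aicc`, best model first
#' @export
select_model <- function(fits) {
  stopifnot(length(fits) >= 1,
            all(vapply(fits, inherits, logical(1), "kinetic_fit")))
  if (length(fits) > 1) {
    ref <- fits[[1]]$data
    same <- vapply(fits, function(f) {
      isTRUE(all.equal(f$data$concentration_mol_per_L,
                       ref$concentration_mol_per_L)) &&
        isTRUE(all.equal(f$data$velocity_nm_s, ref$velocity_nm_s))
    }, logical(1))
    if (!all(same)) stop("fits were made on different datasets", call. = FALSE)
  }
  tab <- data.frame(
    model = vapply(fits, `[[`, character(1), "model"),
    order_m = vapply(fits, `[[`, numeric(1), "order_m"),
    aicc = vapply(fits, `[[`, numeric(1), "aicc")
  )
  tab <- tab[order(tab$aicc, tab$order_m), , drop = FALSE]
  tab$delta_aicc <- tab$aicc - tab$aicc[1]
  # tie-break toward lower order
  if (nrow(tab) > 1 && tab$delta_aicc[2] < 1e-8 &&
      tab$order_m[2] < tab$order_m[1]) {
    tab <- tab[c(2, 1, seq_len(nrow(tab))[-(1:2)]), , drop = FALSE]
    tab$delta_aicc <- tab$aicc - tab$aicc[1]
  }
  rownames(tab) <- NULL
  tab
}

#' Step-velocity anisotropy ratio between two directions
#'
#' Evaluates \eqn{v_{fast}(C)/v_{slow}(C)} for two kinetic fits sharing the
#' same Ce, on a concentration grid. Grid points where the slow model
#' predicts zero velocity are flagged and masked (NA).
#'
#' @param fit_fast,fit_slow `kinetic_fit` objects with equal `Ce`
#' @param C_grid concentrations, mol/L; must exceed Ce
#' @return data.frame with `concentration_mol_per_L`, `ratio`, `masked`
#' @export
anisotropy_ratio <- function(fit_fast, fit_slow, C_grid) {
  if (!isTRUE(all.equal(fit_fast$Ce, fit_slow$Ce))) {
    stop("fits do not share the same Ce", call. = FALSE)
  }
  if (any(C_grid <= fit_fast$Ce)) {
    stop("C_grid must lie strictly above Ce", call. = FALSE)
  }
  vf <- predict_velocity(fit_fast, C_grid)
  vs <- predict_velocity(fit_slow, C_grid)
  masked <- vs == 0
  ratio <- ifelse(masked, NA_real_, vf / vs)
  data.frame(concentration_mol_per_L = C_grid, ratio = ratio, masked = masked)
}

#' Construct an absorbance-versus-concentration series
#'
#' @param concentration_mol_per_L concentrations, mol/L (>= 0)
#' @param absorbance absorbances, AU
#' @param wavelength_nm measurement wavelength (metadata)
#' @return data.frame of class `absorbance_series`
#' @export
absorbance_series <- function(concentration_mol_per_L, absorbance,
                              wavelength_nm = 270) {
  .check_nonneg(concentration_mol_per_L, "concentration_mol_per_L")
  if (length(concentration_mol_per_L) != length(absorbance)) {
    stop("concentration and absorbance must have equal length", call. = FALSE)
  }
  out <- data.frame(concentration_mol_per_L = concentration_mol_per_L,
                    absorbance = absorbance)
  attr(out, "wavelength_nm") <- wavelength_nm
  class(out) <- c("absorbance_series", "data.frame")
  out
}

# monomer concentration from total C under dimerization K = [D]/[M]^2
.monomer_conc <- function(C, K) {
  if (K <= 0) return(C)
  (sqrt(1 + 8 * K * C) - 1) / (4 * K)
}

#' Absorbance linearity screen for solution speciation
#'
#' Compares linear Beer-Lambert absorbance (\eqn{A = \epsilon l C},
#' monomeric solute) against a monomer-dimer equilibrium model in which
#' monomers in dimers absorb with relative strength `eta`:
#' \eqn{A = \epsilon l [M + \eta(C - M)]} with \eqn{M} from mass balance
#' under \eqn{K_d = [D]/[M]^2}. The preferred model (AICc) yields the
#' speciation verdict: step-velocity superlinearity cannot be blamed on
#' dimers when the linear model wins.
#'
#' @param series an [absorbance_series()] with >= 4 concentrations
#' @return list with `verdict` ("monomeric" or "dimerization detected"),
#'   `epsilon_l`, `K_dimer`, `dimer_fraction_max` (fraction of solute mass
#'   in dimers at the highest concentration), `delta_aicc`
#'   (linear - dimer; negative prefers linear), `curvature_p` from a
#'   quadratic-term t-test
#' @export
absorbance_linearity <- function(series) {
  C <- series$concentration_mol_per_L
  A <- series$absorbance
  if (length(C) < 4) stop("need at least 4 concentrations", call. = FALSE)
  n <- length(C)
  # linear Beer-Lambert through the origin
  el <- sum(A * C) / sum(C^2)
  rss_lin <- sum((A - el * C)^2)
  aicc_lin <- .aicc(rss_lin, n, 1)
  # curvature diagnostic: t-test on a quadratic term
  qfit <- lm(A ~ 0 + C + I(C^2))
  curv_p <- tryCatch(
    suppressWarnings(summary(qfit))$coefficients["I(C^2)", "Pr(>|t|)"],
    error = function(e) NA_real_)
  # monomer-dimer model
  df <- data.frame(C = C, A = A)
  dimer <- tryCatch({
    fit <- minpack.lm::nlsLM(
      A ~ el2 * (.monomer_conc(C, K) + eta * (C - .monomer_conc(C, K))),
      data = df,
      start = list(el2 = el, K = 1, eta = 0.6),
      lower = c(el2 = 0, K = 0, eta = 0), upper = c(Inf, Inf, 1),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    list(fit = fit, rss = sum(stats::residuals(fit)^2))
  }, error = function(e) NULL)
  if (is.null(dimer)) {
    return(list(verdict = "monomeric", epsilon_l = el, K_dimer = 0,
                dimer_fraction_max = 0, delta_aicc = -Inf,
                curvature_p = curv_p))
  }
  aicc_dim <- .aicc(dimer$rss, n, 3)
  cf <- coef(dimer$fit)
  Cmax <- max(C)
  M <- .monomer_conc(Cmax, cf["K"])
  frac <- unname((Cmax - M) / Cmax)
  linear_preferred <- aicc_lin <= aicc_dim
  list(
    verdict = if (linear_preferred) "monomeric" else "dimerization detected",
    epsilon_l = if (linear_preferred) el else unname(cf["el2"]),
    K_dimer = if (linear_preferred) 0 else unname(cf["K"]),
    dimer_fraction_max = if (linear_preferred) 0 else frac,
    delta_aicc = aicc_lin - aicc_dim,
    curvature_p = curv_p
  )
}
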