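# Turns (synthetic) AFM height data into step positions, heights,
# displacement traces and fitted step velocities, and tests the
# velocity-independence claims that identify direct incorporation.
#
# Pixel convention: 0-based pixel coordinates, row-major, row 0 at the top
# of the frame; profile positions are physical nanometres.

#' Construct an ordered series of height maps
#'
#' @param frames list of numeric matrices (heights in nm), all the same shape
#' @param pixel_size_nm pixel edge length, nm
#' @param times_s strictly increasing frame timestamps, s
#' @param metadata optional free-form list
#' @return object of class `height_map_series`
#' @export
height_map_series <- function(frames, pixel_size_nm, times_s, metadata = list()) {
  if (!is.list(frames) || length(frames) == 0 ||
      !all(vapply(frames, is.matrix, logical(1)))) {
    stop("`frames` must be a non-empty list of matrices", call. = FALSE)
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must have the same shape", call. = FALSE)
  }
  if (length(times_s) != length(frames) || any(diff(times_s) <= 0)) {
    stop("`times_s` must be strictly increasing, one per frame", call. = FALSE)
  }
  .check_positive(pixel_size_nm, "pixel_size_nm")
  structure(list(frames = frames, pixel_size_nm = pixel_size_nm,
                 times_s = times_s, metadata = metadata),
            class = "height_map_series")
}

#' Sample a height profile along a line
#'
#' Bilinear interpolation of a frame along the segment from `p0` to `p1`
#' (0-based pixel coordinates `c(x, y)`, x = column, y = row), at a spacing
#' of at most one pixel. Positions are returned in physical nm from `p0`.
#'
#' @param frame numeric matrix of heights, nm
#' @param p0,p1 segment endpoints in pixel coordinates `c(x, y)`
#' @param pixel_size_nm pixel size, nm
#' @return data.frame of class `height_profile` with columns `position_nm`,
#'   `height_nm`
#' @export
extract_profile <- function(frame, p0, p1, pixel_size_nm) {
  stopifnot(is.matrix(frame), length(p0) == 2, length(p1) == 2)
  nc <- ncol(frame); nr <- nrow(frame)
  inb <- function(p) p[1] >= 0 && p[1] <= nc - 1 && p[2] >= 0 && p[2] <= nr - 1
  if (!inb(p0) || !inb(p1)) {
    stop("profile endpoints fall outside the frame", call. = FALSE)
  }
  len_px <- sqrt(sum((p1 - p0)^2))
  n <- max(2L, ceiling(len_px) + 1L)
  tt <- seq(0, 1, length.out = n)
  xs <- p0[1] + tt * (p1[1] - p0[1])
  ys <- p0[2] + tt * (p1[2] - p0[2])
  # bilinear sample at (x, y); row index = y + 1, col index = x + 1
  x0 <- pmin(floor(xs), nc - 2); x0 <- pmax(x0, 0)
  y0 <- pmin(floor(ys), nr - 2); y0 <- pmax(y0, 0)
  fx <- xs - x0; fy <- ys - y0
  idx <- function(r, c) frame[cbind(r + 1, c + 1)]
  h <- (1 - fx) * (1 - fy) * idx(y0, x0) +
    fx * (1 - fy) * idx(y0, x0 + 1) +
    (1 - fx) * fy * idx(y0 + 1, x0) +
    fx * fy * idx(y0 + 1, x0 + 1)
  out <- data.frame(position_nm = tt * len_px * pixel_size_nm, height_nm = h)
  class(out) <- c("height_profile", "data.frame")
  out
}

#' Detect and classify step risers in a height profile
#'
#' Terraces are segmented by change-points where the first difference of the
#' height exceeds `tol`; adjacent candidate points (gap <= 1) are merged into
#' one riser region. Each riser's height is the difference of the flanking
#' terrace medians, and risers smaller than `tol` in magnitude are dropped as
#' noise. Heights within `tol` of `unit_height` are classed `"full"`, within
#' `tol` of `unit_height/2` `"half"`, otherwise `"unclassified"`.
#'
#' @param profile a `height_profile` (or data.frame with `position_nm`,
#'   `height_nm`)
#' @param unit_height_nm full step height, nm (default the theophylline
#'   (200) value 2.413)
#' @param tol_nm classification tolerance, nm; must be < `unit_height_nm`/4
#' @return data.frame with columns `position_nm`, `height_nm`, `class`
#'   (zero rows for a flat profile)
#' @export
detect_steps <- function(profile, unit_height_nm = 2.413, tol_nm = 0.3) {
  .check_positive(unit_height_nm, "unit_height_nm")
  .check_positive(tol_nm, "tol_nm")
  if (tol_nm >= unit_height_nm / 4) {
    stop("`tol_nm` must be smaller than unit_height_nm / 4", call. = FALSE)
  }
  pos <- profile$position_nm
  h <- profile$height_nm
  if (any(diff(pos) <= 0)) stop("profile positions must be strictly increasing",
                                call. = FALSE)
  empty <- data.frame(position_nm = numeric(0), height_nm = numeric(0),
                      class = character(0), stringsAsFactors = FALSE)
  n <- length(h)
  if (n < 3) return(empty)
  d <- diff(h)
  cand <- which(abs(d) > tol_nm)  # riser between sample i and i+1
  if (length(cand) == 0) return(empty)
  # group candidates allowing gaps of one sample (risers spread over pixels)
  grp <- cumsum(c(1, diff(cand) > 2))
  out <- lapply(split(cand, grp), function(ix) {
    lo <- min(ix); hi <- max(ix) + 1  # riser spans samples lo..hi
    left <- h[seq(max(1, lo - 8), lo)]
    right <- h[seq(hi, min(n, hi + 8))]
    height <- median(right) - median(left)
    data.frame(position_nm = (pos[lo] + pos[hi]) / 2, height_nm = height,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[abs(out$height_nm) >= tol_nm, , drop = FALSE]
  if (nrow(out) == 0) return(empty)
  cls <- rep("unclassified", nrow(out))
  cls[abs(abs(out$height_nm) - unit_height_nm) <= tol_nm] <- "full"
  cls[abs(abs(out$height_nm) - unit_height_nm / 2) <= tol_nm] <- "half"
  out$class <- cls
  rownames(out) <- NULL
  out
}

#' Track one step across a height-map series
#'
#' Extracts the same profile line from every frame, runs [detect_steps()],
#' and follows the detection nearest to the previous position within a gating
#' window. Displacements are measured relative to the first frame, with
#' positive displacement toward the reference point (growth; dissolution
#' yields negative velocity).
#'
#' @param series a [height_map_series()]
#' @param p0,p1 profile line endpoints, pixel coordinates
#' @param start_position_nm approximate position of the step of interest in
#'   the first frame, nm along the profile
#' @param reference_position_nm position of the fixed reference point along
#'   the profile, nm; defaults to the far end of the line
#' @param gate_nm half-width of the tracking gate, nm
#' @param unit_height_nm,tol_nm passed to [detect_steps()]
#' @return data.frame of class `step_trace` with columns `time_s`,
#'   `displacement_nm`, plus attributes `step_height_class` and
#'   `direction_label`
#' @export
track_step <- function(series, p0, p1, start_position_nm,
                       reference_position_nm = NULL,
                       gate_nm = 30, unit_height_nm = 2.413, tol_nm = 0.3) {
  stopifnot(inherits(series, "height_map_series"))
  .check_positive(gate_nm, "gate_nm")
  prof1 <- extract_profile(series$frames[[1]], p0, p1, series$pixel_size_nm)
  if (is.null(reference_position_nm)) {
    reference_position_nm <- max(prof1$position_nm)
  }
  positions <- numeric(length(series$frames))
  classes <- character(length(series$frames))
  last <- start_position_nm
  for (i in seq_along(series$frames)) {
    prof <- extract_profile(series$frames[[i]], p0, p1, series$pixel_size_nm)
    det <- detect_steps(prof, unit_height_nm, tol_nm)
    if (nrow(det) == 0) {
      stop(sprintf("tracking error: step lost at frame %d (no detection)", i),
           call. = FALSE)
    }
    inside <- which(abs(det$position_nm - last) <= gate_nm)
    if (length(inside) == 0) {
      stop(sprintf("tracking error: step lost at frame %d (no detection within gate)", i),
           call. = FALSE)
    }
    if (length(inside) > 1) {
      stop(sprintf("tracking error: %d steps inside the gate at frame %d",
                   length(inside), i), call. = FALSE)
    }
    positions[i] <- det$position_nm[inside]
    classes[i] <- det$class[inside]
    last <- positions[i]
  }
  s <- sign(reference_position_nm - positions[1])
  if (s == 0) s <- 1
  out <- data.frame(time_s = series$times_s,
                    displacement_nm = s * (positions - positions[1]))
  attr(out, "step_height_class") <- names(sort(table(classes), decreasing = TRUE))[1]
  attr(out, "positions_nm") <- positions
  class(out) <- c("step_trace", "data.frame")
  out
}

#' Fit a step velocity to a displacement trace
#'
#' Ordinary least-squares slope of displacement versus time; the reported
#' uncertainty is the standard error of the slope.
#'
#' @param trace a `step_trace` or data.frame with `time_s`,
#'   `displacement_nm`
#' @return object of class `velocity_estimate`: list with `velocity_nm_s`,
#'   `sd_nm_s`, `n_points`, `r_squared`
#' @export
fit_velocity <- function(trace) {
  t <- trace$time_s
  d <- trace$displacement_nm
  if (length(t) < 3) stop("velocity fit needs at least 3 points", call. = FALSE)
  if (diff(range(t)) <= 0) stop("zero time span in trace", call. = FALSE)
  fit <- lm(d ~ t)
  sm <- suppressWarnings(summary(fit))  # exact lines: benign perfect-fit warning
  out <- list(velocity_nm_s = unname(coef(fit)["t"]),
              sd_nm_s = unname(sm$coefficients["t", "Std. Error"]),
              n_points = length(t),
              r_squared = sm$r.squared)
  class(out) <- "velocity_estimate"
  out
}

#' @export
print.velocity_estimate <- function(x, ...) {
  cat(sprintf("step velocity: %.4g +/- %.2g nm/s (n = %d, R^2 = %.4f)\n",
              x$velocity_nm_s, x$sd_nm_s, x$n_points, x$r_squared))
  invisible(x)
}

#' Permutation test of step-velocity independence
#'
#' Tests whether mean step velocities differ across groups (e.g. step-height
#' class or inter-step-distance bin). Direct incorporation from solution
#' predicts no dependence, so a non-significant result is reported as
#' "consistent with direct incorporation". The statistic is the
#' between-group sum of squares \eqn{\sum_g n_g(\bar v_g - \bar v)^2},
#' compared against its permutation distribution.
#'
#' @param velocities numeric velocities, nm/s
#' @param groups grouping factor (>= 2 groups, >= 3 estimates each)
#' @param n_perm number of permutations (default 1e4)
#' @param seed RNG seed for the permutation draw
#' @return list with `p_value`, `group_means`, `statistic`, `verdict`
#' @export
velocity_independence_test <- function(velocities, groups, n_perm = 1e4,
                                       seed = 1L) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) {
    stop("need at least 2 groups", call. = FALSE)
  }
  if (any(table(groups) < 3)) {
    stop("each group needs at least 3 estimates", call. = FALSE)
  }
  stat <- function(v, g) {
    gm <- tapply(v, g, mean)
    ns <- tapply(v, g, length)
    sum(ns * (gm - mean(v))^2)
  }
  obs <- stat(velocities, groups)
  set.seed(seed)
  perm <- replicate(n_perm, stat(sample(velocities), groups))
  p <- (1 + sum(perm >= obs)) / (1 + n_perm)
  verdict <- if (p > 0.05) {
    "consistent with direct incorporation"
  } else {
    "velocity depends on grouping"
  }
  list(p_value = p,
       group_means = tapply(velocities, groups, mean),
       statistic = obs,
       n_perm = n_perm,
       verdict = verdict)
}
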