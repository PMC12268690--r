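# Step detection, tracking, velocity fitting and the independence test.

test_that("profile extraction samples bilinearly in physical units", {
  flat <- matrix(5, 16, 32)
  p <- extract_profile(flat, c(0, 8), c(31, 8), pixel_size_nm = 4)
  expect_true(all(p$height_nm == 5))
  expect_equal(max(p$position_nm), 31 * 4)
  # diagonal line length is the Euclidean pixel distance times pixel size
  pd <- extract_profile(flat, c(0, 0), c(15, 15), pixel_size_nm = 2)
  expect_equal(max(pd$position_nm), sqrt(2 * 15^2) * 2)
  expect_error(extract_profile(flat, c(0, 0), c(40, 8), 4), "outside")
})

test_that("detect_steps finds and classifies full, half and odd risers", {
  x <- seq(0, 1000, by = 4)
  h <- ifelse(x < 300, 3.62, ifelse(x < 700, 3.62 - 2.413, 3.62 - 2.413 - 1.2065))
  det <- detect_steps(data.frame(position_nm = x, height_nm = h))
  expect_equal(nrow(det), 2)
  expect_setequal(det$class, c("full", "half"))
  expect_equal(sort(det$position_nm), c(300, 700), tolerance = 4)
  # flat profile: no detections
  expect_equal(nrow(detect_steps(data.frame(position_nm = x,
                                            height_nm = rep(1, length(x))))), 0)
  # a 0.6 nm riser with unit 2.413 is detected but unclassified
  h2 <- ifelse(x < 500, 0.6, 0)
  det2 <- detect_steps(data.frame(position_nm = x, height_nm = h2))
  expect_equal(det2$class, "unclassified")
  expect_error(detect_steps(data.frame(position_nm = x, height_nm = h),
                            unit_height_nm = 2.413, tol_nm = 0.7),
               "tol")
})

test_that("detection is robust: no false positives on noisy flat maps, high recall", {
  set.seed(11)
  x <- seq(0, 1000, by = 4)
  for (i in 1:20) {
    noisy <- rnorm(length(x), 0, 0.3 / 3.5)  # sigma < tol/3
    expect_equal(nrow(detect_steps(data.frame(position_nm = x,
                                              height_nm = noisy))), 0)
  }
  # recall on noisy risers at SNR >= 5
  hits <- 0
  for (i in 1:40) {
    h <- ifelse(x < 500, 2.413, 0) + rnorm(length(x), 0, 2.413 / 10)
    det <- detect_steps(data.frame(position_nm = x, height_nm = h),
                        tol_nm = 0.55)
    hits <- hits + any(det$class == "full" & abs(det$position_nm - 500) < 20)
  }
  expect_gte(hits / 40, 0.95)
})

test_that("tracking a generated series recovers the generator velocity", {
  hs <- gen_height_series(step_positions_nm = 300, step_classes = "full",
                          velocities_nm_s = 0.5,
                          frame_times_s = seq(0, 90, by = 10),
                          noise_sd_nm = 0, seed = 2)
  tr <- track_step(hs, c(0, 5), c(255, 5), start_position_nm = 300)
  expect_equal(tr$displacement_nm, seq(0, 45, by = 5), tolerance = 0.3)
  v <- fit_velocity(tr)
  expect_equal(v$velocity_nm_s, 0.5, tolerance = 0.01)
  expect_identical(attr(tr, "step_height_class"), "full")
  # static surface: zero displacements
  hs0 <- gen_height_series(step_positions_nm = 300, step_classes = "full",
                           velocities_nm_s = 0, noise_sd_nm = 0, seed = 2)
  tr0 <- track_step(hs0, c(0, 5), c(255, 5), start_position_nm = 300)
  expect_true(all(tr0$displacement_nm == 0))
  # noisy recovery within 3 sd
  hsn <- gen_height_series(step_positions_nm = 300, step_classes = "full",
                           velocities_nm_s = 0.5, noise_sd_nm = 0.08, seed = 9)
  vn <- fit_velocity(track_step(hsn, c(0, 5), c(255, 5),
                                start_position_nm = 300))
  expect_lt(abs(vn$velocity_nm_s - 0.5), 3 * max(vn$sd_nm_s, 0.01))
})

test_that("tracking errors are frame-attributed and ambiguity is fatal", {
  # two steps drifting into the same gate window
  hs <- gen_height_series(step_positions_nm = c(300, 420),
                          step_classes = c("full", "full"),
                          velocities_nm_s = c(0, 0), noise_sd_nm = 0, seed = 3)
  expect_error(track_step(hs, c(0, 5), c(255, 5), start_position_nm = 360,
                          gate_nm = 120),
               "steps inside the gate")
  # step lost: gate too small around a wrong start
  expect_error(track_step(hs, c(0, 5), c(255, 5), start_position_nm = 800,
                          gate_nm = 20),
               "step lost")
})

test_that("velocity fit is exact on lines and validates inputs", {
  tr <- data.frame(time_s = 0:9, displacement_nm = 0.8 * (0:9))
  v <- fit_velocity(tr)
  expect_equal(v$velocity_nm_s, 0.8, tolerance = 1e-12)
  expect_equal(v$sd_nm_s, 0, tolerance = 1e-10)
  expect_error(fit_velocity(data.frame(time_s = 0:1, displacement_nm = 0:1)),
               "3 points")
  expect_error(fit_velocity(data.frame(time_s = rep(1, 4),
                                       displacement_nm = 1:4)),
               "time span")
})

test_that("velocity estimator is unbiased across seeded replicates", {
  set.seed(21)
  v_hat <- replicate(200, {
    t <- seq(0, 90, by = 10)
    d <- 0.25 * t + rnorm(length(t), 0, 2)
    fit_velocity(data.frame(time_s = t, displacement_nm = d))$velocity_nm_s
  })
  sem <- sd(v_hat) / sqrt(length(v_hat))
  expect_lt(abs(mean(v_hat) - 0.25), 2 * sem)
})

test_that("permutation independence test separates null from shifted groups", {
  set.seed(5)
  null_v <- rnorm(12, 1, 0.05)
  grp <- rep(c("full", "half"), each = 6)
  r0 <- velocity_independence_test(null_v, grp, seed = 7)
  expect_gt(r0$p_value, 0.05)
  expect_match(r0$verdict, "direct incorporation")
  alt_v <- c(rnorm(6, 0.5, 0.02), rnorm(6, 1.0, 0.02))
  r1 <- velocity_independence_test(alt_v, grp, seed = 7)
  expect_lt(r1$p_value, 0.01)
  # identical duplicated estimates: p = 1
  r2 <- velocity_independence_test(rep(0.7, 8), rep(c("a", "b"), each = 4),
                                   seed = 7)
  expect_identical(r2$p_value, 1)
  expect_error(velocity_independence_test(1:6, rep("a", 6)), "2 groups")
  expect_error(velocity_independence_test(1:4, c("a", "a", "b", "b")),
               "3 estimates")
})
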