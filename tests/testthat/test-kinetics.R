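# Kinetic-law fits, model selection, anisotropy ratios, absorbance screen.

test_that("all laws reproduce generating parameters exactly on noiseless data", {
  lin <- gen_vc(beta = 3, m = 1, rel_noise = 0, seed = 1)
  f <- fit_linear_bcf(lin)
  expect_equal(f$beta, 3, tolerance = 1e-12)
  expect_equal(max(abs(f$residuals)), 0, tolerance = 1e-12)
  quad <- gen_vc(beta = 1.7, m = 2, rel_noise = 0, seed = 1)
  fq <- fit_kink_limited(quad)
  expect_equal(fq$beta, 1.7, tolerance = 1e-12)
  fp <- fit_power_law(quad)
  expect_equal(fp$order_m, 2, tolerance = 1e-6)
  expect_equal(fp$beta, 1.7, tolerance = 1e-5)
  # exact linear data drives the power law to the m = 1 boundary
  fpl <- fit_power_law(lin)
  expect_equal(fpl$order_m, 1, tolerance = 1e-6)
})

test_that("noisy recovery stays within stated uncertainty envelopes", {
  f <- fit_linear_bcf(gen_vc(beta = 2.5, m = 1, rel_noise = 0.05,
                             C_grid = 13.5e-3 * c(1.1, 1.2, 1.3, 1.4, 1.5, 1.7),
                             seed = 42))
  expect_lt(abs(f$beta - 2.5), 3 * f$parameter_ses[["beta"]])
  # power-law recovery envelope over 200 seeded replicates (m = 2, 5% noise)
  m_hat <- vapply(1:200, function(s) {
    fit_power_law(gen_vc(beta = 2.5, m = 2, rel_noise = 0.05, seed = s))$order_m
  }, numeric(1))
  expect_gte(mean(m_hat >= 1.6 & m_hat <= 2.4), 0.9)
})

test_that("quadratic fit flags systematic residual trends on linear data", {
  lin <- gen_vc(beta = 3, m = 1, rel_noise = 0.02, seed = 8)
  fq <- fit_kink_limited(lin)
  expect_lt(fq$residual_trend_p, 0.1)  # few sign runs: trend flagged
  quad <- gen_vc(beta = 3, m = 2, rel_noise = 0.02, seed = 8)
  expect_gt(fit_kink_limited(quad)$residual_trend_p, 0.1)
})

test_that("model selection identifies the generating order", {
  ok <- vapply(1:50, function(s) {
    d1 <- gen_vc(beta = 2.5, m = 1, rel_noise = 0.05, seed = s)
    d2 <- gen_vc(beta = 2.5, m = 2, rel_noise = 0.05, seed = 500 + s)
    r1 <- select_model(fit_all_laws(d1))
    r2 <- select_model(fit_all_laws(d2))
    c(r1$model[1] == "linear_bcf",
      r2$model[1] %in% c("power_law", "quadratic_kink_limited"))
  }, logical(2))
  expect_gte(mean(ok[1, ]), 0.9)
  expect_gte(mean(ok[2, ]), 0.9)
  # single fit: trivial ranking; mismatched datasets: error
  single <- select_model(list(fit_linear_bcf(gen_vc(m = 1, seed = 1))))
  expect_equal(nrow(single), 1)
  expect_error(select_model(list(fit_linear_bcf(gen_vc(m = 1, seed = 1)),
                                 fit_linear_bcf(gen_vc(m = 1, seed = 2)))),
               "different datasets")
})

test_that("anisotropy ratio follows the closed form and its monotonicity", {
  Ce <- 13.5e-3
  lin <- fit_linear_bcf(gen_vc(beta = 1, m = 1, Ce = Ce, rel_noise = 0, seed = 1))
  quad <- fit_kink_limited(gen_vc(beta = 1, m = 2, Ce = Ce, rel_noise = 0, seed = 1))
  grid <- Ce * seq(1.05, 1.5, by = 0.05)
  ar <- anisotropy_ratio(lin, quad, grid)
  # beta_f = beta_s = 1: ratio = 1/x, 20x at x = 0.05, 2x at x = 0.5
  expect_equal(ar$ratio, 1 / (grid / Ce - 1), tolerance = 1e-9)
  expect_equal(ar$ratio[1], 20, tolerance = 1e-9)
  expect_equal(ar$ratio[nrow(ar)], 2, tolerance = 1e-9)
  expect_true(all(diff(ar$ratio) < 0))
  # equal models: ratio identically 1
  same <- anisotropy_ratio(lin, lin, grid)
  expect_equal(same$ratio, rep(1, length(grid)))
  expect_error(anisotropy_ratio(lin, quad, Ce * c(0.9, 1.2)), "above Ce")
})

test_that("absorbance linearity screen separates monomeric from dimerizing solutions", {
  lin <- gen_absorbance(K_dimer = 0, rel_noise = 0, seed = 1)
  r <- absorbance_linearity(lin)
  expect_identical(r$verdict, "monomeric")
  expect_identical(r$dimer_fraction_max, 0)
  # K chosen so ~20% of solute mass is dimer-bound at 20 mM
  dim20 <- gen_absorbance(K_dimer = 7.8, rel_noise = 0.003, seed = 2)
  expect_gt(attr(dim20, "truth")$dimer_fraction_max, 0.15)
  rd <- absorbance_linearity(dim20)
  expect_identical(rd$verdict, "dimerization detected")
  expect_gt(rd$dimer_fraction_max, 0.1)
  # paper-range linear series with realistic noise stays monomeric
  noisy <- gen_absorbance(K_dimer = 0, rel_noise = 0.005, seed = 3)
  expect_identical(absorbance_linearity(noisy)$verdict, "monomeric")
  expect_error(absorbance_linearity(absorbance_series(c(1e-3, 2e-3, 3e-3),
                                                      c(0.1, 0.2, 0.3))),
               "4 concentrations")
})
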