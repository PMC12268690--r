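# Thermodynamic relations: supersaturation, van 't Hoff fitting,
# Gibbs/solubility interconversion, kink density, nucleation barrier.

test_that("supersaturation is ln(C/Ce) with the right sign structure", {
  expect_identical(supersaturation(13.5e-3, 13.5e-3), 0)
  expect_equal(supersaturation(16.7e-3, 13.5e-3), log(16.7 / 13.5))
  expect_equal(supersaturation(6.75e-3, 13.5e-3), log(0.5))
  # antisymmetry over random valid pairs
  set.seed(1)
  C <- runif(50, 1e-4, 1); Ce <- runif(50, 1e-4, 1)
  expect_equal(supersaturation(C, Ce) + supersaturation(Ce, C), rep(0, 50))
  expect_error(supersaturation(-1, 0.01), "C")
  expect_error(supersaturation(0.01, 0), "Ce")
})

test_that("van 't Hoff fit inverts the generating model exactly on noiseless data", {
  pts <- gen_solubility(dH_J_mol = -20.5e3, dS_J_mol_K = -34.0,
                        temperatures_K = c(283, 288, 293, 300),
                        rel_noise = 0, n_rep = 1, seed = 1)
  fit <- fit_vant_hoff(pts)
  expect_equal(fit$enthalpy_J_mol, -20.5e3, tolerance = 1e-10)
  expect_equal(fit$entropy_J_mol_K, -34.0, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # two points on an exact line: exact slope, zero residual
  p2 <- solubility_points(c(280, 300),
                          solubility_from_thermo(-18e3, -30, c(280, 300)))
  f2 <- fit_vant_hoff(p2)
  expect_equal(f2$enthalpy_J_mol, -18e3, tolerance = 1e-9)
  expect_equal(max(abs(f2$residuals)), 0, tolerance = 1e-12)
})

test_that("van 't Hoff fit validates its inputs and supports weighting", {
  expect_error(fit_vant_hoff(solubility_points(c(290, 290), c(0.01, 0.011))),
               "distinct temperatures")
  pts <- gen_solubility(rel_noise = 0.03, seed = 4)
  expect_s3_class(fit_vant_hoff(pts, weighted = TRUE), "thermo_params")
  pts$sd <- NA_real_
  expect_error(fit_vant_hoff(pts, weighted = TRUE), "sd")
})

test_that("Gibbs energy and solubility are exact inverses on the molarity scale", {
  expect_equal(gibbs_from_solubility(1, 310), 0)
  # Fig-2-style inputs: Ce = 13.5 mM at 25.2 C lands near -10.7 kJ/mol
  g <- gibbs_from_solubility(13.5e-3, as_kelvin(25.2, "C"))
  expect_equal(g, -10679.23, tolerance = 1e-5)
  # round trip through solubility_from_thermo
  set.seed(2)
  dH <- runif(20, -40e3, -5e3); dS <- runif(20, -60, 0); T_K <- runif(20, 270, 320)
  Ce <- solubility_from_thermo(dH, dS, T_K)
  expect_equal(gibbs_from_solubility(Ce, T_K), dH - T_K * dS, tolerance = 1e-12)
  expect_equal(gibbs_from_hs(5, 0, 298), 5)
  expect_equal(gibbs_from_hs(0, -34, 298), 298 * 34)
  expect_equal(solubility_from_thermo(0, 0, 298), 1)
  expect_error(solubility_from_thermo(1e10, -1e6, 298), "overflow")
})

test_that("equilibrium kink density matches the three-state Boltzmann enumeration", {
  expect_equal(equilibrium_kink_density(0, 298.15), 2 / 3)
  expect_equal(equilibrium_kink_density(4e3, 298.15), 0.2848693,
               tolerance = 1e-6)
  expect_equal(equilibrium_kink_density(40e3, 298), 1.947e-7,
               tolerance = 1e-3)
  # brute-force enumeration oracle across an omega grid
  for (om in c(0, 1e3, 5e3, 12e3, 30e3)) {
    expect_equal(equilibrium_kink_density(om, 298.15),
                 kink_density_enumeration_oracle(om, 298.15),
                 tolerance = 1e-12)
  }
  # strictly decreasing in omega, bounded by (0, 2/3]
  dens <- equilibrium_kink_density(seq(0, 30e3, by = 500), 298.15)
  expect_true(all(diff(dens) < 0))
  expect_true(all(dens > 0 & dens <= 2 / 3))
  expect_error(equilibrium_kink_density(-1, 298), "omega")
})

test_that("profile kink density counts the alternating configuration as 1/2", {
  expect_identical(profile_kink_density(rep(c(1L, 1L, 0L, 0L), 8)), 0.5)
  expect_identical(profile_kink_density(rep(0L, 16)), 0)
  # non-periodic flat staircase of one kink
  expect_equal(profile_kink_density(c(0, 0, 1, 1), periodic = FALSE), 0.25)
})

test_that("2D nucleation barrier has the closed-form scalings", {
  b <- nucleation_barrier_2d(193.4, 0.84743, 5e-3, 1e-21)
  expect_gt(b, 0)
  # inverse proportionality in driving force
  expect_equal(nucleation_barrier_2d(193.4, 0.84743, 5e-3, 2e-21), b / 2)
  # square law in edge free energy
  expect_equal(nucleation_barrier_2d(193.4, 0.84743, 1e-2, 1e-21), 4 * b)
  # manual unit-tracked evaluation
  expect_equal(b, pi * 193.4e-30 * 0.84743e-9 * (5e-3)^2 / 1e-21,
               tolerance = 1e-12)
  # per-length gamma convention converts by dividing by h
  expect_equal(nucleation_barrier_2d(193.4, 0.84743, 5e-3 * 0.84743e-9,
                                     1e-21, gamma_unit = "per_length"),
               b, tolerance = 1e-12)
  expect_error(nucleation_barrier_2d(193.4, 0.84743, 5e-3, -1), "driving_force")
})

test_that("face growth rate is h*v/l", {
  expect_equal(face_growth_rate(2.413, 1.0, 241.3), 0.01)
  expect_equal(face_growth_rate(2.413, 1.0, 120.65),
               2 * face_growth_rate(2.413, 1.0, 241.3))
  expect_error(face_growth_rate(2.413, 1.0, 0), "l_nm")
})
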