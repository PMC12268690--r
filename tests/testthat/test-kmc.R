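# KMC engines: detailed balance, equilibrium statistics, growth, healing.

test_that("the rate catalog satisfies detailed balance exhaustively", {
  expect_true(audit_detailed_balance(4e3, saturation_ratio = 1))
  expect_true(audit_detailed_balance(0, saturation_ratio = 1))
  expect_true(audit_detailed_balance(12e3, saturation_ratio = 1.3))
})

test_that("identical config and seed reproduce bit-identical results", {
  cfg <- step_sim_config(edge_length = 64, omega_J_mol = 4e3,
                         saturation_ratio = 1.2, n_events = 5e4, seed = 77)
  a <- simulate_step_edge(cfg)
  b <- simulate_step_edge(cfg)
  expect_identical(a$heights, b$heights)
  expect_identical(a$velocity, b$velocity)
  expect_identical(a$kink_density, b$kink_density)
})

test_that("equilibrium edges neither grow nor roughen beyond the analytic law", {
  # omega = 0: kink density at the 2/3 limit, velocity statistically zero
  r0 <- simulate_step_edge(step_sim_config(edge_length = 128, omega_J_mol = 0,
                                           saturation_ratio = 1,
                                           n_events = 2e5, boundary = "free",
                                           seed = 7))
  expect_lt(abs(r0$kink_density - 2 / 3), 3 * r0$kink_density_se)
  expect_lt(abs(r0$velocity), 3 * r0$velocity_se)
  # omega = 4 kJ/mol: the reported [010] kink energy
  r4 <- simulate_step_edge(step_sim_config(edge_length = 256,
                                           omega_J_mol = 4e3,
                                           saturation_ratio = 1,
                                           n_events = 3e5, boundary = "free",
                                           seed = 7))
  expect_lt(abs(r4$kink_density - equilibrium_kink_density(4e3, 298.15)),
            3 * r4$kink_density_se)
  expect_lt(abs(r4$velocity), 3 * r4$velocity_se)
})

test_that("step velocity is positive under supersaturation and edge-length invariant", {
  v <- sapply(c(64, 128, 256), function(L) {
    r <- simulate_step_edge(step_sim_config(edge_length = L,
                                            omega_J_mol = 4e3,
                                            saturation_ratio = 1.3,
                                            n_events = 4e5, seed = 11))
    c(r$velocity, r$velocity_se)
  })
  expect_true(all(v[1, ] > 0))
  # invariance above 64 sites: pairwise within 3 combined SE
  for (i in 1:2) for (j in (i + 1):3) {
    expect_lt(abs(v[1, i] - v[1, j]), 3 * sqrt(v[2, i]^2 + v[2, j]^2))
  }
})

test_that("velocity curves at saturation unity are statistically zero", {
  cfg <- step_sim_config(edge_length = 64, omega_J_mol = 4e3,
                         n_events = 1e5, seed = 5)
  vc <- velocity_curve(cfg, rep(1, 4))
  expect_true(all(abs(vc$velocity_nm_s) < 3 * pmax(vc$sd, 1e-4)))
})

test_that("groove etching is exact bookkeeping with an orientation transpose", {
  lat <- matrix(1L, 64, 64)
  g <- etch_groove(lat, "[001]", width = 6, length = 40)
  expect_equal(sum(g == 0), 6 * 40)
  fp <- attr(g, "footprint")
  expect_equal(length(fp$rows), 6)
  expect_equal(length(fp$cols), 40)
  # orientation flag transposes the footprint
  g2 <- etch_groove(lat, "[010]", width = 6, length = 40)
  fp2 <- attr(g2, "footprint")
  expect_equal(length(fp2$rows), 40)
  expect_equal(length(fp2$cols), 6)
  expect_identical(unname(g[fp$rows, fp$cols]),
                   unname(t(g2[fp2$rows, fp2$cols])))
  # the etch touches only the footprint
  mask <- matrix(TRUE, 64, 64)
  mask[fp$rows, fp$cols] <- FALSE
  expect_true(all(g[mask] == 1))
  expect_error(etch_groove(lat, "[001]", width = 80), "out of bounds")
  expect_error(etch_groove(lat, "[001]", width = 6, depth = 2),
               "single molecular layer")
})

test_that("the lattice gas respects equilibrium and refills grooves under drive", {
  # dmu = 0 from a half-filled strip: no net growth beyond fluctuations
  lat <- matrix(0L, 64, 64)
  lat[1:32, ] <- 1L
  cfg0 <- surface_sim_config(64, 64, E_010_J_mol = 15e3, E_001_J_mol = 1e3,
                             E_011_J_mol = 2e3, dmu_J_mol = 0,
                             n_events = 2e4, seed = 3)
  out0 <- simulate_surface(cfg0, lat)
  expect_lt(abs(sum(out0$lattice) - sum(lat)), 160)  # interface fluctuation only
  # dmu = 0 healing of a smooth-walled groove: essentially nothing refills
  # (the rough-walled orientation can close by capillarity even at
  # coexistence, since eliminating its walls lowers the edge energy)
  g <- gen_groove_fixture(64, 64, "[010]", width = 6)
  h0 <- heal(g$lattice, cfg0)
  expect_lt(h0$healed_fraction, 0.2)
  # a narrow groove at strong drive heals completely, leaving no voids
  cfg_hi <- surface_sim_config(64, 64, E_010_J_mol = 15e3, E_001_J_mol = 1e3,
                               E_011_J_mol = 2e3, dmu_J_mol = 4e3,
                               n_events = 1e5, seed = 3)
  g1 <- gen_groove_fixture(64, 64, "[001]", width = 1)
  h1 <- heal(g1$lattice, cfg_hi)
  expect_equal(h1$healed_fraction, 1)
  expect_equal(h1$void_count, 0)
})

test_that("interfaces advancing along [010] outgrow interfaces advancing along [001]", {
  # the [010]-advancing interface runs along [001]: cheap kinks, fast growth
  grow <- function(horizontal, s) {
    lat <- matrix(0L, 64, 64)
    if (horizontal) lat[17:48, ] <- 1L else lat[, 17:48] <- 1L
    cfg <- surface_sim_config(64, 64, E_010_J_mol = 15e3, E_001_J_mol = 1e3,
                              E_011_J_mol = 2e3, dmu_J_mol = 2e3,
                              n_events = 2e4, seed = s)
    sum(simulate_surface(cfg, lat)$lattice) - sum(lat)
  }
  for (s in 1:2) {
    expect_gt(grow(TRUE, s), 2 * max(grow(FALSE, s), 1))
  }
})

test_that("grooves healed via the kink-rich direction refill faster (paired seeds)", {
  hf <- sapply(1:3, function(s) {
    sapply(c("[001]", "[010]"), function(orient) {
      g <- gen_groove_fixture(64, 64, orient, width = 6)
      cfg <- surface_sim_config(64, 64, E_010_J_mol = 15e3, E_001_J_mol = 1e3,
                                E_011_J_mol = 2e3, dmu_J_mol = 1.5e3,
                                n_events = 1e4, seed = s)
      heal(g$lattice, cfg)$healed_fraction
    })
  })
  expect_true(all(hf["[001]", ] > hf["[010]", ]))
})
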