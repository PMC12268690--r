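# Burton-pathway kink-energy accounting on the (200) bond-chain lattice.

test_that("kink creation cost reproduces the bond-chain anisotropy", {
  sch <- bond_scheme(pi_stack = 10e3, h_bond = 8e3, vdw_in_plane = 2e3,
                     vdw_out_of_plane = 3e3)
  # [001]-advancing step (edge along [010]): cost of 4 kinks = 2 pi-pi bonds
  k001 <- kink_creation_cost("[001]", sch)
  expect_equal(k001$total_for_4_kinks, 2 * 10e3)
  expect_equal(k001$per_kink, 10e3 / 2)
  led <- k001$bond_ledger
  expect_equal(led$net_energy[led$bond == "h_bond"], 0)
  expect_equal(led$net_energy[led$bond == "vdw_in_plane"], 0)
  # [010]-advancing step (edge along [001]): only in-plane vdW is charged
  k010 <- kink_creation_cost("[010]", sch)
  expect_equal(k010$total_for_4_kinks, 2 * 2e3)
  expect_equal(k010$per_kink, 2e3 / 2)
  led2 <- k010$bond_ledger
  expect_equal(led2$net_energy[led2$bond == "pi_stack"], 0)
  expect_equal(led2$net_energy[led2$bond == "h_bond"], 0)
  # all energies zero: zero cost
  z <- bond_scheme(0, 0, 0, 0)
  expect_equal(kink_creation_cost("[001]", z)$total_for_4_kinks, 0)
})

test_that("bond ledger conserves bonds and the cost is linear in each energy", {
  sch <- bond_scheme(pi_stack = 9e3, h_bond = 7e3, vdw_in_plane = 1.5e3)
  for (dir in c("[010]", "[001]")) {
    led <- kink_creation_cost(dir, sch)$bond_ledger
    # every broken bond is either restored or charged; none appears twice
    expect_true(all(led$n_broken >= led$n_restored))
    expect_equal(sum(led$net_energy),
                 sum((led$n_broken - led$n_restored) *
                       c(pi_stack = 9e3, h_bond = 7e3,
                         vdw_in_plane = 1.5e3)[led$bond]))
  }
  # linearity via finite differences in each bond energy
  base <- kink_creation_cost("[001]", sch)$total_for_4_kinks
  dE <- 123.4
  up <- kink_creation_cost("[001]",
                           bond_scheme(9e3 + dE, 7e3, 1.5e3))$total_for_4_kinks
  expect_equal((up - base) / dE, 2, tolerance = 1e-9)  # 2 pi bonds charged
  up2 <- kink_creation_cost("[010]",
                            bond_scheme(9e3, 7e3, 1.5e3 + dE))$total_for_4_kinks
  expect_equal((up2 - kink_creation_cost("[010]", sch)$total_for_4_kinks) / dE,
               2, tolerance = 1e-9)
})

test_that("[001] kinks cost at least as much as [010] kinks when pi-pi dominates", {
  set.seed(6)
  for (i in 1:25) {
    E_pi <- runif(1, 1e3, 20e3)
    E_vdw <- runif(1, 0, E_pi)  # pi-pi stronger than in-plane vdW
    sch <- bond_scheme(E_pi, runif(1, 0, 15e3), E_vdw)
    expect_gte(kink_creation_cost("[001]", sch)$per_kink,
               kink_creation_cost("[010]", sch)$per_kink)
  }
})

test_that("lattice enthalpy is the negative half-sum of bonds", {
  # per-molecule bond sum 41 kJ/mol -> -20.5 kJ/mol
  sch <- bond_scheme(pi_stack = 10e3, h_bond = 6e3, vdw_in_plane = 2e3,
                     vdw_out_of_plane = 5e3 / 4,
                     multiplicities = c(pi_stack = 2, h_bond = 2,
                                        vdw_in_plane = 2, vdw_out_of_plane = 4))
  expect_equal(lattice_enthalpy(sch)$enthalpy_J_mol, -20.5e3)
  expect_equal(lattice_enthalpy(sch, target_J_mol = -20.5e3)$residual_J_mol, 0)
  expect_equal(lattice_enthalpy(bond_scheme(0, 0, 0, 0))$enthalpy_J_mol, 0)
  # enumeration oracle: explicit neighbor list on a small periodic lattice
  n <- 6
  E <- c(pi = 3e3, hb = 2e3, vdw = 1e3)
  total <- 0
  for (u in 1:n) for (w in 1:n) {
    # each molecule: 2 pi ([010]), 2 vdw ([001]), 2 hb ([011]); half to avoid
    # double counting
    total <- total + 0.5 * (2 * E["pi"] + 2 * E["vdw"] + 2 * E["hb"])
  }
  per_molecule <- unname(total / n^2)
  sch2 <- bond_scheme(E[["pi"]], E[["hb"]], E[["vdw"]], 0)
  expect_equal(lattice_enthalpy(sch2)$enthalpy_J_mol, -per_molecule)
})

test_that("calibration solves both constraints and detects infeasibility", {
  cal <- calibrate_scheme(-20.5e3, 4e3, E_pi = 8e3, E_hb = 4e3)
  expect_equal(kink_creation_cost("[010]", cal)$per_kink, 4e3,
               tolerance = 1e-9)
  expect_equal(lattice_enthalpy(cal)$enthalpy_J_mol, -20.5e3,
               tolerance = 1e-9)
  # omega target 0: no in-plane vdW
  cal0 <- calibrate_scheme(-20.5e3, 0, E_pi = 8e3, E_hb = 4e3)
  expect_equal(cal0$energy[cal0$name == "vdw_in_plane"], 0)
  # strong bonds exceeding the enthalpy budget
  expect_error(calibrate_scheme(-20.5e3, 4e3, E_pi = 12e3, E_hb = 8e3),
               "infeasible")
})
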