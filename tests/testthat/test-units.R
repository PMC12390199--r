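test_that("Bjerrum length matches CODATA evaluation and its scaling laws", {
  sol <- solution_conditions(5, temperature = 298.15, eps_water = 78.7)
  expect_equal(bjerrum_length(sol), 7.1215, tolerance = 1e-3)
  half_eps <- solution_conditions(5, eps_water = 2 * 78.7)
  expect_equal(bjerrum_length(half_eps), bjerrum_length(sol) / 2)
  hot <- solution_conditions(5, temperature = 2 * 298.15)
  expect_equal(bjerrum_length(hot), bjerrum_length(sol) / 2)
})

test_that("inverse Debye length pins the kappa*a = 1.625 anchor at 5 mM", {
  sol <- solution_conditions(5)
  expect_equal(inverse_debye_length(sol) * 70, 1.625, tolerance = 0.002 / 1.625)
  expect_identical(inverse_debye_length(solution_conditions(0)), 0)
  s100 <- solution_conditions(100)
  expect_equal(inverse_debye_length(s100),
               sqrt(20) * inverse_debye_length(sol), tolerance = 1e-12)
  expect_equal(inverse_debye_length(s100), 0.1038, tolerance = 1e-3)
})

test_that("kappa obeys the square-root law in salt density", {
  for (c0 in c(0.2, 1, 7, 40)) {
    k1 <- inverse_debye_length(solution_conditions(c0))
    k4 <- inverse_debye_length(solution_conditions(4 * c0))
    expect_equal(k4, 2 * k1, tolerance = 1e-12)
  }
})

test_that("unit conversions are exact and invert to 1e-12", {
  expect_equal(convert_sigma(1), 0.0624151, tolerance = 1e-6)
  expect_equal(convert_sigma(0.03), 1.87245e-3, tolerance = 1e-5)
  expect_identical(convert_sigma(0), 0)
  for (x in c(1e-4, 0.03, 2.7)) {
    expect_equal(convert_sigma_inverse(convert_sigma(x)), x,
                 tolerance = 1e-12)
    expect_equal(convert_bond_k_inverse(convert_bond_k(x)), x,
                 tolerance = 1e-12)
  }
  expect_equal(convert_bond_k(0.5, 298.15), 1.2147, tolerance = 1e-4)
  expect_identical(convert_bond_k(0, 298.15), 0)
  expect_equal(convert_bond_k(1, 298.15), 2 * convert_bond_k(0.5, 298.15))
})

test_that("invalid physical parameters are rejected by name", {
  expect_error(solution_conditions(-1), "salt_mM")
  expect_error(solution_conditions(5, temperature = 0), "temperature")
  expect_error(solution_conditions(5, eps_water = -3), "eps_water")
  expect_error(convert_bond_k(0.5, temperature = -1), "temperature")
  expect_error(patchy_particle(theta_p = 2, theta_n = 1), "theta")
  expect_error(patchy_particle(radius = 0), "radius")
  expect_error(chain_parameters(n_beads = 0), "n_beads")
})

test_that("salt_for_kappa_a inverts the kappa(salt) relation", {
  for (ka in c(0.15, 1.625, 4.11, 9)) {
    sol <- solution_conditions(salt_for_kappa_a(ka, 70))
    expect_equal(sol$kappa * 70, ka, tolerance = 1e-10)
  }
})
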