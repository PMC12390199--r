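test_that("closed-form screened sphere potential: anchors and ratios", {
  sol <- sol5()
  Z <- 4 * pi * 70^2 * convert_sigma(0.01)
  expect_equal(Z, 38.43, tolerance = 1e-3)
  expect_equal(dh_sphere_potential(70, Z, 70, sol), 1.489,
               tolerance = 1e-3)
  expect_identical(dh_sphere_potential(c(70, 140), 0, 70, sol), c(0, 0))
  ratio <- dh_sphere_potential(140, Z, 70, sol) /
    dh_sphere_potential(70, Z, 70, sol)
  expect_equal(ratio, exp(-sol$kappa * 70) / 2, tolerance = 1e-12)
  expect_error(dh_sphere_potential(50, Z, 70, sol), "domain")
})

test_that("monomer quadrature: zero-charge particle gives zero mean energy", {
  pp <- patchy_particle(sigma_p = 0, sigma_n = 0, theta_p = 1, theta_n = 1)
  qd <- boltzmann_quadrature_monomer(pp, sol5(), chain_parameters(1), 150)
  expect_equal(qd$mean_u, 0, tolerance = 1e-12)
  expect_equal(qd$p_adsorbed, 0)
})

test_that("monomer quadrature converges under node doubling", {
  qd <- boltzmann_quadrature_monomer(janus120(eps_part = 4), sol5(),
                                     chain_parameters(1), 150,
                                     image_charges = TRUE)
  expect_lt(qd$convergence, 1e-6)
})

test_that("cap swap with opposite bead charge leaves the monomer average unchanged", {
  sol <- sol5()
  a <- patchy_particle(sigma_p = 0.03, sigma_n = 0.01, theta_p = pi / 2,
                       theta_n = pi / 2, eps_part = 4)
  b <- patchy_particle(sigma_p = 0.01, sigma_n = 0.03, theta_p = pi / 2,
                       theta_n = pi / 2, eps_part = 4)
  qa <- boltzmann_quadrature_monomer(a, sol, chain_parameters(1), 150,
                                     image_charges = TRUE)
  chm <- chain_parameters(1, bead_valence = -1)
  qb <- boltzmann_quadrature_monomer(b, sol, chm, 150,
                                     image_charges = TRUE)
  expect_equal(qa$mean_u, qb$mean_u, tolerance = 1e-9)
})

test_that("free dimer gyration radius matches the 1-D bond quadrature", {
  sol <- sol5()
  neutral <- patchy_particle(sigma_p = 0, sigma_n = 0, theta_p = 1,
                             theta_n = 1)
  ch <- chain_parameters(n_beads = 2)
  qd <- boltzmann_quadrature_dimer(neutral, sol, ch, 150)
  dens <- function(s) s^2 * exp(-ch$bond_k * (s - ch$bond_r0)^2 -
                                  sol$lB * exp(-sol$kappa * s) / s)
  num <- integrate(function(s) s^2 / 4 * dens(s), 4, 14,
                   rel.tol = 1e-10)$value
  den <- integrate(dens, 4, 14, rel.tol = 1e-10)$value
  ## the 1-D reference ignores the box walls and the particle hard core,
  ## which clip long bonds near the boundaries: an O(1e-3) effect
  expect_equal(qd$mean_Rg2, num / den, tolerance = 2e-3)
})

test_that("refinement suite passes on a fresh build", {
  rep <- refinement_suite(seed = 3, quick = TRUE)
  expect_true(all(rep$pass))
  expect_true(attr(rep, "pass"))
  expect_setequal(unique(rep$oracle),
                  c("closed-form sphere", "quadrature doubling",
                    "series truncation", "incremental energy",
                    "Boltzmann quadrature"))
})

test_that("single-bead image effect flips sign between uniform sphere and large patches", {
  ## exact canonical averages: for a homogeneously charged sphere the
  ## polarization repulsion weakens binding, while for a 120-degree patchy
  ## particle the low-dielectric amplification of the high multipoles wins
  ch1 <- chain_parameters(n_beads = 1)
  sol <- solution_conditions(salt_for_kappa_a(6, 70))
  uni78 <- patchy_particle(sigma_p = 0.03, sigma_n = 0.03, theta_p = 0,
                           theta_n = 0, eps_part = 78.7)
  uni4 <- patchy_particle(sigma_p = 0.03, sigma_n = 0.03, theta_p = 0,
                          theta_n = 0, eps_part = 4)
  u_off <- boltzmann_quadrature_monomer(uni78, sol, ch1, 200)
  u_on <- boltzmann_quadrature_monomer(uni4, sol, ch1, 200,
                                       image_charges = TRUE)
  expect_gt(u_on$mean_u, u_off$mean_u)     # images weaken binding
  th <- 2 * pi / 3
  p78 <- patchy_particle(sigma_p = 0.03, sigma_n = 0.03, theta_p = th,
                         theta_n = th, eps_part = 78.7)
  p4 <- patchy_particle(sigma_p = 0.03, sigma_n = 0.03, theta_p = th,
                        theta_n = th, eps_part = 4)
  v_off <- boltzmann_quadrature_monomer(p78, sol, ch1, 200)
  v_on <- boltzmann_quadrature_monomer(p4, sol, ch1, 200,
                                       image_charges = TRUE)
  expect_lt(v_on$mean_u, v_off$mean_u)     # images strengthen binding
})
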