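test_that("bond energy: zero at r0, converted magnitude, even in stretch", {
  ch <- chain_parameters(n_beads = 3)
  p0 <- rbind(c(0, 0, -100), c(7, 0, -100), c(14, 0, -100))
  expect_identical(bond_energy(p0, ch), 0)
  p1 <- rbind(c(0, 0, -100), c(8, 0, -100))
  expect_equal(bond_energy(p1, chain_parameters(n_beads = 2)),
               convert_bond_k(0.5, 298.15), tolerance = 1e-12)
  pplus <- rbind(c(0, 0, -100), c(7.5, 0, -100))
  pminus <- rbind(c(0, 0, -100), c(6.5, 0, -100))
  expect_equal(bond_energy(pplus, ch), bond_energy(pminus, ch))
})

test_that("screened pair energy: Bjerrum-contact value, decay, hard core", {
  ch <- chain_parameters(n_beads = 2)
  tiny_salt <- solution_conditions(1e-4)
  p <- rbind(c(0, 0, -100), c(tiny_salt$lB, 0, -100))
  expect_equal(pe_pe_energy(p, tiny_salt, ch), 1, tolerance = 1e-3)
  sol <- sol5()
  p10 <- rbind(c(0, 0, -100), c(10, 0, -100))
  expect_equal(pe_pe_energy(p10, sol, ch), 0.5646, tolerance = 1e-3)
  overlap <- rbind(c(0, 0, -100), c(3.9, 0, -100))
  expect_identical(pe_pe_energy(overlap, sol, ch), Inf)
})

test_that("per-bead particle energy honors the image-charge flag", {
  sol <- sol5()
  pp <- janus120(eps_part = 4)
  mp <- multipole_coefficients(pp, sol)
  kern <- polarization_kernel(pp, sol)
  pos <- rbind(c(0, 0, -80), c(0, 7, -80))
  r <- sqrt(rowSums(pos^2)); th <- acos(pos[, 3] / r)
  ## flag off: direct term only
  expect_equal(per_bead_particle_energy(1, pos, mp),
               psi_sigma(r[1], th[1], mp), tolerance = 1e-12)
  ## single bead with images: direct plus half of a positive self term
  u1 <- per_bead_particle_energy(1, pos[1, , drop = FALSE], mp, kern)
  self1 <- psi_polar_self(r[1], kern)
  expect_gt(self1, 0)
  expect_equal(u1, psi_sigma(r[1], th[1], mp) + self1 / 2,
               tolerance = 1e-12)
})

test_that("bead energy is negligible at the box edge", {
  mp <- multipole_coefficients(janus120(), sol5())
  pos <- matrix(c(0, 0, -490), 1)
  expect_lt(abs(per_bead_particle_energy(1, pos, mp)), 1e-4)
})

test_that("binding energy: far-field zero, flag contract, pair counting", {
  sol <- sol5()
  pp <- janus120(eps_part = 4)
  mp <- multipole_coefficients(pp, sol)
  kern <- polarization_kernel(pp, sol)
  far <- straight_chain(10, z = -450)
  expect_lt(abs(binding_energy(far, mp)), 1e-3)
  near <- straight_chain(5, z = -80)
  r <- sqrt(rowSums(near^2)); th <- acos(near[, 3] / r)
  expect_equal(binding_energy(near, mp), sum(psi_sigma(r, th, mp)),
               tolerance = 1e-12)
  ## literal counting doubles exactly the pair cross terms
  two <- near[1:2, ]
  lit <- binding_energy(two, mp, kern, cross_counting = "literal")
  pair <- binding_energy(two, mp, kern, cross_counting = "pair")
  expect_equal(lit - pair, psi_polar(two[1, ], two[2, ], kern),
               tolerance = 1e-12)
})

test_that("binding energy is linear in the charge pattern at fixed geometry", {
  sol <- sol5()
  mp1 <- multipole_coefficients(janus120(0.015, 0.015), sol)
  mp2 <- multipole_coefficients(janus120(0.03, 0.03), sol)
  pos <- straight_chain(8, z = -85)
  expect_equal(binding_energy(pos, mp2), 2 * binding_energy(pos, mp1),
               tolerance = 1e-10)
})

test_that("total energy is invariant under rotation about the symmetry axis", {
  sol <- sol5()
  pp <- janus120(eps_part = 4)
  mp <- multipole_coefficients(pp, sol)
  kern <- polarization_kernel(pp, sol)
  ch <- chain_parameters(n_beads = 6)
  pos <- straight_chain(6, z = -85)
  rot <- patchyPE:::.rotate_about(pos, c(0, 0, 0), c(0, 0, 1), 1.23)
  e0 <- total_energy(pos, sol, pp, ch, mp, kern)
  e1 <- total_energy(rot, sol, pp, ch, mp, kern)
  expect_equal(e1$total, e0$total, tolerance = 1e-10)
  expect_equal(e0$total, e0$bond_total + e0$pe_pe_total + e0$binding_energy)
  expect_equal(e0$binding_energy, e0$direct_particle_total +
                 e0$polar_self_total + e0$polar_cross_total)
})

test_that("oppositely charged uniform sphere attracts at all exterior points", {
  sol <- sol5()
  mp <- multipole_coefficients(uniform_sphere(0.02), sol)
  pos <- cbind(0, 0, -seq(72, 300, by = 10))
  for (k in seq_len(nrow(pos)))
    expect_lt(per_bead_particle_energy(k, pos, mp), 0)
})
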