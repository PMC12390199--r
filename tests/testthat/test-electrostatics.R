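test_that("surface charge profile has the cap plateaus and midpoints", {
  p <- patchy_particle(sigma_p = 0.03, sigma_n = 0.03,
                       theta_p = 80 * pi / 180, theta_n = 100 * pi / 180)
  expect_equal(surface_charge_density(0, p), 0.03, tolerance = 1e-10)
  expect_equal(surface_charge_density(pi, p), -0.03, tolerance = 1e-10)
  ## at theta_p the first tanh is zero and the second is saturated
  expect_equal(surface_charge_density(p$theta_p, p), 0.015,
               tolerance = 1e-5)
  expect_error(surface_charge_density(-0.1, p), "domain")
  expect_error(surface_charge_density(3.2, p), "domain")
})

test_that("Gauss-Legendre quadrature reproduces Legendre orthogonality", {
  gl <- pracma::gaussLegendre(512, -1, 1)
  P <- patchyPE:::.pl_table(gl$x, 10)
  G <- crossprod(P * gl$w, P)          # integrals of P_l P_m
  expect_equal(unname(diag(G)), 2 / (2 * (0:10) + 1), tolerance = 1e-10)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-10)
})

test_that("multipole integrals: uniform sphere is pure monopole", {
  mp <- multipole_coefficients(uniform_sphere(0.01), sol5())
  expect_equal(mp$integrals[1], -2 * convert_sigma(0.01), tolerance = 1e-10)
  expect_lt(max(abs(mp$integrals[-1])), 1e-10)
})

test_that("multipole integrals: antisymmetric Janus has odd-l only", {
  jp <- patchy_particle(sigma_p = 0.02, sigma_n = 0.02, theta_p = pi / 2,
                        theta_n = pi / 2, abruptness = 200)
  mp <- multipole_coefficients(jp, sol5())
  even <- mp$integrals[seq(1, 11, by = 2)]
  odd1 <- mp$integrals[2]
  expect_lt(max(abs(even)), 1e-12)
  ## step-function dipole integral is exactly sigma
  expect_equal(odd1, convert_sigma(0.02), tolerance = 1e-3)
})

test_that("patchy potential matches the closed-form sphere in the uniform limit", {
  sol <- sol5()
  for (eps in c(2, 78.7)) {
    u <- uniform_sphere(0.01, eps_part = eps)
    mp <- multipole_coefficients(u, sol)
    r <- seq(70, 700, length.out = 80)
    Z <- -4 * pi * 70^2 * convert_sigma(0.01)
    ref <- dh_sphere_potential(r, Z, 70, sol)
    expect_lt(max(abs(psi_sigma(r, 0.7, mp) - ref) / abs(ref)), 1e-8)
  }
})

test_that("potential is linear in the charge pattern (superposition)", {
  sol <- sol5()
  th_p <- 1.0; th_n <- 2.2
  pa <- patchy_particle(sigma_p = 0.02, sigma_n = 0, theta_p = th_p,
                        theta_n = th_n)
  pb <- patchy_particle(sigma_p = 0, sigma_n = 0.03, theta_p = th_p,
                        theta_n = th_n)
  pc <- patchy_particle(sigma_p = 0.02, sigma_n = 0.03, theta_p = th_p,
                        theta_n = th_n)
  r <- c(72, 90, 150); th <- c(0.3, 1.5, 2.9)
  va <- psi_sigma(r, th, multipole_coefficients(pa, sol))
  vb <- psi_sigma(r, th, multipole_coefficients(pb, sol))
  vc <- psi_sigma(r, th, multipole_coefficients(pc, sol))
  expect_equal(vc, va + vb, tolerance = 1e-12)
})

test_that("antisymmetric Janus potential is odd about the equator", {
  jp <- patchy_particle(sigma_p = 0.03, sigma_n = 0.03, theta_p = pi / 2,
                        theta_n = pi / 2)
  mp <- multipole_coefficients(jp, sol5())
  th <- c(0.2, 0.9, 1.4)
  expect_equal(psi_sigma(85, pi - th, mp), -psi_sigma(85, th, mp),
               tolerance = 1e-12)
  expect_equal(psi_sigma(85, pi / 2, mp), 0, tolerance = 1e-12)
  expect_error(psi_sigma(60, 0.3, mp), "domain")
})

test_that("potential decays to zero far from the particle", {
  mp <- multipole_coefficients(janus120(), sol5())
  expect_lt(abs(psi_sigma(500, 2.8, mp)), 1e-4)
})

test_that("polarization kernel: repulsive self term, exchange symmetry, decay", {
  sol <- sol5()
  k4 <- polarization_kernel(janus120(eps_part = 4), sol)
  expect_gt(psi_polar_self(74, k4), 0)
  x <- c(80, 0, 10); y <- c(0, 75, 20)
  expect_identical(psi_polar(x, y, k4), psi_polar(y, x, k4))
  near <- psi_polar(c(74, 0, 0), c(74, 0, 0), k4)
  far <- psi_polar(c(74, 0, 0), c(700, 0, 0), k4)
  expect_lt(abs(far), 1e-6 * abs(near))
  expect_error(psi_polar(c(10, 0, 0), y, k4), "domain")
  ## ion exclusion: kernel nonzero even without dielectric contrast
  k78 <- polarization_kernel(janus120(eps_part = 78.7), sol)
  expect_gt(max(abs(k78$ratios)), 0)
})

test_that("series truncation at lmax = 10: bounded at contact, converged off-surface", {
  ## the l <= 10 reference model is not a fully converged series right at
  ## bead-surface contact: the direct potential at the cap poles changes
  ## by a few percent from lmax 10 -> 20 (and the polarization self term,
  ## whose image a charge 4 A under a 70 A sphere cannot be resolved by
  ## l <= 10, by tens of percent).  One patch-resolution length (~25 A)
  ## off the surface both series are converged below 1%.
  sol <- sol5()
  p10 <- janus120(eps_part = 4)
  p20 <- janus120(eps_part = 4); p20$lmax <- 20L
  m10 <- multipole_coefficients(p10, sol)
  m20 <- multipole_coefficients(p20, sol)
  v10 <- psi_sigma(74, pi, m10); v20 <- psi_sigma(74, pi, m20)
  expect_lt(abs(v10 - v20) / abs(v20), 0.05)
  w10 <- psi_sigma(95, pi, m10); w20 <- psi_sigma(95, pi, m20)
  expect_lt(abs(w10 - w20) / abs(w20), 0.01)
  s10 <- psi_polar_self(95, polarization_kernel(p10, sol))
  s20 <- psi_polar_self(95, polarization_kernel(p20, sol))
  expect_lt(abs(s10 - s20) / abs(s20), 0.01)
})

test_that("zero-screening evaluation is refused", {
  expect_error(multipole_coefficients(janus120(), solution_conditions(0)),
               "salt")
})
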