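test_that("radius of gyration: closed forms", {
  expect_equal(rg_sq(rbind(c(0, 0, 0), c(7, 0, 0))), 3.5^2)
  n <- 50; s <- 7
  straight <- cbind(s * (0:(n - 1)), 0, 0)
  expect_equal(rg_sq(straight), s^2 * (n^2 - 1) / 12, tolerance = 1e-12)
  expect_equal(rg_sq(matrix(5, 4, 3)), 0)
})

test_that("adsorption classifier uses a strict threshold", {
  expect_true(classify_adsorbed(-20))
  expect_false(classify_adsorbed(0))
  expect_false(classify_adsorbed(-1))          # tie goes to desorbed
  expect_true(classify_adsorbed(10, min_dist = 3, method = "distance"))
  expect_false(classify_adsorbed(10, min_dist = 30, method = "distance"))
})

test_that("adsorbed fraction counts flags with block errors", {
  expect_equal(adsorbed_fraction(rep(TRUE, 100))$fraction, 1)
  expect_equal(adsorbed_fraction(rep(FALSE, 100))$fraction, 0)
  alt <- rep(c(TRUE, FALSE), 50)
  af <- adsorbed_fraction(alt)
  expect_equal(af$fraction, 0.5)
  expect_equal(af$block_error, 0)              # balanced blocks
  expect_error(adsorbed_fraction(logical(0)), "empty")
})

test_that("block statistics: invariance, degenerate cases, scaling", {
  x <- rep(3.2, 100)
  bs <- block_stats(x)
  expect_equal(bs$grand_mean, 3.2)
  expect_equal(bs$block_sd, 0)
  expect_error(block_stats(1:5, n_blocks = 10), "fewer")
  y <- sin(1:1000)
  expect_equal(block_stats(y)$grand_mean, mean(y), tolerance = 1e-12)
  set.seed(4)
  z <- rnorm(1e4)
  expect_equal(block_stats(z)$block_sd, 1 / sqrt(1e3), tolerance = 0.3)
})

test_that("density profile conserves bead counts shell by shell", {
  snaps <- list(cbind(0, 0, -c(75, 75.5, 90)),
                cbind(0, 0, c(76, 80, 95)))
  dp <- density_profile(snaps, edges = c(70, 80, 100, 120))
  expect_equal(sum(dp$counts), 3)              # beads per configuration
  expect_true(all(dp$density >= 0))
  expect_equal(dp$counts[3], 0)
  one <- density_profile(list(cbind(0, 0, c(85, -85))), c(70, 80, 90))
  expect_equal(one$counts, c(0, 2))
})

test_that("free-chain gyration radius shrinks with screening", {
  pp <- patchy_particle(sigma_p = 0, sigma_n = 0, theta_p = 1, theta_n = 1)
  ch <- chain_parameters(n_beads = 20)
  rg <- vapply(c(0.5, 1.5, 4), function(ka) {
    sol <- solution_conditions(salt_for_kappa_a(ka, 70))
    run <- run_simulation(sol, pp, ch,
                          quick_protocol(equilibration_moves = 4e4,
                                         n_samples = 2500,
                                         sampling_interval = 20,
                                         seed = round(100 * ka)))
    mean(run$Rg2)
  }, numeric(1))
  expect_gt(rg[1], rg[2])
  expect_gt(rg[2], rg[3])
})
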