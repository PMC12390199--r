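test_that("pivot and crankshaft proposals preserve bond lengths exactly", {
  set.seed(99)
  pos <- random_chain(chain_parameters(n_beads = 20), janus120(), 300,
                      seed = 5)
  bl <- function(p) sqrt(rowSums((p[-1, ] - p[-nrow(p), ])^2))
  ref <- bl(pos)
  for (i in 1:500) {
    pr <- propose_pivot(pos, amplitude = pi)
    expect_lt(max(abs(bl(pr$trial) - ref)), 1e-12)
  }
  for (i in 1:500) {
    pr <- propose_crankshaft(pos, amplitude = pi)
    expect_lt(max(abs(bl(pr$trial) - ref)), 1e-12)
    ## endpoints of the rotated segment stay put
    fixed <- setdiff(seq_len(nrow(pos)), pr$idx)
    expect_identical(pr$trial[fixed, ], pos[fixed, ])
  }
})

test_that("zero-amplitude and full-turn rotations are identities", {
  set.seed(7)
  pos <- random_chain(chain_parameters(n_beads = 8), janus120(), 300,
                      seed = 2)
  pr <- propose_pivot(pos, amplitude = 0)
  expect_equal(pr$trial, pos, tolerance = 1e-14)
  expect_identical(propose_displace(pos, 0)$trial, pos)
  rot <- patchyPE:::.rotate_about(pos, pos[3, ], c(1 / sqrt(2), 0.5, 0.5),
                                  2 * pi)
  expect_equal(rot, pos, tolerance = 1e-12)
})

test_that("displace moves one bead; translate preserves the gyration radius", {
  set.seed(11)
  pos <- random_chain(chain_parameters(n_beads = 12), janus120(), 300,
                      seed = 3)
  pr <- propose_displace(pos, 5)
  expect_equal(sum(rowSums((pr$trial - pos)^2) > 0), 1)
  tr <- propose_translate(pos, 50)
  expect_equal(rg_sq(tr$trial), rg_sq(pos), tolerance = 1e-12)
})

test_that("Metropolis rule: downhill always accepted, overlap never", {
  set.seed(1)
  expect_true(all(replicate(200, metropolis_accept(-5))))
  expect_false(any(replicate(200, metropolis_accept(Inf))))
})

test_that("simulation runs are bit-reproducible for a fixed seed", {
  sol <- sol5()
  pp <- janus120()
  ch <- chain_parameters(n_beads = 5)
  prot <- quick_protocol(n_samples = 200, seed = 31)
  r1 <- run_simulation(sol, pp, ch, prot)
  r2 <- run_simulation(sol, pp, ch, prot)
  expect_identical(r1$E_B, r2$E_B)
  expect_identical(attr(r1, "final_positions"), attr(r2, "final_positions"))
  r3 <- run_simulation(sol, pp, ch, quick_protocol(n_samples = 200,
                                                   seed = 32))
  expect_false(identical(r1$E_B, r3$E_B))
})

test_that("neutral particle and chain give exactly zero binding energy", {
  sol <- sol5()
  pp <- patchy_particle(sigma_p = 0, sigma_n = 0, theta_p = 1, theta_n = 2)
  ch <- chain_parameters(n_beads = 3)
  run <- run_simulation(sol, pp, ch, quick_protocol(n_samples = 100))
  expect_identical(unique(run$E_B), 0)
})

test_that("incremental energies agree with scratch recomputation", {
  sol <- sol5()
  pp <- janus120(eps_part = 4)
  ch <- chain_parameters(n_beads = 12)
  prot <- quick_protocol(equilibration_moves = 1e4, n_samples = 500,
                         sampling_interval = 10, image_charges = TRUE,
                         seed = 8)
  run <- run_simulation(sol, pp, ch, prot)
  ei <- attr(run, "energy"); es <- attr(run, "energy_scratch")
  expect_lt(abs(ei[["total"]] - es[["total"]]), 1e-6)
  ## and the engine's scratch energies match the R-level definitions
  mp <- multipole_coefficients(pp, sol)
  kern <- polarization_kernel(pp, sol)
  te <- total_energy(attr(run, "final_positions"), sol, pp, ch, mp, kern)
  expect_equal(es[["total"]], te$total, tolerance = 1e-9)
  expect_equal(es[["binding"]], te$binding_energy, tolerance = 1e-9)
})

test_that("chains stay connected and finite over a full run", {
  sol <- sol5()
  run <- run_simulation(sol, janus120(0.01, 0.05),
                        chain_parameters(n_beads = 15),
                        quick_protocol(n_samples = 500, seed = 12,
                                       snapshot_every = 50))
  expect_true(all(is.finite(run$E_B)))
  expect_true(all(is.finite(run$Rg2)))
  expect_true(all(run$min_dist >= 0))
  for (s in attr(run, "snapshots")) {
    expect_true(all(is.finite(s)))
    bl <- sqrt(rowSums((s[-1, ] - s[-nrow(s), ])^2))
    expect_true(all(bl > 4 & bl < 20))
  }
})

test_that("amplitude tuning steers acceptance toward one half on an adsorbed chain", {
  ## an adsorbed, strongly interacting chain: every local move kind can
  ## reach ~50% acceptance within its amplitude clamps
  sol <- sol5()
  pp <- patchy_particle(sigma_p = 0.03, sigma_n = 0.05,
                        theta_p = 2 * pi / 3, theta_n = 2 * pi / 3)
  ch <- chain_parameters(n_beads = 15)
  prot <- quick_protocol(equilibration_moves = 1.5e5, n_samples = 2000,
                         sampling_interval = 10, seed = 77)
  run <- run_simulation(sol, pp, ch, prot)
  acc <- attr(run, "acceptance")
  for (k in c("pivot", "crankshaft", "displace", "rotate"))
    expect_true(acc[[k]] > 0.3 && acc[[k]] < 0.7)
})
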