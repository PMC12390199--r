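# shared fixture builders

sol5 <- function() solution_conditions(5)

janus120 <- function(sigma_p = 0.03, sigma_n = 0.03, eps_part = 78.7) {
  patchy_particle(sigma_p = sigma_p, sigma_n = sigma_n,
                  theta_p = 2 * pi / 3, theta_n = 2 * pi / 3,
                  eps_part = eps_part)
}

# uniform sphere in the step limit: the tanh transition collapsed to the
# pole so the profile is exactly -sigma_n everywhere sampled
uniform_sphere <- function(sigma = 0.01, eps_part = 78.7)
  patchy_particle(sigma_p = 0, sigma_n = sigma, theta_p = 0, theta_n = 0,
                  eps_part = eps_part, abruptness = 1e6)

straight_chain <- function(n, spacing = 7, z = -100) {
  cbind(seq(-(n - 1) / 2, (n - 1) / 2) * spacing, 0, z)
}

quick_protocol <- function(...) {
  args <- list(...)
  defaults <- list(box_radius = 300, equilibration_moves = 2e4,
                   sampling_interval = 20, n_samples = 1000, seed = 1)
  do.call(simulation_protocol, utils::modifyList(defaults, args))
}
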