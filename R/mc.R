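## R-level move proposals (used for validation and small-scale work) and the
## wrapper around the compiled Metropolis engine.

.with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(expr)
}

.rotate_about <- function(points, origin, axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  ct <- cos(angle); st <- sin(angle)
  rel <- sweep(points, 2, origin)
  dotp <- drop(rel %*% u)
  crossp <- cbind(u[2] * rel[, 3] - u[3] * rel[, 2],
                  u[3] * rel[, 1] - u[1] * rel[, 3],
                  u[1] * rel[, 2] - u[2] * rel[, 1])
  out <- rel * ct + crossp * st + outer(dotp * (1 - ct), u)
  sweep(out, 2, origin, FUN = "+")
}

.rand_unit <- function() {
  repeat {
    v <- runif(3, -1, 1)
    s <- sum(v^2)
    if (s > 0 && s < 1) return(v / sqrt(s))
  }
}

#' Propose a pivot move
#'
#' Chooses a random pivot bead and rotates the chain segment on a random
#' side of it by a random angle (uniform within the amplitude) about a
#' random axis through the pivot.  Bond lengths are preserved exactly.
#'
#' @param positions N x 3 matrix of bead positions.
#' @param amplitude Maximum rotation angle in radians.
#' @return List with `kind`, `idx` (moved bead indices) and `trial`
#'   (full trial position matrix).
#' @export
propose_pivot <- function(positions, amplitude) {
  p <- .as_positions(positions); n <- nrow(p)
  if (n < 2) stop("pivot requires at least 2 beads")
  piv <- sample.int(n, 1)
  sides <- list(left = seq_len(piv - 1),
                right = if (piv < n) (piv + 1):n else integer(0))
  sides <- Filter(length, sides)
  idx <- sides[[sample.int(length(sides), 1)]]
  angle <- runif(1, -amplitude, amplitude)
  trial <- p
  trial[idx, ] <- .rotate_about(p[idx, , drop = FALSE], p[piv, ],
                                .rand_unit(), angle)
  list(kind = "pivot", idx = idx, trial = trial)
}

#' Propose a crankshaft move
#'
#' Rotates the interior segment between two randomly chosen beads about
#' their connecting axis; the two endpoints and all bond lengths are
#' preserved.
#'
#' @inheritParams propose_pivot
#' @export
propose_crankshaft <- function(positions, amplitude) {
  p <- .as_positions(positions); n <- nrow(p)
  if (n < 3) stop("crankshaft requires at least 3 beads")
  i <- sample.int(n - 2, 1)
  j <- i + 1 + sample.int(n - i - 1, 1)
  idx <- (i + 1):(j - 1)
  axis <- p[j, ] - p[i, ]
  angle <- runif(1, -amplitude, amplitude)
  trial <- p
  trial[idx, ] <- .rotate_about(p[idx, , drop = FALSE], p[i, ], axis, angle)
  list(kind = "crankshaft", idx = idx, trial = trial)
}

#' Propose a single-bead displacement
#' @inheritParams propose_pivot
#' @param amplitude Half-width of the uniform displacement cube, Angstrom.
#' @export
propose_displace <- function(positions, amplitude) {
  p <- .as_positions(positions)
  j <- sample.int(nrow(p), 1)
  trial <- p
  trial[j, ] <- p[j, ] + runif(3, -amplitude, amplitude)
  list(kind = "displace", idx = j, trial = trial)
}

#' Propose a whole-chain translation
#' @inheritParams propose_displace
#' @export
propose_translate <- function(positions, amplitude) {
  p <- .as_positions(positions)
  trial <- sweep(p, 2, runif(3, -amplitude, amplitude), FUN = "+")
  list(kind = "translate", idx = seq_len(nrow(p)), trial = trial)
}

#' Propose a whole-chain rotation about its centroid
#' @inheritParams propose_pivot
#' @export
propose_rotate <- function(positions, amplitude) {
  p <- .as_positions(positions)
  angle <- runif(1, -amplitude, amplitude)
  trial <- .rotate_about(p, colMeans(p), .rand_unit(), angle)
  list(kind = "rotate", idx = seq_len(nrow(p)), trial = trial)
}

#' Metropolis acceptance decision
#'
#' Accepts with probability min(1, exp(-delta_u)); an infinite energy
#' change (hard-core overlap) is always rejected.
#'
#' @param delta_u Energy change of the proposed move in kBT.
#' @return Logical.
#' @export
metropolis_accept <- function(delta_u) {
  if (!is.finite(delta_u)) return(delta_u < 0)
  delta_u <= 0 || runif(1) < exp(-delta_u)
}

#' Apply one Metropolis step at the R level
#'
#' Scratch-recomputes the total energy of the trial configuration, rejects
#' hard-core/box violations outright, and otherwise accepts with the
#' Metropolis probability.  Intended for validation and small systems; the
#' production engine ([run_simulation()]) uses incremental energies in
#' compiled code.
#'
#' @param positions Current N x 3 configuration.
#' @param proposal A proposal from one of the `propose_*` functions.
#' @param solution,particle,chain,multipoles Model objects.
#' @param kernel Optional polarization kernel (image charges on).
#' @param box_radius Spherical box radius, Angstrom.
#' @return List with `positions` (new or unchanged), `accepted`, `delta_u`.
#' @export
metropolis_step <- function(positions, proposal, solution, particle, chain,
                            multipoles, kernel = NULL, box_radius) {
  p <- .as_positions(positions)
  trial <- proposal$trial
  r <- sqrt(rowSums(trial^2))
  if (any(r < particle$radius + chain$bead_radius) ||
      any(r > box_radius - chain$bead_radius))
    return(list(positions = p, accepted = FALSE, delta_u = Inf))
  u_old <- total_energy(p, solution, particle, chain, multipoles, kernel)$total
  u_new <- total_energy(trial, solution, particle, chain, multipoles,
                        kernel)$total
  du <- u_new - u_old
  if (metropolis_accept(du))
    list(positions = trial, accepted = TRUE, delta_u = du)
  else list(positions = p, accepted = FALSE, delta_u = du)
}

#' Random initial chain configuration
#'
#' Grows a self-avoiding, particle-avoiding random walk with step length
#' `bond_r0`, starting from a uniformly random position inside the box.
#' Reproducible for a given seed; the global RNG state is left untouched.
#'
#' @param chain A [chain_parameters()] object.
#' @param particle A [patchy_particle()] object.
#' @param box_radius Spherical box radius, Angstrom.
#' @param seed Integer seed.
#' @param max_attempts Restarts before giving up.
#' @return N x 3 position matrix.
#' @export
random_chain <- function(chain, particle, box_radius, seed = 1,
                         max_attempts = 1000) {
  n <- chain$n_beads; b <- chain$bead_radius
  rmin <- particle$radius + b; rmax <- box_radius - b
  if (rmax <= rmin) stop("box too small for the particle and chain")
  .with_seed(seed, {
    for (att in seq_len(max_attempts)) {
      r0 <- (runif(1, rmin^3, rmax^3))^(1 / 3)
      pos <- matrix(0, n, 3)
      pos[1, ] <- .rand_unit() * r0
      ok <- TRUE
      if (n > 1) for (i in 2:n) {
        placed <- FALSE
        for (k in 1:150) {
          cand <- pos[i - 1, ] + .rand_unit() * chain$bond_r0
          rc <- sqrt(sum(cand^2))
          if (rc < rmin || rc > rmax) next
          d2 <- rowSums(sweep(pos[seq_len(i - 1), , drop = FALSE], 2,
                              cand)^2)
          if (any(d2 <= (2 * b)^2)) next
          pos[i, ] <- cand; placed <- TRUE; break
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) return(pos)
    }
    stop("failed to place a random chain after ", max_attempts, " attempts")
  })
}

#' Run a Metropolis Monte Carlo simulation
#'
#' Equilibrates the chain (with amplitude tuning toward ~50% acceptance),
#' then records `n_samples` samples separated by `sampling_interval` moves
#' with tuning frozen.  Each sample records the binding energy E_B, the
#' squared radius of gyration, the minimum bead-surface distance, and the
#' adsorbed flag (E_B below the threshold).  Fully reproducible for a given
#' protocol seed.
#'
#' @param solution A [solution_conditions()] object.
#' @param particle A [patchy_particle()] object.
#' @param chain A [chain_parameters()] object.
#' @param protocol A [simulation_protocol()] object.
#' @param initial Optional starting N x 3 configuration; default is a
#'   seeded [random_chain()].
#' @return Object of class `pe_samples`: a data.frame with columns
#'   `sample`, `n_moves`, `E_B`, `Rg2`, `min_dist`, `adsorbed`, with run
#'   metadata in attributes (`acceptance`, `amplitudes`, `energy`,
#'   `snapshots`, `final_positions`, `params`).
#' @export
run_simulation <- function(solution, particle, chain, protocol,
                           initial = NULL) {
  stopifnot(inherits(solution, "solution_conditions"),
            inherits(particle, "patchy_particle"),
            inherits(chain, "chain_parameters"),
            inherits(protocol, "simulation_protocol"))
  box <- protocol$box_radius
  if (is.null(box)) box <- .default_box_radius(particle, chain)
  mp <- multipole_coefficients(particle, solution)
  kern_coef <- rep(0, particle$lmax + 1)
  if (protocol$image_charges)
    kern_coef <- polarization_kernel(particle, solution)$ratios
  if (is.null(initial))
    initial <- random_chain(chain, particle, box,
                            seed = protocol$seed + 77003L)
  amp <- protocol$amplitudes
  if (is.na(amp$translate)) amp$translate <- box / 2
  kind_codes <- c(pivot = 0L, crankshaft = 1L, displace = 2L,
                  translate = 3L, rotate = 4L)
  res <- .run_mc_cpp(
    .as_positions(initial),
    particle$radius, chain$bead_radius, box,
    solution$kappa, solution$lB, chain$bond_k, chain$bond_r0,
    chain$bead_valence,
    mp$coef, kern_coef, protocol$image_charges,
    protocol$equilibration_moves, protocol$sampling_interval,
    protocol$n_samples, protocol$tune, protocol$tune_window,
    unlist(amp[c("pivot", "crankshaft", "displace", "translate",
                 "rotate")]),
    unname(kind_codes[protocol$move_kinds]),
    protocol$adsorption_threshold, protocol$snapshot_every,
    protocol$seed)
  out <- data.frame(sample = seq_len(protocol$n_samples),
                    n_moves = res$n_moves, E_B = res$E_B, Rg2 = res$Rg2,
                    min_dist = res$min_dist, adsorbed = res$adsorbed)
  structure(out, class = c("pe_samples", "data.frame"),
            acceptance = res$accepts / pmax(res$attempts, 1),
            attempts = res$attempts,
            amplitudes = res$final_amplitudes,
            energy = res$energy_incremental,
            energy_scratch = res$energy_scratch,
            snapshots = res$snapshots,
            final_positions = res$final_positions,
            params = list(solution = solution, particle = particle,
                          chain = chain, protocol = protocol,
                          box_radius = box))
}

#' @export
print.pe_samples <- function(x, ...) {
  cat(sprintf("MC sample series: %d samples\n", nrow(x)))
  bs <- block_stats(x$E_B)
  cat(sprintf("  <E_B>  = %8.3f +/- %.3f kBT (10-block error)\n",
              bs$grand_mean, bs$block_error))
  cat(sprintf("  <Rg2>  = %8.1f A^2  (Rg = %.2f A)\n", mean(x$Rg2),
              sqrt(mean(x$Rg2))))
  cat(sprintf("  f_ads  = %8.3f\n", mean(x$adsorbed)))
  invisible(x)
}
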