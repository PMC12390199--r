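## Reference (R-level) energy functions.  The MC engine keeps its own
## incremental C++ implementation; these functions are the from-scratch
## definition used for validation, analysis and tests.

.as_positions <- function(positions) {
  p <- if (is.matrix(positions)) positions else matrix(positions, ncol = 3)
  storage.mode(p) <- "double"
  p
}

#' Harmonic bond energy of a chain configuration
#'
#' Sum over consecutive bead pairs of k (r - r0)^2 in kBT.
#'
#' @param positions N x 3 matrix of bead positions (Angstrom,
#'   particle-centered).
#' @param chain A [chain_parameters()] object.
#' @return Bond energy in kBT (>= 0).
#' @export
bond_energy <- function(positions, chain) {
  stopifnot(inherits(chain, "chain_parameters"))
  p <- .as_positions(positions)
  n <- nrow(p)
  if (n < 2) return(0)
  d <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-n, , drop = FALSE])^2))
  sum(chain$bond_k * (d - chain$bond_r0)^2)
}

#' Screened Coulomb (Yukawa) bead-bead energy
#'
#' Sum over all bead pairs, bonded neighbours included, of
#' lB exp(-kappa r_ij) / r_ij in kBT (monovalent beads).  Pairs at or below
#' the hard-core contact distance 2b signal an overlap with an infinite
#' energy.
#'
#' @inheritParams bond_energy
#' @param solution A [solution_conditions()] object.
#' @return Pair energy in kBT; `Inf` on hard-core overlap.
#' @export
pe_pe_energy <- function(positions, solution, chain) {
  stopifnot(inherits(solution, "solution_conditions"),
            inherits(chain, "chain_parameters"))
  p <- .as_positions(positions)
  n <- nrow(p)
  if (n < 2) return(0)
  d <- dist(p)
  if (any(d <= 2 * chain$bead_radius)) return(Inf)
  v2 <- chain$bead_valence^2
  sum(v2 * solution$lB * exp(-solution$kappa * d) / d)
}

## particle-interaction pieces for every bead: direct, self, per-pair cross
.particle_terms <- function(positions, multipoles, kernel = NULL) {
  p <- .as_positions(positions)
  r <- sqrt(rowSums(p^2))
  th <- acos(pmin(1, pmax(-1, p[, 3] / r)))
  direct <- psi_sigma(r, th, multipoles)
  n <- nrow(p)
  self <- numeric(n); cross <- matrix(0, n, n)
  if (!is.null(kernel)) {
    self <- psi_polar_self(r, kernel)
    if (n >= 2) {
      idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      v <- psi_polar(p[idx[, 1], , drop = FALSE],
                     p[idx[, 2], , drop = FALSE], kernel)
      cross[idx] <- v
      cross <- cross + t(cross)
    }
  }
  list(direct = direct, self = self, cross = cross)
}

#' Interaction energy of one bead with the particle
#'
#' For bead k: Psi_sigma(r_k, theta_k) + 1/2 Psi_self(r_k) +
#' sum over other beads i of Psi_polar(i -> k).  With the polarization
#' kernel omitted (`kernel = NULL`, the "image charges off" mode) this
#' reduces to the direct term alone.  This per-bead form counts a bead's
#' pair-polarization terms fully and is therefore the correct single-bead
#' move increment; the configuration total counts each pair once (see
#' [binding_energy()]).
#'
#' @param k Bead index (1-based).
#' @inheritParams bond_energy
#' @param multipoles A [multipole_coefficients()] object.
#' @param kernel Optional [polarization_kernel()]; `NULL` disables the
#'   polarization terms.
#' @return Energy in kBT.
#' @export
per_bead_particle_energy <- function(k, positions, multipoles,
                                     kernel = NULL) {
  p <- .as_positions(positions)
  stopifnot(k >= 1, k <= nrow(p))
  t <- .particle_terms(p, multipoles, kernel)
  t$direct[k] + 0.5 * t$self[k] + sum(t$cross[k, ])
}

#' Binding energy of the chain to the particle
#'
#' Total polymer-particle interaction energy:
#' \deqn{E_B = \sum_k \Psi_\sigma(r_k,\theta_k)
#'   + \tfrac12 \sum_k \Psi_{self}(r_k) + \sum_{i<k} \Psi_{polar}(i,k),}
#' with the cross-polarization pairs counted once
#' (`cross_counting = "pair"`, the default, consistent with
#' U = 1/2 sum_j q_j Psi_polar).  `cross_counting = "literal"` instead sums
#' the per-bead energies, which counts every cross pair twice.
#'
#' @inheritParams per_bead_particle_energy
#' @param cross_counting `"pair"` (once per pair) or `"literal"`.
#' @return Binding energy in kBT.
#' @export
binding_energy <- function(positions, multipoles, kernel = NULL,
                           cross_counting = c("pair", "literal")) {
  cross_counting <- match.arg(cross_counting)
  t <- .particle_terms(positions, multipoles, kernel)
  cross <- sum(t$cross) / 2
  if (cross_counting == "literal") cross <- 2 * cross
  sum(t$direct) + 0.5 * sum(t$self) + cross
}

#' Full energy breakdown of a configuration
#'
#' @inheritParams pe_pe_energy
#' @param particle A [patchy_particle()] object (used for the bead-particle
#'   excluded-volume check |r_k| >= a + b).
#' @param multipoles A [multipole_coefficients()] object.
#' @param kernel Optional [polarization_kernel()]; `NULL` = image charges
#'   off.
#' @return Object of class `energy_breakdown`: list with `bond_total`,
#'   `pe_pe_total`, `direct_particle_total`, `polar_self_total`,
#'   `polar_cross_total`, `binding_energy`
#'   (= direct + self/2-summed + cross), and `total` (sum of all
#'   components).  `Inf` components signal hard-core overlap.
#' @export
total_energy <- function(positions, solution, particle, chain,
                         multipoles, kernel = NULL) {
  p <- .as_positions(positions)
  r <- sqrt(rowSums(p^2))
  overlap <- any(r < particle$radius + chain$bead_radius)
  t <- .particle_terms(p, multipoles, kernel)
  comp <- list(
    bond_total = bond_energy(p, chain),
    pe_pe_total = if (overlap) Inf else pe_pe_energy(p, solution, chain),
    direct_particle_total = sum(t$direct),
    polar_self_total = 0.5 * sum(t$self),
    polar_cross_total = sum(t$cross) / 2
  )
  comp$binding_energy <- comp$direct_particle_total +
    comp$polar_self_total + comp$polar_cross_total
  comp$total <- comp$bond_total + comp$pe_pe_total + comp$binding_energy
  structure(comp, class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("Energy breakdown (kBT):\n")
  cat(sprintf("  bonds          %12.4f\n", x$bond_total))
  cat(sprintf("  bead-bead      %12.4f\n", x$pe_pe_total))
  cat(sprintf("  direct         %12.4f\n", x$direct_particle_total))
  cat(sprintf("  polar self     %12.4f\n", x$polar_self_total))
  cat(sprintf("  polar cross    %12.4f\n", x$polar_cross_total))
  cat(sprintf("  binding energy %12.4f\n", x$binding_energy))
  cat(sprintf("  total          %12.4f\n", x$total))
  invisible(x)
}
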