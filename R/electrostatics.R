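## Modified spherical Bessel functions in the exponential convention
## k0(x) = exp(-x)/x, i0(x) = sinh(x)/x (no pi/2 factor).  The R-level path
## evaluates k_l by upward recursion (stable: k_l grows with l); i_l and the
## derivatives, needed only at x = kappa*a during setup, go through the
## half-integer-order besselI to avoid the unstable upward recursion for i_l.

## matrix of k_l(x) for l = 0..lmax, rows follow x
.kl_table <- function(x, lmax) {
  stopifnot(all(x > 0))
  out <- matrix(0, length(x), lmax + 1)
  e <- exp(-x)
  out[, 1] <- e / x
  if (lmax >= 1) out[, 2] <- e * (1 / x + 1 / x^2)
  if (lmax >= 2) for (l in 1:(lmax - 1))
    out[, l + 2] <- out[, l] + (2 * l + 1) / x * out[, l + 1]
  out
}

## matrix of P_l(c) for l = 0..lmax, rows follow c
.pl_table <- function(c, lmax) {
  out <- matrix(0, length(c), lmax + 1)
  out[, 1] <- 1
  if (lmax >= 1) out[, 2] <- c
  if (lmax >= 2) for (l in 1:(lmax - 1))
    out[, l + 2] <- ((2 * l + 1) * c * out[, l + 1] - l * out[, l]) / (l + 1)
  out
}

.il_at <- function(l, x) sqrt(pi / (2 * x)) * besselI(x, l + 0.5)
.kl_at <- function(l, x) sqrt(2 / (pi * x)) * besselK(x, l + 0.5)
## derivative recurrences: k_l' = -k_{l-1} - (l+1)/x k_l  (k_{-1} = k_0)
##                         i_l' =  i_{l-1} - (l+1)/x i_l  (i_{-1} = cosh x / x)
.kl_prime <- function(l, x) {
  km1 <- if (l == 0) .kl_at(0, x) else .kl_at(l - 1, x)
  -km1 - (l + 1) / x * .kl_at(l, x)
}
.il_prime <- function(l, x) {
  im1 <- if (l == 0) cosh(x) / x else .il_at(l - 1, x)
  im1 - (l + 1) / x * .il_at(l, x)
}

## denominator D_l = eps_part * l * k_l(ka) - eps_water * ka * k_l'(ka)
.denom_l <- function(l, ka, eps_part, eps_water)
  eps_part * l * .kl_at(l, ka) - eps_water * ka * .kl_prime(l, ka)

#' Surface charge density of the patchy sphere
#'
#' Evaluates the smoothed two-cap profile
#' sigma(theta) = sigma_p/2 \[1 - tanh(n(theta - theta_p))\]
#'              - sigma_n/2 \[1 + tanh(n(theta - theta_n))\].
#'
#' @param theta Polar angle(s) in radians, in \[0, pi\].
#' @param particle A [patchy_particle()] object.
#' @return Charge density in C/m^2 (same length as `theta`).
#' @export
surface_charge_density <- function(theta, particle) {
  stopifnot(inherits(particle, "patchy_particle"))
  if (any(theta < 0 | theta > pi))
    stop("domain error: theta must lie in [0, pi]")
  n <- particle$abruptness
  particle$sigma_p / 2 * (1 - tanh(n * (theta - particle$theta_p))) -
    particle$sigma_n / 2 * (1 + tanh(n * (theta - particle$theta_n)))
}

#' Multipole coefficients of the patchy sphere potential
#'
#' Computes the coefficients of the Debye-Hueckel multipole series for the
#' dimensionless potential of the patchy dielectric sphere,
#' \deqn{\Psi_\sigma(r,\theta) = \sum_{l=0}^{l_{max}} C_l\, k_l(\kappa r)
#'   P_l(\cos\theta),}
#' with \eqn{C_l = 2\pi l_B \epsilon_w (2l+1)\, a\, I_l / D_l}, where
#' \eqn{I_l = \int_0^\pi \tilde\sigma(\theta) P_l(\cos\theta)
#' \sin\theta\, d\theta} (charge density in e0/Angstrom^2) and
#' \eqn{D_l = \epsilon_{part}\, l\, k_l(\kappa a) - \epsilon_w \kappa a\,
#' k_l'(\kappa a)}.  The angular integrals are evaluated by Gauss-Legendre
#' quadrature in cos(theta); convergence is verified by node doubling.
#'
#' @param particle A [patchy_particle()] object.
#' @param solution A [solution_conditions()] object with kappa > 0
#'   (salt >= 1e-4 mM; the screened series is ill-defined at zero salt).
#' @param n_nodes Number of Gauss-Legendre nodes (default 1024).
#' @return Object of class `multipole_set` with fields `coef` (C_l),
#'   `integrals` (I_l), `kappa`, `lmax`, `particle`, `solution`.
#' @export
multipole_coefficients <- function(particle, solution, n_nodes = 1024) {
  stopifnot(inherits(particle, "patchy_particle"),
            inherits(solution, "solution_conditions"))
  if (solution$kappa * particle$radius <= 1e-8 ||
      solution$salt_mM < 1e-4)
    stop("screened multipole series requires salt >= 1e-4 mM (kappa > 0)")
  lmax <- particle$lmax
  quad_I <- function(n) {
    gl <- pracma::gaussLegendre(n, -1, 1)
    th <- acos(gl$x)
    sig <- convert_sigma(surface_charge_density(th, particle))
    drop(crossprod(.pl_table(gl$x, lmax), gl$w * sig))
  }
  I1 <- quad_I(n_nodes)
  I2 <- quad_I(2 * n_nodes)
  scale <- max(abs(I2), 1e-30)
  if (max(abs(I2 - I1)) / scale > 1e-8)
    stop(sprintf(paste0("angular quadrature not converged at %d nodes ",
                        "(max rel change %.3g on doubling)"),
                 n_nodes, max(abs(I2 - I1)) / scale))
  ka <- solution$kappa * particle$radius
  l <- 0:lmax
  D <- vapply(l, .denom_l, numeric(1), ka = ka,
              eps_part = particle$eps_part, eps_water = solution$eps_water)
  coef <- 2 * pi * solution$lB * solution$eps_water *
    (2 * l + 1) * particle$radius * I2 / D
  structure(list(coef = coef, integrals = I2, denominators = D,
                 kappa = solution$kappa, lmax = lmax,
                 particle = particle, solution = solution),
            class = "multipole_set")
}

#' Dimensionless potential of the patchy sphere
#'
#' Evaluates the multipole series Psi_sigma(r, theta) outside the particle.
#' The normalization is fixed so that the uniformly charged sphere
#' reproduces the closed-form Debye-Hueckel potential
#' lB Z exp(-kappa (r-a)) / (r (1 + kappa a)).
#'
#' @param r Radial distance(s) from the particle center, Angstrom (>= a).
#' @param theta Polar angle(s) in radians.
#' @param multipoles A [multipole_coefficients()] object.
#' @return Dimensionless potential (in units of kBT/e0), vectorized over
#'   `r`/`theta` (recycled to common length).
#' @export
psi_sigma <- function(r, theta, multipoles) {
  stopifnot(inherits(multipoles, "multipole_set"))
  n <- max(length(r), length(theta))
  r <- rep_len(r, n); theta <- rep_len(theta, n)
  if (any(r < multipoles$particle$radius * (1 - 1e-12)))
    stop("domain error: r < particle radius (interior potential not evaluated)")
  kl <- .kl_table(multipoles$kappa * r, multipoles$lmax)
  pl <- .pl_table(cos(theta), multipoles$lmax)
  drop((kl * pl) %*% multipoles$coef)
}

#' Polarization (image-charge) kernel of the dielectric sphere
#'
#' Precomputes the source-independent factors of the polarization potential
#' series: \eqn{R_l = l_B \kappa (2l+1)
#' [\epsilon_w \kappa a\, i_l'(\kappa a) - \epsilon_{part}\, l\, i_l(\kappa a)]
#' / D_l}, so that the potential at x generated by the polarization charges
#' induced by a unit charge at y is
#' \eqn{\Psi_{polar} = \sum_l R_l k_l(\kappa |y|) k_l(\kappa |x|)
#' P_l(\cos\gamma)} with gamma the angle between x and y.  For
#' eps_part < eps_water the self term is positive (repulsive); the kernel is
#' nonzero even at eps_part = eps_water because of ion exclusion from the
#' particle interior.
#'
#' @param particle A [patchy_particle()] object.
#' @param solution A [solution_conditions()] object with kappa > 0.
#' @return Object of class `polarization_kernel` with fields `ratios`
#'   (R_l including the lB*kappa prefactor), `kappa`, `lmax`, `particle`.
#' @export
polarization_kernel <- function(particle, solution) {
  stopifnot(inherits(particle, "patchy_particle"),
            inherits(solution, "solution_conditions"))
  if (solution$kappa <= 0)
    stop("polarization kernel requires kappa > 0")
  lmax <- particle$lmax
  ka <- solution$kappa * particle$radius
  l <- 0:lmax
  num <- vapply(l, function(ll)
    solution$eps_water * ka * .il_prime(ll, ka) -
      particle$eps_part * ll * .il_at(ll, ka), numeric(1))
  D <- vapply(l, .denom_l, numeric(1), ka = ka,
              eps_part = particle$eps_part, eps_water = solution$eps_water)
  if (any(!is.finite(num / D)))
    stop("polarization kernel: vanishing denominator for some l")
  structure(list(ratios = solution$lB * solution$kappa * (2 * l + 1) * num / D,
                 kappa = solution$kappa, lmax = lmax,
                 particle = particle, solution = solution),
            class = "polarization_kernel")
}

#' Polarization potential between two exterior points
#'
#' Dimensionless potential at `field` generated by the polarization
#' (image) charges that a unit charge at `source` induces on the dielectric
#' sphere.  Symmetric under exchange of the two points.
#'
#' @param field,source Cartesian positions (length-3 vectors or n x 3
#'   matrices, Angstrom, particle-centered), both with |x| >= a.
#' @param kernel A [polarization_kernel()] object.
#' @return Dimensionless potential per unit source charge.
#' @export
psi_polar <- function(field, source, kernel) {
  stopifnot(inherits(kernel, "polarization_kernel"))
  f <- if (is.matrix(field)) field else matrix(field, ncol = 3)
  s <- if (is.matrix(source)) source else matrix(source, ncol = 3)
  n <- max(nrow(f), nrow(s))
  f <- f[rep_len(seq_len(nrow(f)), n), , drop = FALSE]
  s <- s[rep_len(seq_len(nrow(s)), n), , drop = FALSE]
  rf <- sqrt(rowSums(f^2)); rs <- sqrt(rowSums(s^2))
  a <- kernel$particle$radius
  if (any(rf < a * (1 - 1e-12)) || any(rs < a * (1 - 1e-12)))
    stop("domain error: point inside the particle")
  cg <- pmin(1, pmax(-1, rowSums(f * s) / (rf * rs)))
  klf <- .kl_table(kernel$kappa * rf, kernel$lmax)
  kls <- .kl_table(kernel$kappa * rs, kernel$lmax)
  pl <- .pl_table(cg, kernel$lmax)
  drop((klf * kls * pl) %*% kernel$ratios)
}

#' Self polarization potential at a point
#'
#' Potential of a unit charge's own image charges evaluated back at the
#' charge location: \eqn{\sum_l R_l k_l(\kappa r)^2}.  The corresponding
#' self energy of the charge is one half of this value.
#'
#' @param r Radial distance(s) from the particle center (>= a), Angstrom.
#' @param kernel A [polarization_kernel()] object.
#' @return Dimensionless potential, vectorized over `r`.
#' @export
psi_polar_self <- function(r, kernel) {
  stopifnot(inherits(kernel, "polarization_kernel"))
  if (any(r < kernel$particle$radius * (1 - 1e-12)))
    stop("domain error: r < particle radius")
  kl <- .kl_table(kernel$kappa * r, kernel$lmax)
  drop((kl * kl) %*% kernel$ratios)
}
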