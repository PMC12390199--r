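#' @useDynLib patchyPE, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor integrate lm coef predict sd runif ks.test rbinom
#'   quantile setNames
#' @importFrom utils read.csv write.csv head tail
NULL

## CODATA 2018 constants (SI)
.const <- list(
  e0   = 1.602176634e-19,   # C
  eps0 = 8.8541878128e-12,  # F/m
  kB   = 1.380649e-23,      # J/K
  NA_  = 6.02214076e23      # 1/mol
)

## Internal unit system: lengths in Angstrom, energies in kBT, charges in e0.
## 1 C/m^2 expressed in e0/A^2:
.SIGMA_E0_A2 <- .const$e0^-1 * 1e-20  # = 0.0624151...

#' Physical constants used by the package
#'
#' Returns the CODATA values of the elementary charge, vacuum permittivity,
#' Boltzmann constant and Avogadro number, together with the conversion
#' factor from C/m^2 to e0/Angstrom^2.  All internal computations use
#' Angstrom / kBT / e0 units; SI inputs are converted at the boundary.
#'
#' @return Named list of constants.
#' @export
unit_registry <- function() {
  c(.const, list(sigma_Cm2_to_e0A2 = .SIGMA_E0_A2))
}

#' Convert a surface charge density from C/m^2 to e0/Angstrom^2
#'
#' @param sigma_Cm2 Surface charge density in C/m^2.
#' @return Charge density in elementary charges per square Angstrom.
#' @examples
#' convert_sigma(0.03)  # 1.8725e-3 e0/A^2
#' @export
convert_sigma <- function(sigma_Cm2) {
  stopifnot(is.numeric(sigma_Cm2), all(is.finite(sigma_Cm2)))
  sigma_Cm2 * .SIGMA_E0_A2
}

#' Convert a surface charge density from e0/Angstrom^2 back to C/m^2
#'
#' Exact inverse of [convert_sigma()].
#' @param sigma_e0A2 Charge density in e0/Angstrom^2.
#' @return Density in C/m^2.
#' @export
convert_sigma_inverse <- function(sigma_e0A2) {
  stopifnot(is.numeric(sigma_e0A2), all(is.finite(sigma_e0A2)))
  sigma_e0A2 / .SIGMA_E0_A2
}

#' Convert a harmonic spring constant from N/m to kBT/Angstrom^2
#'
#' The bead-spring bond potential is u(r) = k (r - r0)^2 with k commonly
#' quoted in N/m; internally energies are measured in units of the thermal
#' energy at the simulation temperature.
#'
#' @param k_Nm Spring constant in N/m (>= 0).
#' @param temperature Temperature in kelvin.
#' @return Spring constant in kBT/Angstrom^2.
#' @examples
#' convert_bond_k(0.5, 298.15)  # ~1.215
#' @export
convert_bond_k <- function(k_Nm, temperature = 298.15) {
  if (!is.numeric(temperature) || temperature <= 0)
    stop("invalid parameter 'temperature': must be > 0 K")
  stopifnot(is.numeric(k_Nm), all(k_Nm >= 0))
  k_Nm * 1e-20 / (.const$kB * temperature)
}

#' Convert a spring constant from kBT/Angstrom^2 back to N/m
#' @param k_kT Spring constant in kBT/Angstrom^2.
#' @param temperature Temperature in kelvin.
#' @return Spring constant in N/m.
#' @export
convert_bond_k_inverse <- function(k_kT, temperature = 298.15) {
  if (!is.numeric(temperature) || temperature <= 0)
    stop("invalid parameter 'temperature': must be > 0 K")
  k_kT * (.const$kB * temperature) / 1e-20
}

#' Solution conditions of the 1:1 electrolyte
#'
#' Bundles temperature, solvent relative permittivity and salt concentration,
#' and precomputes the Bjerrum length and inverse Debye length.  The solvent
#' permittivity is treated as independent of the salt concentration.
#'
#' @param salt_mM Concentration of 1:1 salt in mmol/L (>= 0).
#' @param temperature Temperature in kelvin (default 298.15).
#' @param eps_water Relative permittivity of the solvent (default 78.7).
#' @return Object of class `solution_conditions` with fields `temperature`,
#'   `eps_water`, `salt_mM`, `n0` (ion-pair number density in 1/Angstrom^3),
#'   `lB` (Bjerrum length, Angstrom) and `kappa` (inverse Debye length,
#'   1/Angstrom).
#' @examples
#' sol <- solution_conditions(5)
#' sol$kappa * 70  # = 1.625 for a 70 Angstrom sphere
#' @export
solution_conditions <- function(salt_mM, temperature = 298.15,
                                eps_water = 78.7) {
  if (!is.numeric(temperature) || length(temperature) != 1 || temperature <= 0)
    stop("invalid parameter 'temperature': must be a single value > 0 K")
  if (!is.numeric(eps_water) || length(eps_water) != 1 || eps_water <= 0)
    stop("invalid parameter 'eps_water': must be a single value > 0")
  if (!is.numeric(salt_mM) || length(salt_mM) != 1 || salt_mM < 0)
    stop("invalid parameter 'salt_mM': must be a single value >= 0")
  n0 <- salt_mM * 1e-3 * .const$NA_ / 1e27  # ion pairs per Angstrom^3
  lB <- .const$e0^2 /
    (4 * pi * .const$eps0 * eps_water * .const$kB * temperature) * 1e10
  structure(list(
    temperature = temperature, eps_water = eps_water,
    salt_mM = salt_mM, n0 = n0,
    lB = lB, kappa = sqrt(8 * pi * lB * n0)
  ), class = "solution_conditions")
}

#' Bjerrum length of the solution
#'
#' Distance at which two elementary charges in the solvent interact with
#' thermal energy kBT: lB = e0^2 / (4 pi eps0 eps_water kB T).
#'
#' @param solution A [solution_conditions()] object.
#' @return Bjerrum length in Angstrom.
#' @export
bjerrum_length <- function(solution) {
  stopifnot(inherits(solution, "solution_conditions"))
  solution$lB
}

#' Inverse Debye screening length
#'
#' kappa = sqrt(8 pi lB n0) for a 1:1 electrolyte with ion-pair number
#' density n0; zero at zero salt.
#'
#' @param solution A [solution_conditions()] object.
#' @return kappa in 1/Angstrom.
#' @export
inverse_debye_length <- function(solution) {
  stopifnot(inherits(solution, "solution_conditions"))
  solution$kappa
}

#' @export
print.solution_conditions <- function(x, ...) {
  cat(sprintf(
    "1:1 electrolyte: %.4g mM, T = %.2f K, eps_water = %.1f\n",
    x$salt_mM, x$temperature, x$eps_water))
  cat(sprintf("  Bjerrum length  lB = %.4f A\n", x$lB))
  if (x$kappa > 0)
    cat(sprintf("  Debye length   1/k = %.2f A  (kappa = %.5g 1/A)\n",
                1 / x$kappa, x$kappa))
  else cat("  No screening (zero salt)\n")
  invisible(x)
}

#' Convert a target dimensionless screening kappa*a to a salt concentration
#'
#' Convenience inverse of the kappa(salt) relation at fixed particle radius:
#' returns the 1:1 salt concentration (mM) for which the inverse Debye length
#' times `radius` equals `kappa_a`.
#'
#' @param kappa_a Target dimensionless screening parameter (>= 0).
#' @param radius Particle radius in Angstrom.
#' @param temperature Temperature in kelvin.
#' @param eps_water Solvent relative permittivity.
#' @return Salt concentration in mM.
#' @export
salt_for_kappa_a <- function(kappa_a, radius, temperature = 298.15,
                             eps_water = 78.7) {
  stopifnot(kappa_a >= 0, radius > 0)
  lB <- .const$e0^2 /
    (4 * pi * .const$eps0 * eps_water * .const$kB * temperature) * 1e10
  n0 <- (kappa_a / radius)^2 / (8 * pi * lB)       # 1/A^3
  n0 * 1e27 / .const$NA_ * 1e3                     # mM
}
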