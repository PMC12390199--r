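#' Patchy spherical particle
#'
#' A sphere of radius `radius` whose axisymmetric surface charge density is
#' \deqn{\sigma(\theta) = \frac{\sigma_p}{2}[1 - \tanh(n(\theta-\theta_p))]
#'   - \frac{\sigma_n}{2}[1 + \tanh(n(\theta-\theta_n))]}
#' i.e. a positive cap of density `sigma_p` for theta < theta_p, a negative
#' cap of density -`sigma_n` for theta > theta_n, and a neutral belt in
#' between, with smooth tanh transitions of width ~1/`abruptness` radians.
#' The particle interior has relative permittivity `eps_part`; a value below
#' the solvent permittivity generates repulsive image-charge interactions.
#'
#' @param sigma_p,sigma_n Cap charge density magnitudes in C/m^2 (both >= 0;
#'   the negative cap carries density -`sigma_n`).
#' @param theta_p,theta_n Cap boundary polar angles in radians,
#'   0 <= theta_p <= theta_n <= pi.
#' @param radius Sphere radius in Angstrom (default 70).
#' @param eps_part Interior relative permittivity (default 78.7, i.e. no
#'   dielectric contrast with water).
#' @param abruptness Sharpness n of the tanh transition, per radian
#'   (default 20).
#' @param lmax Multipole series truncation; terms l = 0..lmax are kept
#'   (default 10).
#' @return Object of class `patchy_particle`.
#' @examples
#' p <- patchy_particle(sigma_p = 0.03, sigma_n = 0.03,
#'                      theta_p = 2 * pi / 3, theta_n = 2 * pi / 3)
#' @export
patchy_particle <- function(sigma_p = 0, sigma_n = 0,
                            theta_p = pi / 2, theta_n = pi / 2,
                            radius = 70, eps_part = 78.7,
                            abruptness = 20, lmax = 10) {
  if (!is.numeric(radius) || radius <= 0)
    stop("invalid parameter 'radius': must be > 0 Angstrom")
  if (!is.numeric(eps_part) || eps_part <= 0)
    stop("invalid parameter 'eps_part': must be > 0")
  if (sigma_p < 0) stop("invalid parameter 'sigma_p': must be >= 0 C/m^2")
  if (sigma_n < 0) stop("invalid parameter 'sigma_n': must be >= 0 C/m^2")
  if (theta_p < 0 || theta_n > pi || theta_p > theta_n)
    stop("invalid parameters 'theta_p'/'theta_n': need 0 <= theta_p <= theta_n <= pi")
  if (abruptness <= 0) stop("invalid parameter 'abruptness': must be > 0")
  if (lmax < 0 || lmax != round(lmax))
    stop("invalid parameter 'lmax': must be a non-negative integer")
  structure(list(
    radius = radius, eps_part = eps_part,
    sigma_p = sigma_p, sigma_n = sigma_n,
    theta_p = theta_p, theta_n = theta_n,
    abruptness = abruptness, lmax = as.integer(lmax)
  ), class = "patchy_particle")
}

#' @export
print.patchy_particle <- function(x, ...) {
  cat(sprintf("Patchy sphere: a = %g A, eps_part = %g\n", x$radius, x$eps_part))
  cat(sprintf("  sigma_p = %g C/m^2 (theta < %.1f deg), sigma_n = %g C/m^2 (theta > %.1f deg)\n",
              x$sigma_p, x$theta_p * 180 / pi, x$sigma_n, x$theta_n * 180 / pi))
  cat(sprintf("  transition abruptness n = %g/rad, lmax = %d\n",
              x$abruptness, x$lmax))
  cat(sprintf("  net charge = %.2f e0\n", particle_net_charge(x)))
  invisible(x)
}

#' Net charge of a patchy particle
#'
#' Integrates the smoothed surface charge profile over the sphere.  For the
#' step-function limit with theta_p = theta_n = theta the result is
#' 2 pi a^2 \[sigma_p (1 - cos theta) - sigma_n (1 + cos theta)\] (in e0 after
#' conversion); with the default abruptness the smoothed value is within ~1%.
#'
#' @param particle A [patchy_particle()] object.
#' @return Net charge in units of e0.
#' @export
particle_net_charge <- function(particle) {
  stopifnot(inherits(particle, "patchy_particle"))
  f <- function(th) surface_charge_density(th, particle) * sin(th)
  integ <- integrate(f, 0, pi, rel.tol = 1e-10, abs.tol = 1e-12)$value
  2 * pi * particle$radius^2 * convert_sigma(integ)
}

#' Bead-spring chain parameters
#'
#' The polyelectrolyte is a linear chain of `n_beads` spherical beads of
#' radius `bead_radius`, each carrying `bead_valence` elementary charges,
#' joined by harmonic bonds u(r) = k (r - r0)^2.  Bonded neighbours also
#' interact through the screened Coulomb pair potential; the hard-core
#' contact distance between beads is 2 `bead_radius`.
#'
#' @param n_beads Number of beads N (>= 1, default 50).
#' @param bead_radius Bead radius b in Angstrom (default 2).
#' @param bond_r0 Equilibrium bond length in Angstrom (default 7).
#' @param bond_k_Nm Spring constant in N/m (default 0.5); converted
#'   internally to kBT/Angstrom^2 at `temperature`.
#' @param bead_valence Charge per bead in e0 (default +1).
#' @param temperature Temperature used for the spring-constant conversion.
#' @return Object of class `chain_parameters` with the internal-unit spring
#'   constant in field `bond_k` (kBT/Angstrom^2).
#' @export
chain_parameters <- function(n_beads = 50, bead_radius = 2, bond_r0 = 7,
                             bond_k_Nm = 0.5, bead_valence = 1,
                             temperature = 298.15) {
  if (n_beads < 1 || n_beads != round(n_beads))
    stop("invalid parameter 'n_beads': must be a positive integer")
  if (bead_radius <= 0) stop("invalid parameter 'bead_radius': must be > 0")
  if (bond_r0 <= 0) stop("invalid parameter 'bond_r0': must be > 0")
  if (bond_k_Nm < 0) stop("invalid parameter 'bond_k_Nm': must be >= 0")
  structure(list(
    n_beads = as.integer(n_beads), bead_radius = bead_radius,
    bond_r0 = bond_r0, bond_k_Nm = bond_k_Nm,
    bond_k = convert_bond_k(bond_k_Nm, temperature),
    bead_valence = bead_valence
  ), class = "chain_parameters")
}

#' Monte Carlo simulation protocol
#'
#' Controls the box, the move schedule and the sampling.  The spherical
#' simulation box is a hard reflecting wall implemented by move rejection.
#' During equilibration, move amplitudes are tuned multiplicatively toward
#' ~50% acceptance; amplitudes are frozen before production so the
#' production chain satisfies detailed balance.
#'
#' @param box_radius Radius of the spherical box in Angstrom.  The default,
#'   `NULL`, resolves to radius + N*r0 + 100 when the run is assembled.
#' @param equilibration_moves Number of equilibration MC moves (default 1e6).
#' @param sampling_interval Moves between recorded samples (default 1000).
#' @param n_samples Number of recorded samples (default 1e4).
#' @param seed Integer RNG seed for the engine's own generator.
#' @param image_charges Logical; include the polarization (image-charge)
#'   interactions of the dielectric interface (default FALSE).
#' @param adsorption_threshold Binding-energy threshold in kBT below which a
#'   sample is classified as adsorbed (default -1).
#' @param move_kinds Character vector of enabled move kinds among
#'   `"pivot"`, `"crankshaft"`, `"displace"`, `"translate"`, `"rotate"`;
#'   selection among enabled kinds is uniform.
#' @param amplitudes Named list of initial move amplitudes:
#'   `pivot`/`crankshaft`/`rotate` in radians, `displace`/`translate` in
#'   Angstrom.  Missing entries take defaults.
#' @param tune Logical; tune amplitudes during equilibration (default TRUE).
#' @param tune_window Moves per tuning window (default 2000).
#' @param snapshot_every Record a configuration snapshot every this many
#'   samples (0 = no snapshots).
#' @return Object of class `simulation_protocol`.
#' @export
simulation_protocol <- function(box_radius = NULL,
                                equilibration_moves = 1e6,
                                sampling_interval = 1000,
                                n_samples = 1e4,
                                seed = 1,
                                image_charges = FALSE,
                                adsorption_threshold = -1,
                                move_kinds = c("pivot", "crankshaft",
                                               "displace", "translate",
                                               "rotate"),
                                amplitudes = list(),
                                tune = TRUE,
                                tune_window = 2000,
                                snapshot_every = 0) {
  if (sampling_interval < 1) stop("invalid parameter 'sampling_interval': must be >= 1")
  if (n_samples < 1) stop("invalid parameter 'n_samples': must be >= 1")
  if (equilibration_moves < 0) stop("invalid parameter 'equilibration_moves': must be >= 0")
  move_kinds <- match.arg(move_kinds, several.ok = TRUE)
  amp <- list(pivot = pi / 2, crankshaft = pi / 2, displace = 5,
              translate = NA_real_, rotate = pi / 2)
  for (nm in names(amplitudes)) {
    if (!nm %in% names(amp)) stop("unknown amplitude name: ", nm)
    amp[[nm]] <- amplitudes[[nm]]
  }
  structure(list(
    box_radius = box_radius,
    equilibration_moves = equilibration_moves,
    sampling_interval = as.integer(sampling_interval),
    n_samples = as.integer(n_samples),
    seed = as.integer(seed),
    image_charges = isTRUE(image_charges),
    adsorption_threshold = adsorption_threshold,
    move_kinds = move_kinds,
    amplitudes = amp,
    tune = isTRUE(tune),
    tune_window = as.integer(tune_window),
    snapshot_every = as.integer(snapshot_every)
  ), class = "simulation_protocol")
}

.default_box_radius <- function(particle, chain) {
  particle$radius + chain$n_beads * chain$bond_r0 + 100
}

## ---- configuration files ----------------------------------------------

.config_schema <- list(
  solution = c("temperature_K", "eps_water", "salt_mM"),
  particle = c("radius_A", "eps_part", "sigma_p_Cm2", "sigma_n_Cm2",
               "theta_p_deg", "theta_n_deg", "abruptness", "lmax"),
  chain    = c("n_beads", "bead_radius_A", "bond_r0_A", "bond_k_Nm",
               "bead_valence"),
  protocol = c("box_radius_A", "equilibration_moves", "sampling_interval",
               "n_samples", "seed", "image_charges",
               "adsorption_threshold_kT", "snapshot_every")
)

#' Load a YAML run configuration
#'
#' Parses a structured YAML file with sections `solution`, `particle`,
#' `chain` and `protocol`; keys carry explicit units in their names
#' (e.g. `salt_mM`, `sigma_p_Cm2`, `theta_p_deg`).  Unknown keys are
#' rejected (a typo in a physics parameter must not pass silently) and all
#' invariants are validated.  Omitted keys take the package defaults
#' (a = 70 A, N = 50, b = 2 A, r0 = 7 A, k = 0.5 N/m, n = 20, lmax = 10,
#' T = 298.15 K, eps_water = 78.7).
#'
#' @param path Path to a YAML file.
#' @return List with validated components `solution`, `particle`, `chain`,
#'   `protocol`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  bad_sec <- setdiff(names(cfg), names(.config_schema))
  if (length(bad_sec))
    stop("unknown config section(s): ", paste(bad_sec, collapse = ", "))
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), .config_schema[[sec]])
    if (length(bad))
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
  }
  g <- function(sec, key, default) {
    v <- cfg[[sec]][[key]]
    if (is.null(v)) default else v
  }
  solution <- solution_conditions(
    salt_mM = g("solution", "salt_mM", 5),
    temperature = g("solution", "temperature_K", 298.15),
    eps_water = g("solution", "eps_water", 78.7))
  particle <- patchy_particle(
    radius = g("particle", "radius_A", 70),
    eps_part = g("particle", "eps_part", 78.7),
    sigma_p = g("particle", "sigma_p_Cm2", 0),
    sigma_n = g("particle", "sigma_n_Cm2", 0),
    theta_p = g("particle", "theta_p_deg", 90) * pi / 180,
    theta_n = g("particle", "theta_n_deg", 90) * pi / 180,
    abruptness = g("particle", "abruptness", 20),
    lmax = g("particle", "lmax", 10))
  chain <- chain_parameters(
    n_beads = g("chain", "n_beads", 50),
    bead_radius = g("chain", "bead_radius_A", 2),
    bond_r0 = g("chain", "bond_r0_A", 7),
    bond_k_Nm = g("chain", "bond_k_Nm", 0.5),
    bead_valence = g("chain", "bead_valence", 1),
    temperature = solution$temperature)
  protocol <- simulation_protocol(
    box_radius = g("protocol", "box_radius_A", NULL),
    equilibration_moves = g("protocol", "equilibration_moves", 1e6),
    sampling_interval = g("protocol", "sampling_interval", 1000),
    n_samples = g("protocol", "n_samples", 1e4),
    seed = g("protocol", "seed", 1),
    image_charges = g("protocol", "image_charges", FALSE),
    adsorption_threshold = g("protocol", "adsorption_threshold_kT", -1),
    snapshot_every = g("protocol", "snapshot_every", 0))
  box <- if (is.null(protocol$box_radius))
    .default_box_radius(particle, chain) else protocol$box_radius
  if (box <= particle$radius + 2 * chain$bead_radius)
    stop("invalid parameter 'box_radius_A': box too small for the particle")
  protocol$box_radius <- box
  list(solution = solution, particle = particle, chain = chain,
       protocol = protocol)
}
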