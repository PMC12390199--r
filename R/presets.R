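## Reference parameter bundles and plain-text writers/readers.

.preset_table <- function() {
  j120 <- function(sp, ka) list(
    sigma_p = sp, sigma_n = 0.03, theta_deg = 120, eps_part = 78.7,
    kappa_a = ka, images = FALSE)
  dens <- function(theta, eps) list(
    sigma_p = 0.03, sigma_n = 0.03, theta_deg = theta, eps_part = eps,
    kappa_a = 1.625036, images = eps < 78.7)
  list(
    ## two-cap particle, net charge from neutral to strongly positive
    janus120_neutral           = j120(0.01, 1.625036),
    janus120_net_positive_mid  = j120(0.02, 1.625036),
    janus120_net_positive_high = j120(0.03, 1.625036),
    ## coexistence state points of the strongly net-positive particle
    coexistence_low_salt       = j120(0.03, 0.91),
    coexistence_high_salt      = j120(0.03, 4.11),
    ## monomer-density study: equal caps at 5 mM, with and without a
    ## low-dielectric interior
    density_eps78_theta120 = dens(120, 78.7),
    density_eps78_theta90  = dens(90, 78.7),
    density_eps78_theta45  = dens(45, 78.7),
    density_eps78_theta0   = dens(0, 78.7),
    density_eps4_theta120  = dens(120, 4),
    density_eps4_theta90   = dens(90, 4),
    density_eps4_theta45   = dens(45, 4),
    density_eps4_theta0    = dens(0, 4),
    ## homogeneously (negatively) charged sphere baseline
    uniform_sphere = list(sigma_p = 0, sigma_n = 0.03, theta_deg = 0,
                          eps_part = 78.7, kappa_a = 1.625036,
                          images = FALSE)
  )
}

#' Named reference parameter bundles
#'
#' Assembles a complete, validated parameter set (solution, particle,
#' chain, protocol) for the study conditions explored by the package:
#' a 70 Angstrom sphere with two oppositely charged caps
#' (`janus120_*`, boundary angles at 120 degrees, sigma_n = 0.03 C/m^2),
#' the two adsorbed/desorbed coexistence state points of the strongly
#' net-positive particle (`coexistence_low_salt` at kappa*a = 0.91,
#' `coexistence_high_salt` at kappa*a = 4.11), the 5 mM monomer-density
#' study over patch angles 0-120 degrees with solvent-matched or
#' low-dielectric (eps_part = 4, image charges on) interior
#' (`density_eps*_theta*`), and a homogeneously charged sphere baseline
#' (`uniform_sphere`).  The chain is the standard 50-bead, +1/bead chain.
#'
#' @param name Preset name; call with no arguments to list valid names.
#' @param fidelity `"desk"` (1e4 samples, the package default) or
#'   `"full"` (1e7 samples, matching full-scale production statistics).
#' @param seed Protocol seed.
#' @return List with `solution`, `particle`, `chain`, `protocol`.
#' @export
make_preset <- function(name, fidelity = c("desk", "full"), seed = 1) {
  tab <- .preset_table()
  if (missing(name)) return(names(tab))
  if (!name %in% names(tab))
    stop("unknown preset '", name, "'; available: ",
         paste(names(tab), collapse = ", "))
  fidelity <- match.arg(fidelity)
  p <- tab[[name]]
  th <- p$theta_deg * pi / 180
  particle <- patchy_particle(sigma_p = p$sigma_p, sigma_n = p$sigma_n,
                              theta_p = th, theta_n = th,
                              eps_part = p$eps_part)
  solution <- solution_conditions(salt_for_kappa_a(p$kappa_a,
                                                   particle$radius))
  chain <- chain_parameters()
  protocol <- simulation_protocol(
    box_radius = .default_box_radius(particle, chain),
    equilibration_moves = 1e6,
    sampling_interval = 1000,
    n_samples = if (fidelity == "full") 1e7 else 1e4,
    seed = seed, image_charges = p$images)
  list(solution = solution, particle = particle, chain = chain,
       protocol = protocol)
}

#' Write a sample series to CSV with a JSON metadata sidecar
#'
#' The CSV holds the per-sample observables; `<path>.meta.json` records
#' the full parameter set, seed and package version so a series is
#' reproducible from its files alone.
#'
#' @param samples A `pe_samples` object from [run_simulation()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_series <- function(samples, path) {
  stopifnot(inherits(samples, "pe_samples"))
  d <- as.data.frame(samples)
  ## round-trip exactness: 17 significant digits preserve doubles
  for (cn in c("E_B", "Rg2", "min_dist", "n_moves"))
    d[[cn]] <- sprintf("%.17g", d[[cn]])
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  pr <- attr(samples, "params")
  meta <- list(
    format_version = 1L,
    package_version = as.character(utils::packageVersion("patchyPE")),
    solution = unclass(pr$solution),
    particle = unclass(pr$particle),
    chain = unclass(pr$chain),
    protocol = unclass(pr$protocol[setdiff(names(pr$protocol),
                                           "amplitudes")]),
    amplitudes = pr$protocol$amplitudes,
    box_radius = pr$box_radius,
    acceptance = as.list(attr(samples, "acceptance")))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a sample series written by [write_series()]
#'
#' @param path CSV path.
#' @return Data.frame of samples with the metadata list in attribute
#'   `meta`.
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("series file not found: ", path)
  d <- read.csv(path)
  need <- c("sample", "n_moves", "E_B", "Rg2", "min_dist", "adsorbed")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop("series schema mismatch (format_version 1): missing column(s) ",
         paste(missing_cols, collapse = ", "))
  mpath <- paste0(path, ".meta.json")
  meta <- if (file.exists(mpath)) jsonlite::read_json(mpath) else NULL
  structure(d, meta = meta)
}

#' Write configuration snapshots as XYZ frames
#'
#' Standard multi-frame XYZ: each frame holds the particle as one
#' pseudo-atom (`P`) at the origin followed by the beads (`C`), with
#' coordinates in Angstrom, loadable by common molecular viewers.
#'
#' @param snapshots List of N x 3 configuration matrices.
#' @param path Output file path.
#' @param comment Comment-line prefix per frame.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(snapshots, path, comment = "patchyPE frame") {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(snapshots)) {
    p <- .as_positions(snapshots[[i]])
    writeLines(as.character(nrow(p) + 1), con)
    writeLines(sprintf("%s %d", comment, i), con)
    writeLines("P 0.000000 0.000000 0.000000", con)
    writeLines(sprintf("C %.6f %.6f %.6f", p[, 1], p[, 2], p[, 3]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ file written by [write_xyz()]
#'
#' @param path XYZ file path.
#' @return List of bead coordinate matrices (the particle pseudo-atom is
#'   dropped).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- do.call(rbind, strsplit(trimws(block), "\\s+"))
    coords <- matrix(as.numeric(parts[, 2:4]), ncol = 3)
    frames[[length(frames) + 1]] <- coords[parts[, 1] != "P", , drop = FALSE]
    i <- i + 2 + n
  }
  frames
}
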