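#' Squared radius of gyration
#'
#' Mean squared distance of the beads from their centroid.
#'
#' @param positions N x 3 position matrix.
#' @return Rg^2 in Angstrom^2.
#' @examples
#' rg_sq(rbind(c(0, 0, 0), c(7, 0, 0)))  # (7/2)^2
#' @export
rg_sq <- function(positions) {
  p <- .as_positions(positions)
  sum(sweep(p, 2, colMeans(p))^2) / nrow(p)
}

#' Classify a sample as adsorbed
#'
#' A configuration counts as adsorbed when its binding energy lies strictly
#' below the threshold (default -1 kBT; the adsorbed and desorbed basins
#' are separated by a wide gap, so the classification is insensitive to the
#' exact value).  A distance-based alternative classifier is available for
#' sensitivity checks.
#'
#' @param E_B Binding energies in kBT.
#' @param threshold Energy threshold in kBT (default -1).
#' @param min_dist Optional minimum bead-surface distances; used only with
#'   `method = "distance"`.
#' @param method `"energy"` (default) or `"distance"` (adsorbed iff
#'   min_dist < `dist_threshold`).
#' @param dist_threshold Distance threshold in Angstrom (default 10).
#' @return Logical vector.
#' @export
classify_adsorbed <- function(E_B, threshold = -1, min_dist = NULL,
                              method = c("energy", "distance"),
                              dist_threshold = 10) {
  method <- match.arg(method)
  if (method == "energy") E_B < threshold
  else {
    if (is.null(min_dist)) stop("distance classifier needs 'min_dist'")
    min_dist < dist_threshold
  }
}

#' Block statistics of a sample series
#'
#' Splits the series into `n_blocks` equal contiguous blocks (truncating a
#' remainder), and reports the block means, the grand mean and the standard
#' deviation of the block means — the standard error estimate for
#' correlated MC series.
#'
#' @param x Numeric series.
#' @param n_blocks Number of blocks (default 10).
#' @return List with `n_blocks`, `block_means`, `grand_mean`,
#'   `block_error` (sd of block means / sqrt(n_blocks)) and `block_sd`.
#' @export
block_stats <- function(x, n_blocks = 10) {
  n <- length(x)
  if (n < n_blocks) stop("fewer samples than blocks")
  L <- n %/% n_blocks
  xm <- matrix(x[seq_len(L * n_blocks)], nrow = L)
  bm <- colMeans(xm)
  list(n_blocks = n_blocks, block_means = bm, grand_mean = mean(bm),
       block_sd = sd(bm), block_error = sd(bm) / sqrt(n_blocks))
}

#' Adsorbed fraction with block error
#'
#' @param samples A `pe_samples` data.frame (or any data.frame with an
#'   `adsorbed` column), or a logical vector of flags.
#' @param n_blocks Number of blocks for the error estimate.
#' @return List with `fraction`, `block_error`, `n`.
#' @export
adsorbed_fraction <- function(samples, n_blocks = 10) {
  flags <- if (is.data.frame(samples)) samples$adsorbed else samples
  if (length(flags) == 0) stop("empty sample series")
  f <- as.numeric(flags)
  bs <- if (length(f) >= n_blocks) block_stats(f, n_blocks)
        else list(block_error = NA_real_)
  list(fraction = mean(f), block_error = bs$block_error, n = length(f))
}

#' Radial monomer density profile
#'
#' Bins bead radial distances from the particle center into spherical
#' shells and normalizes by shell volume and number of configurations,
#' giving a number density in 1/Angstrom^3.  Summing density x shell
#' volume over bins recovers the number of beads per configuration.
#'
#' @param snapshots List of N x 3 configuration matrices (e.g. the
#'   `snapshots` attribute of a [run_simulation()] result).
#' @param edges Increasing vector of radial bin edges in Angstrom.
#' @return Object of class `density_profile`: data.frame with `r_center`,
#'   `r_lo`, `r_hi`, `density` (1/A^3) and `counts` (mean beads per
#'   configuration in the shell).
#' @export
density_profile <- function(snapshots, edges) {
  stopifnot(is.list(snapshots), length(snapshots) > 0,
            length(edges) >= 2, all(diff(edges) > 0))
  nb <- length(edges) - 1
  counts <- numeric(nb)
  for (s in snapshots) {
    r <- sqrt(rowSums(.as_positions(s)^2))
    h <- findInterval(r, edges, rightmost.closed = TRUE)
    h <- h[h >= 1 & h <= nb]
    counts <- counts + tabulate(h, nbins = nb)
  }
  counts <- counts / length(snapshots)
  vol <- 4 / 3 * pi * diff(edges^3)
  structure(data.frame(r_center = (edges[-1] + edges[-(nb + 1)]) / 2,
                       r_lo = edges[-(nb + 1)], r_hi = edges[-1],
                       density = counts / vol, counts = counts),
            class = c("density_profile", "data.frame"))
}
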