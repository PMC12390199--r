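## Critical adsorption-desorption boundary analysis: sigmoid fits of the
## adsorbed fraction over a control-variable grid, automatic bracket
## expansion, and power-law boundary fits.

#' Fit the adsorbed fraction with a sigmoid
#'
#' Nonlinear least squares fit of
#' \deqn{f_{ads}(x) = \frac{1}{1 + e^{\alpha (x - x_{1/2})}}}
#' to observed adsorbed fractions.  The midpoint `x_half` is the critical
#' value of the control variable (f = 1/2 there by construction).  The
#' Pearson correlation between observed and fitted fractions is reported;
#' a warning is emitted when it falls below 0.9.
#'
#' @param x Control-variable grid (strictly increasing).
#' @param fractions Observed adsorbed fractions in \[0, 1\].
#' @param weights Optional fit weights (e.g. inverse variance).
#' @return Object of class `sigmoid_fit`: list with `alpha`, `x_half`,
#'   `pearson_r`, `residual_rms`, `fitted`.
#' @export
fit_sigmoid <- function(x, fractions, weights = NULL) {
  stopifnot(length(x) == length(fractions))
  if (length(x) < 4)
    stop("sigmoid fit requires at least 4 grid points")
  if (min(fractions) > 0.25 || max(fractions) < 0.75)
    stop(paste("insufficient span: fractions must reach below 0.25 and",
               "above 0.75; extend the control-variable grid"))
  ord <- order(x); x <- x[ord]; f <- fractions[ord]
  ## initial values: interpolated crossing of 1/2 and local slope
  cross <- which(diff(sign(f - 0.5)) != 0)
  x0 <- if (length(cross)) {
    i <- cross[1]
    x[i] + (0.5 - f[i]) * (x[i + 1] - x[i]) / (f[i + 1] - f[i])
  } else x[which.min(abs(f - 0.5))]
  slope <- (f[length(f)] - f[1]) / (x[length(x)] - x[1])
  a0 <- -4 * slope
  if (!is.finite(a0) || a0 == 0) a0 <- if (slope < 0) 1 else -1
  dat <- data.frame(x = x, f = f)
  w <- if (is.null(weights)) rep(1, length(x)) else weights[ord]
  try_fit <- function(a_start, x_start) tryCatch(
    minpack.lm::nlsLM(f ~ 1 / (1 + exp(alpha * (x - xhalf))),
                      data = dat, weights = w,
                      start = list(alpha = a_start, xhalf = x_start),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  ## a first-order-like transition can give a pure 0/1 step on the grid,
  ## for which the least-squares gradient is singular; try progressively
  ## steeper starts, then fall back to the interpolated crossing with the
  ## steepness set by the local grid spacing
  dx <- stats::median(diff(x))
  starts <- list(c(a0, x0), c(sign(a0) * 2 / dx, x0),
                 c(sign(a0) * 8 / dx, x0))
  fit <- NULL
  for (s in starts) {
    fit <- try_fit(s[1], s[2])
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    alpha_fb <- sign(a0) * 8 / dx
    cf <- c(alpha = alpha_fb, xhalf = x0)
    fhat <- 1 / (1 + exp(alpha_fb * (x - x0)))
  } else {
    cf <- coef(fit)
    fhat <- predict(fit)
  }
  r <- suppressWarnings(cor(f, fhat))
  if (!is.na(r) && r < 0.9)
    warning(sprintf("sigmoid fit correlation %.3f is below 0.9", r))
  structure(list(alpha = unname(cf["alpha"]), x_half = unname(cf["xhalf"]),
                 pearson_r = r,
                 residual_rms = sqrt(mean((f - fhat)^2)),
                 fitted = fhat, x = x, fractions = f),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("sigmoid fit: x_half = %.5g, alpha = %.4g, r = %.4f\n",
              x$x_half, x$alpha, x$pearson_r))
  invisible(x)
}

## shared scan driver: run f_ads(x) over a positive grid with geometric
## auto-bracketing.  `direction` states how the adsorbed fraction varies
## with the control variable: "increasing" (sigma_n scans) or "decreasing"
## (kappa scans in the opposite-charge-dominated regime).
.scan_fractions <- function(grid, run_point, direction = "increasing",
                            max_expand = 6, expand_factor = 1.5,
                            lower_limit = 1e-6, upper_limit = Inf) {
  xs <- sort(grid)
  stopifnot(all(xs > 0))
  fr <- vapply(xs, run_point, numeric(3))  # fraction, error, seed
  grow_hi <- function() {
    xn <- min(max(xs) * expand_factor, upper_limit)
    if (xn <= max(xs) * (1 + 1e-9))
      stop("bracket failure at the upper limit; fractions: ",
           paste(signif(fr[1, ], 3), collapse = ", "))
    xs <<- c(xs, xn); fr <<- cbind(fr, run_point(xn))
  }
  grow_lo <- function() {
    xn <- max(min(xs) / expand_factor, lower_limit)
    if (xn >= min(xs) * (1 - 1e-9))
      stop("bracket failure at the lower limit; fractions: ",
           paste(signif(fr[1, ], 3), collapse = ", "))
    xs <<- c(xn, xs); fr <<- cbind(run_point(xn), fr)
  }
  for (k in seq_len(max_expand)) {
    fmax <- max(fr[1, ]); fmin <- min(fr[1, ])
    if (fmax >= 0.75 && fmin <= 0.25) break
    if (fmax < 0.75) {
      if (direction == "increasing") grow_hi() else grow_lo()
    }
    if (min(fr[1, ]) > 0.25) {
      if (direction == "increasing") grow_lo() else grow_hi()
    }
    ord <- order(xs); xs <- xs[ord]; fr <- fr[, ord, drop = FALSE]
    if (k == max_expand && (max(fr[1, ]) < 0.75 || min(fr[1, ]) > 0.25))
      stop("bracket failure after ", max_expand, " expansions; fractions: ",
           paste(signif(fr[1, ], 3), collapse = ", "))
  }
  list(x = xs, fractions = fr[1, ], errors = fr[2, ], seeds = fr[3, ])
}

.bootstrap_xhalf <- function(x, fractions, n_eff, n_boot = 200, seed = 1) {
  .with_seed(seed, {
    vals <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      fb <- rbinom(length(x), n_eff, pmin(pmax(fractions, 0), 1)) / n_eff
      ft <- tryCatch(suppressWarnings(fit_sigmoid(x, fb)),
                     error = function(e) NULL)
      if (!is.null(ft)) vals[b] <- ft$x_half
    }
    sd(vals, na.rm = TRUE)
  })
}

#' Scan the negative-patch charge density for the critical value
#'
#' Runs one MC simulation per grid value of sigma_n (the template
#' particle's other parameters held fixed), measures the adsorbed fraction,
#' expands the grid geometrically until fractions below 0.25 and above
#' 0.75 are bracketed, and fits the sigmoid to locate the critical charge
#' density sigma_n,c where adsorbed and desorbed states are equally
#' populated.  Per-point seeds derive from the protocol seed by counter.
#'
#' @param solution A [solution_conditions()] object (fixes kappa).
#' @param particle Template [patchy_particle()]; its `sigma_n` is the
#'   control variable.
#' @param chain A [chain_parameters()] object.
#' @param protocol A [simulation_protocol()] object (per-point run length).
#' @param sigma_n_grid Initial grid of sigma_n values in C/m^2.
#' @param n_boot Bootstrap resamples for the critical-value uncertainty
#'   (0 to skip).
#' @return Object of class `scan_result` with fields `control`
#'   (`"sigma_n"`), `x`, `fractions`, `errors`, `fit`, `critical`,
#'   `critical_err`, `seeds`.
#' @export
critical_sigma_scan <- function(solution, particle, chain, protocol,
                                sigma_n_grid, n_boot = 200) {
  counter <- 0
  run_point <- function(sn) {
    counter <<- counter + 1
    seed_i <- protocol$seed + 1000L * counter
    part_i <- particle; part_i$sigma_n <- sn
    prot_i <- protocol; prot_i$seed <- seed_i
    s <- run_simulation(solution, part_i, chain, prot_i)
    af <- adsorbed_fraction(s)
    c(af$fraction, af$block_error, seed_i)
  }
  sc <- .scan_fractions(sigma_n_grid, run_point, lower_limit = 1e-4)
  fit <- fit_sigmoid(sc$x, sc$fractions)
  err <- if (n_boot > 0)
    .bootstrap_xhalf(sc$x, sc$fractions, protocol$n_samples, n_boot,
                     seed = protocol$seed) else NA_real_
  structure(list(control = "sigma_n", x = sc$x, fractions = sc$fractions,
                 errors = sc$errors, seeds = sc$seeds, fit = fit,
                 critical = fit$x_half, critical_err = err,
                 kappa_a = solution$kappa * particle$radius),
            class = "scan_result")
}

#' Scan the screening parameter kappa*a for the critical value
#'
#' As [critical_sigma_scan()], but the control variable is the
#' dimensionless screening kappa*a (adjusted through the salt
#' concentration) at fixed cap charge densities.  In the
#' opposite-charge-dominated regime the adsorbed fraction decreases with
#' kappa*a and the sigmoid midpoint is the critical screening kappa_c*a.
#'
#' @inheritParams critical_sigma_scan
#' @param kappa_a_grid Initial grid of kappa*a values.
#' @return A `scan_result` with `control = "kappa_a"`.
#' @export
critical_kappa_scan <- function(solution, particle, chain, protocol,
                                kappa_a_grid, n_boot = 200) {
  counter <- 0
  run_point <- function(ka) {
    counter <<- counter + 1
    seed_i <- protocol$seed + 1000L * counter
    sol_i <- solution_conditions(
      salt_for_kappa_a(ka, particle$radius, solution$temperature,
                       solution$eps_water),
      solution$temperature, solution$eps_water)
    prot_i <- protocol; prot_i$seed <- seed_i
    s <- run_simulation(sol_i, particle, chain, prot_i)
    af <- adsorbed_fraction(s)
    c(af$fraction, af$block_error, seed_i)
  }
  sc <- .scan_fractions(kappa_a_grid, run_point, direction = "decreasing",
                        lower_limit = 1e-3)
  fit <- fit_sigmoid(sc$x, sc$fractions)
  err <- if (n_boot > 0)
    .bootstrap_xhalf(sc$x, sc$fractions, protocol$n_samples, n_boot,
                     seed = protocol$seed) else NA_real_
  structure(list(control = "kappa_a", x = sc$x, fractions = sc$fractions,
                 errors = sc$errors, seeds = sc$seeds, fit = fit,
                 critical = fit$x_half, critical_err = err),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("critical scan over %s: %d points\n", x$control, length(x$x)))
  cat(sprintf("  critical value = %.5g", x$critical))
  if (is.finite(x$critical_err))
    cat(sprintf(" +/- %.2g (bootstrap)", x$critical_err))
  cat(sprintf("\n  fit correlation r = %.4f\n", x$fit$pearson_r))
  invisible(x)
}

#' Assemble a phase boundary and fit its power law
#'
#' Log-log linear regression of critical charge densities against kappa*a
#' over a chosen window, returning the scaling exponent of
#' sigma_c ~ kappa^alpha with its standard error.
#'
#' @param kappa_a Vector of kappa*a boundary abscissae.
#' @param sigma_c Vector of critical charge densities (same length).
#' @param window Optional c(lo, hi) window in kappa*a over which to fit.
#' @return List with `exponent`, `exponent_se`, `prefactor`, `n_points`,
#'   and the boundary `table` (data.frame kappa_a, sigma_c).
#' @export
boundary_assemble <- function(kappa_a, sigma_c, window = NULL) {
  stopifnot(length(kappa_a) == length(sigma_c))
  keep <- if (is.null(window)) rep(TRUE, length(kappa_a))
          else kappa_a >= window[1] & kappa_a <= window[2]
  if (sum(keep) < 3)
    stop("power-law fit requires at least 3 boundary points in the window")
  fit <- lm(log(sigma_c[keep]) ~ log(kappa_a[keep]))
  s <- summary(fit)$coefficients
  list(exponent = unname(coef(fit)[2]),
       exponent_se = unname(s[2, 2]),
       prefactor = exp(unname(coef(fit)[1])),
       n_points = sum(keep),
       table = data.frame(kappa_a = kappa_a, sigma_c = sigma_c))
}
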