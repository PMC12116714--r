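#' Default template coefficient vectors for the synthetic generators
#'
#' Fixed, documented coefficient vectors on the 8-function cubic B-spline
#' basis. `"two_peak"` yields a template whose SRVF alternates sign four
#' times, i.e. a function with two peaks separated by a valley; `"one_peak"`
#' yields a single interior peak.
#'
#' @param shape `"two_peak"` or `"one_peak"`.
#' @return Numeric vector of length 8.
#' @export
template_coefs <- function(shape = c("two_peak", "one_peak")) {
  shape <- match.arg(shape)
  switch(shape,
         # mirror-symmetric (c_b = -c_{B+1-b}): the two peaks are equal in
         # height and equidistant from the endpoints, and the one-peak bump
         # sits at the centre, so registering it to either peak costs the same
         two_peak = c(2.4, 2.8, -2.6, -3.0, 3.0, 2.6, -2.8, -2.4),
         one_peak = 0.55 * c(2.6, 2.9, 2.4, 1.31, -1.29, -2.4, -2.9, -2.6))
}

#' Configuration of the synthetic-data generators
#'
#' Defaults reproduce the simulation conditions used throughout the package's
#' validation: an 8-coefficient cubic B-spline template on a 100-point grid,
#' piecewise-linear phases with Dirichlet increments on a uniform partition
#' of size 5 with concentration 50 (uniform base), and Gaussian SRVF noise
#' with variance 0.03.
#'
#' @param n Number of functions.
#' @param M Grid size.
#' @param c_true True template coefficients (length defines the true basis
#'   size).
#' @param M_gamma_true True partition size of the piecewise-linear phases.
#' @param kappa_true Concentration of the phase-generating Dirichlet prior.
#' @param noise_var Variance of the SRVF-space white noise.
#' @param base Base measure of the phase-generating Dirichlet: `"uniform"`
#'   (default) draws `d_i ~ Dirichlet(kappa_true * u)` with `u` the uniform
#'   increments, giving moderate warps representable by the centered
#'   piecewise-linear family; `"hierarchical"` redraws `u` per function from
#'   the order-statistics construction, giving much wilder warps.
#' @param f0 Starting value `f_i(0)` of every function.
#' @param scale_range Amplitude-scaling range for the mixed generator.
#' @param seed Optional seed; generators are pure functions of
#'   `(config, seed)`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n = 100, M = 100, c_true = template_coefs("two_peak"),
                       M_gamma_true = 5, kappa_true = 50, noise_var = 0.03,
                       base = c("uniform", "hierarchical"), f0 = 0,
                       scale_range = c(0.7, 1.4), seed = NULL) {
  base <- match.arg(base)
  stopifnot(n >= 1, M >= 10, M_gamma_true >= 3, kappa_true > 0,
            noise_var >= 0)
  structure(list(n = n, M = M, c_true = c_true,
                 M_gamma_true = M_gamma_true, kappa_true = kappa_true,
                 noise_var = noise_var, base = base, f0 = f0,
                 scale_range = scale_range, seed = seed),
            class = "sim_config")
}

# internal: phase increments for the generators
sim_phases <- function(config, n) {
  K <- config$M_gamma_true - 1
  if (config$base == "hierarchical")
    return(matrix(sample_phase_prior(config$kappa_true, config$M_gamma_true,
                                     n = n)$d, nrow = K))
  D <- matrix(0, K, n)
  for (i in seq_len(n)) {
    g <- rgamma(K, shape = config$kappa_true / K, rate = 1)
    d <- g / sum(g)
    d <- pmax(d, 1e-4)
    D[, i] <- d / sum(d)
  }
  D
}

# internal: one noisy warped copy of a template SRVF; d are the increments of
# the function's phase gamma (the observation warps the template by its
# inverse)
sim_one <- function(qmu, d, noise_var, f0) {
  grid <- qmu$grid
  s <- seq(0, 1, length.out = length(d) + 1)
  q <- warp_srvf(qmu, warp_inverse(pl_warp(d, partition = s)))$values +
    rnorm(length(grid), 0, sqrt(noise_var))
  f <- from_srvf(f0, grid_function(grid, q, "q"))
  list(q = q, f = f$values)
}

#' Simulate warped noisy copies of a template
#'
#' Generates `n` functions by warping a B-spline template SRVF with phases
#' drawn from the hierarchical Dirichlet prior, adding Gaussian white noise in
#' SRVF space, and mapping back to the original space with `f_i(0) = f0`.
#' Returns both the data and the generating ground truth, which drives all
#' parameter-recovery checks.
#'
#' @param config A [sim_config()].
#' @param identity_phases Force all phases to the identity (degenerate
#'   checks).
#' @return List with `data` (wide tibble: `t`, `f1`, ..., `fn`) and `truth`
#'   (list with `c`, `D` (increments, one column per function), `sigma2`,
#'   `Q` (the noisy SRVFs actually generated) and `basis`).
#' @export
simulate_panel <- function(config = sim_config(), identity_phases = FALSE) {
  if (!is.null(config$seed)) set.seed(config$seed)
  grid <- seq(0, 1, length.out = config$M)
  basis <- basis_spec(length(config$c_true), grid)
  qmu <- template_srvf(config$c_true, basis)
  K <- config$M_gamma_true - 1
  D <- matrix(1 / K, K, config$n)
  if (!identity_phases) D <- sim_phases(config, config$n)
  Q <- matrix(0, config$M, config$n)
  F <- matrix(0, config$M, config$n)
  for (i in seq_len(config$n)) {
    x <- sim_one(qmu, D[, i], config$noise_var, config$f0)
    Q[, i] <- x$q
    F[, i] <- x$f
  }
  colnames(F) <- paste0("f", seq_len(config$n))
  list(data = matrix_to_wide(grid, F),
       truth = list(c = config$c_true, D = D, sigma2 = config$noise_var,
                    Q = Q, basis = basis))
}

#' Simulate a mixed panel: six two-peak functions and one one-peak function
#'
#' The first six functions are generated as in [simulate_panel()] from the
#' two-peak template, each then multiplied by an independent
#' `Uniform(scale_range)` amplitude scale; the seventh comes from a one-peak
#' template with the same noise model and no scaling. Registering the
#' one-peak function to a two-peak template admits two solutions (align to
#' either peak), which makes its phase posterior bimodal -- the stress case
#' for the sequential sampler.
#'
#' @param config A [sim_config()]; `n` is fixed at 7 by the design.
#' @param one_peak_coefs Coefficients of the seventh function's template.
#' @return As [simulate_panel()], with `truth$scales` and `truth$c7` added.
#' @export
simulate_mixed_panel <- function(config = sim_config(n = 7),
                                 one_peak_coefs = template_coefs("one_peak")) {
  if (!is.null(config$seed)) set.seed(config$seed)
  grid <- seq(0, 1, length.out = config$M)
  basis <- basis_spec(length(config$c_true), grid)
  qmu2 <- template_srvf(config$c_true, basis)
  qmu1 <- template_srvf(one_peak_coefs, basis)
  D <- sim_phases(config, 7)
  scales <- runif(6, config$scale_range[1], config$scale_range[2])
  Q <- matrix(0, config$M, 7)
  F <- matrix(0, config$M, 7)
  for (i in 1:6) {
    x <- sim_one(qmu2, D[, i], config$noise_var, config$f0)
    F[, i] <- scales[i] * x$f
    Q[, i] <- sqrt(scales[i]) * x$q
  }
  x <- sim_one(qmu1, D[, 7], config$noise_var, config$f0)
  F[, 7] <- x$f
  Q[, 7] <- x$q
  colnames(F) <- paste0("f", 1:7)
  list(data = matrix_to_wide(grid, F),
       truth = list(c = config$c_true, c7 = one_peak_coefs, D = D,
                    sigma2 = config$noise_var, Q = Q, scales = scales,
                    basis = basis))
}

# internal: indices of strict interior local maxima of a vector
interior_maxima <- function(y) {
  n <- length(y)
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1L
}
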