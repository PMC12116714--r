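#' Model hyperparameters
#'
#' Collects all fixed hyperparameters of the hierarchical registration model
#' and its samplers.
#'
#' @param B Number of template basis functions.
#' @param sigma_c Prior variance of the template coefficients: a scalar (used
#'   for all coefficients) or a length-`B` vector of diagonal entries.
#' @param kappa Dirichlet concentration of the phase prior.
#' @param kappa_ini Concentration of the initialization kernel used when a
#'   new phase component is created (large values keep the new phase close to
#'   the dynamic-programming alignment).
#' @param M_gamma Partition size for the piecewise-linear phase model
#'   (`M_gamma - 1` increments).
#' @param alpha_sigma,beta_sigma Shape and scale of the inverse-gamma prior
#'   on the SRVF error variance.
#' @param J Particle count.
#' @param n_mh Number of MH perturbation sweeps per assimilation (default 30).
#' @param resample_frac Resampling is triggered when ESS falls below
#'   `resample_frac * J` (default 1/2).
#' @param kappa_prop Concentration of the Dirichlet composition proposal for
#'   phase MH moves (default 5000). Larger values give smaller moves. Phase
#'   posteriors under a fine grid are extremely sharp, so local proposals are
#'   needed for workable acceptance (about 15-35 percent in the packaged
#'   simulations); reusing the diffuse prior concentration would give
#'   near-zero acceptance.
#' @param center_weight_update Update particle weights by the prior ratio
#'   after centering (can be disabled for speed; the ratio is near 1 when the
#'   particles are close to centered).
#' @param eps_d Lower clip for phase increments (keeps warps strictly
#'   increasing).
#' @param strict_paper_gibbs Use the residual sum of squares itself (rather
#'   than half of it) as the inverse-gamma scale update; the half convention
#'   is the conjugate default.
#' @param strict_paper_proposal_cov Use the uncentered weighted second moment
#'   scaled by `1/(J-1)` as the template proposal covariance instead of the
#'   centered weighted covariance.
#' @param jacobian_endpoint Include the endpoint factor in the
#'   initialization-kernel Jacobian product. Off by default: with it the
#'   kernel expression is not a normalized density.
#' @param resampler `"multinomial"` (default) or `"systematic"`.
#' @param n_anneal Reserved hook for tempering sub-steps between adjacent
#'   posteriors (default 0; no annealing).
#' @return An object of class `hyperparams`.
#' @export
hyperparams <- function(B = 8, sigma_c = 20, kappa = 5, kappa_ini = 100,
                        M_gamma = 5, alpha_sigma = 4, beta_sigma = 0.01,
                        J = 500, n_mh = 30, resample_frac = 0.5,
                        kappa_prop = 5000, center_weight_update = TRUE,
                        eps_d = 1e-4, strict_paper_gibbs = FALSE,
                        strict_paper_proposal_cov = FALSE,
                        jacobian_endpoint = FALSE,
                        resampler = c("multinomial", "systematic"),
                        n_anneal = 0) {
  resampler <- match.arg(resampler)
  if (length(sigma_c) == 1) sigma_c <- rep(sigma_c, B)
  stopifnot(B >= 1, all(sigma_c > 0), kappa > 0, kappa_ini > 0, M_gamma >= 3,
            alpha_sigma > 0, beta_sigma > 0, J >= 2, n_mh >= 0,
            resample_frac > 0, resample_frac <= 1, kappa_prop > 0, eps_d > 0)
  structure(list(B = B, sigma_c = sigma_c, kappa = kappa,
                 kappa_ini = kappa_ini, M_gamma = M_gamma,
                 alpha_sigma = alpha_sigma, beta_sigma = beta_sigma, J = J,
                 n_mh = n_mh, resample_frac = resample_frac,
                 kappa_prop = kappa_prop,
                 center_weight_update = center_weight_update, eps_d = eps_d,
                 strict_paper_gibbs = strict_paper_gibbs,
                 strict_paper_proposal_cov = strict_paper_proposal_cov,
                 jacobian_endpoint = jacobian_endpoint, resampler = resampler,
                 n_anneal = n_anneal),
            class = "hyperparams")
}

# internal: uniform base measure for the phase prior, E[u] on the simplex
uniform_base <- function(M_gamma) rep(1 / (M_gamma - 1), M_gamma - 1)

#' Log-likelihood of observed SRVFs under the registration model
#'
#' The observation model is Gaussian white noise on SRVF values: each observed
#' SRVF is the template warped by the inverse of its phase, plus N(0, sigma2)
#' noise at every grid point. This is the reference (pure R) implementation
#' built from the warp algebra; the samplers use an equivalent compiled path.
#'
#' @param q_obs List of `grid_function`s in SRVF space (or an `M x n` matrix).
#' @param coef Template coefficients.
#' @param d_list List (or `K x n` matrix) of phase increment vectors.
#' @param sigma2 Error variance (positive).
#' @param basis A [basis_spec()].
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(q_obs, coef, d_list, sigma2, basis) {
  if (sigma2 <= 0) stop("log_likelihood: sigma2 must be positive", call. = FALSE)
  if (is.matrix(q_obs))
    q_obs <- lapply(seq_len(ncol(q_obs)), function(i)
      grid_function(basis$grid, q_obs[, i], "q"))
  if (is.matrix(d_list))
    d_list <- lapply(seq_len(ncol(d_list)), function(i) d_list[, i])
  n <- length(q_obs)
  if (length(d_list) != n)
    stop("log_likelihood: need one phase per observed function", call. = FALSE)
  qmu <- template_srvf(coef, basis)
  M <- length(basis$grid)
  ll <- 0
  for (i in seq_len(n)) {
    d <- if (inherits(d_list[[i]], "pl_warp")) d_list[[i]] else pl_warp(d_list[[i]])
    w <- warp_srvf(qmu, warp_inverse(d))
    ss <- sum((q_obs[[i]]$values - w$values)^2)
    ll <- ll - (M / 2) * log(2 * pi * sigma2) - ss / (2 * sigma2)
  }
  ll
}

#' Log-density of the Gaussian template prior
#'
#' Mean-zero multivariate normal with diagonal covariance.
#'
#' @param coef Coefficient vector.
#' @param sigma_c Diagonal entries of the covariance (scalar recycled).
#' @return Scalar log-density.
#' @export
log_prior_template <- function(coef, sigma_c) {
  if (length(sigma_c) == 1) sigma_c <- rep(sigma_c, length(coef))
  if (any(sigma_c <= 0)) stop("log_prior_template: non-positive variance", call. = FALSE)
  sum(-0.5 * log(2 * pi * sigma_c) - 0.5 * coef^2 / sigma_c)
}

#' Log-density of the Dirichlet phase prior
#'
#' Increments `d` follow Dirichlet(kappa * u). Points on the simplex boundary
#' have log-density `-Inf`.
#'
#' @param d Increment vector on the open simplex.
#' @param kappa Concentration.
#' @param u Base measure on the simplex; defaults to uniform increments, the
#'   expectation of the hierarchical base draw, which centers the prior at
#'   the identity warp.
#' @return Scalar log-density.
#' @export
log_prior_phase <- function(d, kappa, u = uniform_base(length(d) + 1)) {
  if (any(d <= 0) || any(u <= 0)) return(-Inf)
  if (abs(sum(d) - 1) > 1e-8) stop("log_prior_phase: d must lie on the simplex", call. = FALSE)
  a <- kappa * u
  sum((a - 1) * log(d)) - sum(lgamma(a)) + lgamma(sum(a))
}

#' Sample from the hierarchical phase prior
#'
#' Draws the base measure `u` as the increments of the order statistics of
#' `M_gamma - 2` uniforms, then `d ~ Dirichlet(kappa * u)`.
#'
#' @param kappa Concentration.
#' @param M_gamma Partition size.
#' @param n Number of draws.
#' @param eps_d Lower clip keeping draws strictly inside the simplex.
#' @return For `n = 1`, a list with `d` and `u`; otherwise a list of two
#'   `(M_gamma - 1) x n` matrices `d` and `u`.
#' @export
sample_phase_prior <- function(kappa, M_gamma, n = 1, eps_d = 1e-4) {
  K <- M_gamma - 1
  draw1 <- function() {
    u <- diff(c(0, sort(runif(M_gamma - 2)), 1))
    u <- pmax(u, eps_d); u <- u / sum(u)
    g <- rgamma(K, shape = kappa * u, rate = 1)
    if (sum(g) <= 0) g <- rep(1, K)
    d <- g / sum(g)
    d <- pmax(d, eps_d); d <- d / sum(d)
    list(d = d, u = u)
  }
  if (n == 1) return(draw1())
  ds <- matrix(0, K, n); us <- matrix(0, K, n)
  for (i in seq_len(n)) {
    x <- draw1(); ds[, i] <- x$d; us[, i] <- x$u
  }
  list(d = ds, u = us)
}

#' Log-density of the inverse-gamma prior on the error variance
#'
#' Shape/scale parameterization with density proportional to
#' `x^-(alpha+1) exp(-beta/x)`.
#'
#' @param sigma2 Positive variance value.
#' @param alpha_sigma,beta_sigma Shape and scale.
#' @return Scalar log-density.
#' @export
log_prior_sigma2 <- function(sigma2, alpha_sigma, beta_sigma) {
  if (sigma2 <= 0 || alpha_sigma <= 0 || beta_sigma <= 0)
    stop("log_prior_sigma2: non-positive argument", call. = FALSE)
  alpha_sigma * log(beta_sigma) - lgamma(alpha_sigma) -
    (alpha_sigma + 1) * log(sigma2) - beta_sigma / sigma2
}
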