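#' Batch MCMC configuration
#'
#' @param n_iter Total iterations (default 50,000).
#' @param burn_in Burn-in iterations discarded (default 40,000).
#' @param n_keep Number of retained, equally weighted draws after thinning;
#'   defaults to the particle count `J` of the hyperparameters at fit time.
#' @param target_acc Target acceptance rate of the adaptive template proposal
#'   (Robbins-Monro scaling during burn-in only, frozen afterwards).
#' @param seed Optional RNG seed set at the start of [run_mcmc()].
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 50000, burn_in = 40000, n_keep = NULL,
                        target_acc = 0.234, seed = NULL) {
  stopifnot(n_iter >= 1, burn_in >= 0, burn_in < n_iter)
  structure(list(n_iter = n_iter, burn_in = burn_in, n_keep = n_keep,
                 target_acc = target_acc, seed = seed),
            class = "mcmc_config")
}

# ---------------------------------------------------------------------------
# single MH/Gibbs steps (reference R implementations, used directly by the
# tests and exposed for custom samplers; run_mcmc uses the compiled loop)

# internal: per-function residual sums of squares given template values
state_ss <- function(qmu_values, D, data, partition) {
  ss_functions_cpp(qmu_values, data$grid, partition, as.matrix(D), data$Q)
}

# internal: partition of a state
state_partition <- function(state) seq(0, 1, length.out = nrow(state$D) + 1)

#' One Metropolis-Hastings update of the template coefficients
#'
#' Symmetric Gaussian random-walk proposal; acceptance combines the Gaussian
#' SRVF likelihood and the mean-zero Gaussian prior on the coefficients.
#'
#' @param state List with elements `coef`, `D` (increments, one column per
#'   function) and `sigma2`.
#' @param data A [reg_data()] object.
#' @param basis A [basis_spec()].
#' @param hyper [hyperparams()].
#' @param chol_prop Lower-triangular Cholesky factor of the proposal
#'   covariance.
#' @param use_lik Set `FALSE` to target the prior alone (used by
#'   prior-recovery checks).
#' @return Updated state with an `accepted` flag.
#' @export
mh_step_template <- function(state, data, basis, hyper, chol_prop,
                             use_lik = TRUE) {
  s <- state_partition(state)
  cprop <- state$coef + as.numeric(chol_prop %*% rnorm(length(state$coef)))
  delta <- log_prior_template(cprop, hyper$sigma_c) -
    log_prior_template(state$coef, hyper$sigma_c)
  if (use_lik) {
    qmu0 <- as.numeric(basis$Phi %*% state$coef)
    qmu1 <- as.numeric(basis$Phi %*% cprop)
    delta <- delta -
      (sum(state_ss(qmu1, state$D, data, s)) -
         sum(state_ss(qmu0, state$D, data, s))) / (2 * state$sigma2)
  }
  state$accepted <- log(runif(1)) < delta
  if (state$accepted) state$coef <- cprop
  state
}

# internal: composition proposal for one phase-increment vector; mirrors the
# compiled kernel. Returns proposal and forward/reverse log proposal density.
phase_propose <- function(d, kappa_prop, eps_d) {
  K <- length(d)
  a <- rep(kappa_prop / K, K)
  g <- rgamma(K, shape = kappa_prop / K, rate = 1)
  if (sum(g) <= 0) g <- rep(1, K)
  dp <- g / sum(g); dp <- pmax(dp, eps_d); dp <- dp / sum(dp)
  s <- seq(0, 1, length.out = K + 1)
  V <- c(0, cumsum(d)); V[K + 1] <- 1
  P <- c(0, cumsum(dp)); P[K + 1] <- 1
  Vn <- approx(s, V, xout = P, ties = "ordered")$y
  Vn[1] <- 0; Vn[K + 1] <- 1
  dnew <- pmax(diff(Vn), eps_d); dnew <- dnew / sum(dnew)
  Vn <- c(0, cumsum(dnew)); Vn[K + 1] <- 1
  ldir <- function(x) sum((a - 1) * log(x)) - sum(lgamma(a)) + lgamma(sum(a))
  seg <- function(knots, x) pmin(pmax(findInterval(x, knots,
                                                   rightmost.closed = TRUE), 1), K)
  interior <- P[2:K]
  lfwd <- ldir(dp) - sum(log((d / diff(s))[seg(s, interior)]))
  Prev <- approx(Vn, s, xout = V, ties = "ordered")$y
  dprev <- diff(Prev)
  if (any(dprev <= 0)) return(NULL)
  lrev <- ldir(dprev) -
    sum(log((dnew / diff(s))[seg(s, Prev[2:K])]))
  list(d = dnew, log_fwd = lfwd, log_rev = lrev)
}

#' One Metropolis-Hastings update of a single phase component
#'
#' The proposal composes the current warp with the piecewise-linear
#' interpolation of a symmetric-Dirichlet draw and restricts the result to the
#' partition; the Hastings ratio includes the forward and reverse
#' composition-kernel densities with their change-of-variables Jacobians.
#'
#' @inheritParams mh_step_template
#' @param i Index of the function whose phase is updated.
#' @param kappa_prop Proposal concentration (large values give small moves).
#' @return Updated state with an `accepted` flag.
#' @export
mh_step_phase <- function(state, i, data, basis, hyper,
                          kappa_prop = hyper$kappa_prop, use_lik = TRUE) {
  s <- state_partition(state)
  d <- state$D[, i]
  prop <- phase_propose(d, kappa_prop, hyper$eps_d)
  state$accepted <- FALSE
  if (is.null(prop)) return(state)
  u <- uniform_base(length(d) + 1)
  delta <- log_prior_phase(prop$d, hyper$kappa, u) -
    log_prior_phase(d, hyper$kappa, u) + prop$log_rev - prop$log_fwd
  if (use_lik) {
    qmu <- as.numeric(basis$Phi %*% state$coef)
    ss0 <- ss_functions_cpp(qmu, data$grid, s, cbind(d), data$Q[, i, drop = FALSE])
    ss1 <- ss_functions_cpp(qmu, data$grid, s, cbind(prop$d),
                            data$Q[, i, drop = FALSE])
    delta <- delta - (ss1 - ss0) / (2 * state$sigma2)
  }
  state$accepted <- log(runif(1)) < delta
  if (state$accepted) state$D[, i] <- prop$d
  state
}

#' Gibbs update of the error variance
#'
#' The inverse-gamma prior is conjugate for the Gaussian SRVF likelihood: the
#' full conditional is inverse-gamma with shape `alpha_sigma + n M / 2` and
#' scale `beta_sigma + SS/2` where `SS` is the total residual sum of squares
#' (with `strict_paper_gibbs`, `beta_sigma + SS`).
#'
#' @inheritParams mh_step_template
#' @return Updated state.
#' @export
gibbs_sigma2 <- function(state, data, basis, hyper) {
  s <- state_partition(state)
  qmu <- as.numeric(basis$Phi %*% state$coef)
  ss <- sum(state_ss(qmu, state$D, data, s))
  n <- ncol(data$Q); M <- length(data$grid)
  shape <- hyper$alpha_sigma + n * M / 2
  rate <- hyper$beta_sigma + if (hyper$strict_paper_gibbs) ss else ss / 2
  state$sigma2 <- 1 / rgamma(1, shape = shape, rate = rate)
  state
}

#' Center a state for identifiability
#'
#' Computes the Karcher mean of the phases, applies its inverse to every
#' phase (re-projected onto the partition) and warps the template by the mean
#' (re-projected onto the basis span by least squares). The likelihood is
#' invariant to this simultaneous warp, and afterwards the Karcher mean of
#' the phases is the identity.
#'
#' @inheritParams mh_step_template
#' @return Centered state.
#' @export
center_state <- function(state, data, basis, hyper) {
  s <- state_partition(state)
  warps <- lapply(seq_len(ncol(state$D)), function(i)
    pl_warp(state$D[, i], partition = s))
  gbar <- karcher_mean_warps(warps, max_iter = 200, tol = 1e-12)
  gbar_inv <- warp_inverse(gbar)
  for (i in seq_len(ncol(state$D))) {
    comp <- warp_compose(warps[[i]], gbar_inv)
    state$D[, i] <- project_to_partition(comp, s, eps = hyper$eps_d)$increments
  }
  qmu <- template_srvf(state$coef, basis)
  qtilde <- warp_srvf(qmu, gbar_inv)
  state$coef <- as.numeric(basis$proj %*% qtilde$values)
  state
}

#' Batch MCMC sampler for the registration model
#'
#' Cycles an adaptive random-walk Metropolis update of the template
#' coefficients, composition-proposal MH updates of each phase (random scan),
#' a conjugate Gibbs update of the error variance and an identifiability
#' centering step. After burn-in the chain is thinned to `n_keep` equally
#' weighted draws, returned as a [particle_system] ready for sequential
#' updating, which is also how the sampler serves as the batch-learning
#' comparator.
#'
#' @param data Wide data frame (first column: grid) or [reg_data()] object.
#' @param hyper [hyperparams()].
#' @param config [mcmc_config()].
#' @return A [particle_system] with equally weighted particles and an
#'   `acceptance` attribute.
#' @export
run_mcmc <- function(data, hyper = hyperparams(), config = mcmc_config()) {
  data <- reg_data(data)
  if (!is.null(config$seed)) set.seed(config$seed)
  n_keep <- if (is.null(config$n_keep)) hyper$J else config$n_keep
  n_avail <- config$n_iter - config$burn_in
  if (n_avail < 1 || n_keep < 1)
    stop("run_mcmc: no iterations retained after burn-in", call. = FALSE)
  if (n_keep > n_avail)
    stop("run_mcmc: n_keep exceeds post-burn-in iterations", call. = FALSE)

  basis <- basis_spec(hyper$B, data$grid)
  K <- hyper$M_gamma - 1
  s <- seq(0, 1, length.out = hyper$M_gamma)
  n <- ncol(data$Q)
  op <- projection_operator(s)

  # initialization: project the mean observed SRVF onto the basis, align
  # each function to it by dynamic programming to start the phases, refine
  # the template from the aligned functions, then start sigma2 at the
  # residual level. Cuts the burn-in needed dramatically compared to a cold
  # identity-phase start.
  c0 <- as.numeric(basis$proj %*% rowMeans(data$Q))
  D0 <- matrix(1 / K, K, n)
  qmu0 <- grid_function(data$grid, as.numeric(basis$Phi %*% c0), "q")
  Qa <- data$Q
  for (i in seq_len(n)) {
    qi <- grid_function(data$grid, data$Q[, i], "q")
    gh <- dp_align(qmu0, qi)
    D0[, i] <- project_to_partition(gh, s, eps = hyper$eps_d)$increments
    Qa[, i] <- warp_srvf(qi, gh)$values
  }
  c0 <- as.numeric(basis$proj %*% rowMeans(Qa))
  ss0 <- sum(ss_functions_cpp(as.numeric(basis$Phi %*% c0), data$grid, s,
                              D0, data$Q))
  s20 <- max(ss0 / (n * length(data$grid)), 1e-6)

  keep_iters <- config$burn_in +
    unique(round(seq(1, n_avail, length.out = n_keep)))
  res <- mcmc_run_cpp(c0, D0, s20, data$Q, basis$Phi, data$grid, s,
                      hyper$sigma_c, hyper$kappa, uniform_base(hyper$M_gamma),
                      hyper$kappa_prop, hyper$alpha_sigma, hyper$beta_sigma,
                      config$n_iter, config$burn_in,
                      as.integer(keep_iters), hyper$eps_d,
                      TRUE, TRUE, !hyper$strict_paper_gibbs, TRUE,
                      basis$proj, op$Tmat, op$t0, op$dense,
                      config$target_acc, log(0.01))

  sys <- new_particle_system(C = res$C, D = res$D, sigma2 = res$sigma2,
                             log_w = rep(-log(nrow(res$C)), nrow(res$C)),
                             data = data, basis = basis, hyper = hyper,
                             partition = s)
  attr(sys, "acceptance") <- list(template = res$acc_template,
                                  phase = res$acc_phase)
  sys
}
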