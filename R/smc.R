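#' Weighted particle representation of the registration posterior
#'
#' A `particle_system` holds `J` weighted joint samples of the template
#' coefficients, all phase increments and the error variance, together with
#' the data assimilated so far, the basis and the hyperparameters. It is
#' produced by [run_mcmc()] (equal weights) and updated by [assimilate()]
#' one new function at a time.
#'
#' @name particle_system
#' @seealso [assimilate()], [tidy.particle_system()],
#'   [glance.particle_system()], [autoplot.particle_system()]
NULL

# internal constructor
new_particle_system <- function(C, D, sigma2, log_w, data, basis, hyper,
                                partition, ess_log = NULL) {
  J <- nrow(C)
  n <- ncol(data$Q)
  if (is.null(D)) D <- array(0, dim = c(hyper$M_gamma - 1, 0, J))
  stopifnot(dim(D)[3] == J, dim(D)[2] == n, length(sigma2) == J,
            length(log_w) == J)
  if (is.null(ess_log))
    ess_log <- tibble::tibble(n = integer(), stage = character(),
                              ess = numeric())
  structure(list(C = C, D = D, sigma2 = sigma2, log_w = log_w,
                 data = data, basis = basis, hyper = hyper,
                 partition = partition, ess_log = ess_log),
            class = "particle_system")
}

#' @export
print.particle_system <- function(x, ...) {
  cat(sprintf(paste0("<particle_system: J = %d particles, n = %d functions, ",
                     "B = %d, M_gamma = %d>\n"),
              nrow(x$C), dim(x$D)[2], ncol(x$C), length(x$partition)))
  cat(sprintf("  ESS = %.1f, weighted mean sigma2 = %.4g\n",
              ess(particle_weights(x)), sum(particle_weights(x) * x$sigma2)))
  invisible(x)
}

#' Normalized particle weights
#' @param system A [particle_system].
#' @return Numeric vector of weights summing to 1.
#' @export
particle_weights <- function(system) {
  w <- exp(system$log_w - logsumexp(system$log_w))
  w / sum(w)
}

#' Effective sample size of a weight vector
#'
#' `ESS = 1 / sum(w^2)` for normalized weights: `J` when all weights are
#' equal, 1 when one particle carries all mass. Used as the particle
#' degeneracy diagnostic that triggers resampling.
#'
#' @param w Normalized weights (must sum to 1 within 1e-8).
#' @return Scalar in `[1, J]`.
#' @export
ess <- function(w) {
  if (abs(sum(w) - 1) > 1e-8)
    stop("ess: weights must be normalized", call. = FALSE)
  1 / sum(w^2)
}

# ---------------------------------------------------------------------------
# Algorithm steps

#' Initialization kernel for a new phase component
#'
#' Draws the new phase increments for one particle: the new function is
#' aligned to the particle's template by dynamic programming, the alignment
#' is restricted to the partition, and is then composed with the
#' piecewise-linear interpolation of a concentrated symmetric-Dirichlet draw.
#' Returns the draw and the log sampling density (Dirichlet factor times the
#' change-of-variables Jacobian of the composition).
#'
#' @param coef Template coefficients of the particle.
#' @param q_new New function's SRVF (`grid_function`).
#' @param basis A [basis_spec()].
#' @param hyper [hyperparams()] (uses `kappa_ini`, `M_gamma`, `eps_d`,
#'   `jacobian_endpoint`).
#' @return List with `d` (increments), `log_kernel` (log density) and `ghat`
#'   (the projected alignment increments).
#' @export
sample_init_kernel <- function(coef, q_new, basis, hyper) {
  s <- seq(0, 1, length.out = hyper$M_gamma)
  qmu <- template_srvf(coef, basis)
  gh <- tryCatch(dp_align(qmu, q_new), error = function(e) {
    warning("sample_init_kernel: degenerate alignment, using identity")
    grid_warp(q_new$grid, q_new$grid)
  })
  ghat <- project_to_partition(gh, s, eps = hyper$eps_d)$increments
  draw <- init_phase_one_cpp(ghat, s, hyper$kappa_ini, hyper$eps_d,
                             hyper$jacobian_endpoint)
  list(d = draw$d, log_kernel = draw$log_kernel, ghat = ghat)
}

#' Augment a particle system with a new function
#'
#' Adds a phase component for the new function to every particle using the
#' initialization kernel and updates the importance weights by
#' `likelihood x prior / kernel`, the weight identity for state spaces of
#' increasing dimension. Weights are renormalized in log space.
#'
#' @param system A [particle_system].
#' @param f_new New function: a `grid_function` in the original space on the
#'   system's grid.
#' @param init_kernel Optional custom kernel `function(j, coef, qmu_values)`
#'   returning `list(d, log_kernel)`; used mainly for validation studies.
#' @return The augmented system (`n + 1` phases per particle).
#' @export
smc_augment <- function(system, f_new, init_kernel = NULL) {
  grid <- system$data$grid
  stopifnot(inherits(f_new, "grid_function"))
  if (length(f_new$grid) != length(grid) || max(abs(f_new$grid - grid)) > 1e-10)
    stop("smc_augment: new function is not on the system grid", call. = FALSE)
  if (f_new$space == "q") {
    q_new <- f_new
    f_new <- from_srvf(0, q_new)
  } else {
    q_new <- to_srvf(f_new)
  }
  J <- nrow(system$C)
  K <- length(system$partition) - 1
  s <- system$partition
  hyper <- system$hyper
  op <- projection_operator(s)

  Dnew <- matrix(0, K, J)
  logk <- numeric(J)
  Qmu <- system$basis$Phi %*% t(system$C)  # M x J templates
  if (is.null(init_kernel)) {
    Gh <- dp_align_many_cpp(Qmu, q_new$values, grid,
                            slope_steps(c(1/4, 1/3, 1/2, 2/3, 1, 3/2, 2, 3, 4)))
    # project all alignments onto the partition in one linear map
    idx <- pmin(findInterval(op$dense, grid), length(grid) - 1)
    wgt <- (op$dense - grid[idx]) / (grid[idx + 1] - grid[idx])
    Y <- Gh[idx, , drop = FALSE] * (1 - wgt) + Gh[idx + 1, , drop = FALSE] * wgt
    E <- op$Tmat %*% Y + op$t0
    E <- pmax(E, hyper$eps_d)
    E <- sweep(E, 2, colSums(E), "/")
    for (j in seq_len(J)) {
      draw <- init_phase_one_cpp(E[, j], s, hyper$kappa_ini, hyper$eps_d,
                                 hyper$jacobian_endpoint)
      Dnew[, j] <- draw$d
      logk[j] <- draw$log_kernel
    }
  } else {
    for (j in seq_len(J)) {
      draw <- init_kernel(j, system$C[j, ], Qmu[, j])
      Dnew[, j] <- draw$d
      logk[j] <- draw$log_kernel
    }
  }

  M <- length(grid)
  logh <- vapply(seq_len(J), function(j) {
    ss <- ss_functions_cpp(Qmu[, j], grid, s, Dnew[, j, drop = FALSE],
                           cbind(q_new$values))
    -(M / 2) * log(2 * pi * system$sigma2[j]) - ss / (2 * system$sigma2[j])
  }, numeric(1))
  u <- uniform_base(hyper$M_gamma)
  logp <- vapply(seq_len(J), function(j)
    log_prior_phase(Dnew[, j], hyper$kappa, u), numeric(1))

  log_w <- system$log_w + logh + logp - logk
  if (all(!is.finite(log_w)))
    stop("smc_augment: all weights degenerate after augmentation", call. = FALSE)
  log_w <- log_w - logsumexp(log_w)

  n_old <- dim(system$D)[2]
  D <- array(0, dim = c(K, n_old + 1, J))
  if (n_old > 0) D[, seq_len(n_old), ] <- system$D
  D[, n_old + 1, ] <- Dnew

  system$D <- D
  system$log_w <- log_w
  system$data$Q <- cbind(system$data$Q, q_new$values)
  system$data$F <- cbind(system$data$F, f_new$values)
  system$data$f0 <- c(system$data$f0, f_new$values[1])
  system$ess_log <- dplyr::bind_rows(
    system$ess_log,
    tibble::tibble(n = n_old + 1L, stage = "augment",
                   ess = ess(particle_weights(system))))
  system
}

#' Resample particles
#'
#' Draws `J` particle indices (multinomially by default, or by systematic
#' resampling) proportional to the weights, duplicates/drops particles
#' accordingly and resets all weights to `1/J`.
#'
#' @param system A [particle_system].
#' @param method Resampling scheme; defaults to the system's hyperparameter.
#' @return The resampled system.
#' @export
resample_particles <- function(system, method = system$hyper$resampler) {
  w <- particle_weights(system)
  J <- length(w)
  idx <- if (identical(method, "systematic")) {
    u <- (runif(1) + 0:(J - 1)) / J
    findInterval(u, cumsum(w)) + 1L
  } else {
    sample.int(J, J, replace = TRUE, prob = w)
  }
  system$C <- system$C[idx, , drop = FALSE]
  system$D <- system$D[, , idx, drop = FALSE]
  system$sigma2 <- system$sigma2[idx]
  system$log_w <- rep(-log(J), J)
  system
}

# internal: pooled template proposal covariance from the weighted particles
proposal_cov <- function(system) {
  w <- particle_weights(system)
  C <- system$C
  B <- ncol(C)
  if (system$hyper$strict_paper_proposal_cov) {
    # printed form: uncentered weighted second moment scaled by 1/(J-1)
    S <- crossprod(sqrt(w) * C) / (nrow(C) - 1)
  } else {
    mu <- colSums(C * w)
    Cc <- sweep(C, 2, mu)
    S <- crossprod(sqrt(w) * Cc)
  }
  S + diag(1e-8, B)
}

#' MH perturbation of all particles
#'
#' Applies `n_mh` Metropolis-Hastings sweeps to every particle independently:
#' one template move (Gaussian random walk with the pooled weighted covariance
#' of the current template particles) followed by one composition-proposal
#' move per phase. Each sweep targets the current posterior, so the weights
#' are unchanged (approximate backward-kernel argument for MCMC kernels).
#'
#' @param system A [particle_system].
#' @param n_mh Number of sweeps (defaults to the hyperparameter, 30).
#' @return The perturbed system; weights are untouched.
#' @export
mh_perturb <- function(system, n_mh = system$hyper$n_mh) {
  if (n_mh == 0) return(system)
  hyper <- system$hyper
  S <- proposal_cov(system)
  L <- t(chol(S))
  s <- system$partition
  u <- uniform_base(hyper$M_gamma)
  J <- nrow(system$C)
  K <- dim(system$D)[1]
  for (j in seq_len(J)) {
    res <- mh_sweeps_one_cpp(system$C[j, ], matrix(system$D[, , j], nrow = K),
                             system$sigma2[j], system$data$Q,
                             system$basis$Phi, system$data$grid, s,
                             hyper$sigma_c, hyper$kappa, u, hyper$kappa_prop,
                             L, n_mh, hyper$eps_d, TRUE)
    system$C[j, ] <- res$c
    system$D[, , j] <- res$D
  }
  system
}

#' Center all particles and update weights by the prior ratio
#'
#' Centers each particle as in [center_state()] (Karcher mean of its phases
#' to the identity). Because centering is a deterministic map under which the
#' likelihood and importance density are invariant, the weight update reduces
#' to the ratio of prior densities at the centered versus uncentered values;
#' it can be skipped via the `center_weight_update` hyperparameter.
#'
#' @param system A [particle_system].
#' @return The centered system with renormalized weights.
#' @export
center_particles <- function(system) {
  hyper <- system$hyper
  s <- system$partition
  op <- projection_operator(s)
  u <- uniform_base(hyper$M_gamma)
  J <- nrow(system$C)
  dlw <- numeric(J)
  K <- dim(system$D)[1]
  for (j in seq_len(J)) {
    c_old <- system$C[j, ]
    D_old <- matrix(system$D[, , j], nrow = K)
    res <- center_one_cpp(c_old, D_old, system$basis$Phi, system$basis$proj,
                          system$data$grid, s, op$Tmat, op$t0, op$dense,
                          hyper$eps_d)
    system$C[j, ] <- res$c
    system$D[, , j] <- res$D
    if (hyper$center_weight_update) {
      lp_new <- log_prior_template(res$c, hyper$sigma_c) +
        sum(vapply(seq_len(ncol(res$D)), function(i)
          log_prior_phase(res$D[, i], hyper$kappa, u), numeric(1)))
      lp_old <- log_prior_template(c_old, hyper$sigma_c) +
        sum(vapply(seq_len(ncol(res$D)), function(i)
          log_prior_phase(D_old[, i], hyper$kappa, u), numeric(1)))
      dlw[j] <- lp_new - lp_old
    }
  }
  if (hyper$center_weight_update) {
    log_w <- system$log_w + dlw
    system$log_w <- log_w - logsumexp(log_w)
  }
  system
}

#' Gibbs update of the error variance of every particle
#'
#' Redraws each particle's variance from its inverse-gamma full conditional
#' (shape `alpha_sigma + n M / 2`, scale `beta_sigma` plus half the particle's
#' total residual sum of squares). Weights are unchanged.
#'
#' @param system A [particle_system].
#' @return The updated system.
#' @export
gibbs_sigma2_particles <- function(system) {
  hyper <- system$hyper
  s <- system$partition
  n <- dim(system$D)[2]
  M <- length(system$data$grid)
  J <- nrow(system$C)
  shape <- hyper$alpha_sigma + n * M / 2
  for (j in seq_len(J)) {
    qmu <- as.numeric(system$basis$Phi %*% system$C[j, ])
    ss <- sum(ss_functions_cpp(qmu, system$data$grid, s,
                               matrix(system$D[, , j], nrow = dim(system$D)[1]),
                               system$data$Q))
    rate <- hyper$beta_sigma + if (hyper$strict_paper_gibbs) ss else ss / 2
    system$sigma2[j] <- 1 / rgamma(1, shape = shape, rate = rate)
  }
  system
}

#' Assimilate a new function into the posterior
#'
#' One full sequential update: augment every particle with a phase for the
#' new function and reweight; resample if the effective sample size falls
#' below `resample_frac * J`; rejuvenate with MH perturbation sweeps; center
#' for identifiability; and redraw the error variance from its full
#' conditional. The result approximates the posterior given all functions
#' seen so far plus the new one. ESS before and after resampling is appended
#' to the system's `ess_log`.
#'
#' @param system A [particle_system] (from [run_mcmc()] or previous calls).
#' @param f_new A `grid_function` on the system grid: in the original space
#'   (its SRVF is computed by differencing), or directly in SRVF space; a
#'   plain numeric vector is taken as original-space values.
#' @param center Apply the centering step (default `TRUE`).
#' @param update_sigma2 Apply the variance Gibbs step (default `TRUE`).
#' @return The updated [particle_system].
#' @examples
#' \donttest{
#' sim <- simulate_panel(sim_config(n = 12, seed = 1))
#' hy <- hyperparams(J = 50)
#' fit <- run_mcmc(sim$data[1:11], hy, mcmc_config(2000, 1000))
#' fit <- assimilate(fit, sim$data[[13]])
#' }
#' @export
assimilate <- function(system, f_new, center = TRUE, update_sigma2 = TRUE) {
  if (is.numeric(f_new))
    f_new <- grid_function(system$data$grid, f_new, "f")
  system <- smc_augment(system, f_new)
  J <- nrow(system$C)
  n_now <- dim(system$D)[2]
  if (ess(particle_weights(system)) < system$hyper$resample_frac * J) {
    system <- resample_particles(system)
    system$ess_log <- dplyr::bind_rows(
      system$ess_log,
      tibble::tibble(n = n_now, stage = "resample",
                     ess = ess(particle_weights(system))))
  }
  system <- mh_perturb(system)
  if (center) system <- center_particles(system)
  if (update_sigma2) system <- gibbs_sigma2_particles(system)
  system$ess_log <- dplyr::bind_rows(
    system$ess_log,
    tibble::tibble(n = n_now, stage = "final",
                   ess = ess(particle_weights(system))))
  system
}
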