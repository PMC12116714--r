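#' Weighted posterior mean of the template SRVF
#'
#' @param system A [particle_system].
#' @return A `grid_function` in SRVF space: the pointwise weighted average of
#'   the particle templates.
#' @export
weighted_mean_srvf <- function(system) {
  w <- particle_weights(system)
  qbar <- as.numeric(system$basis$Phi %*% (t(system$C) %*% w))
  grid_function(system$data$grid, qbar, "q")
}

#' Posterior eFR variance of the template
#'
#' Weighted average of the squared L2 (eFR) distance of each particle's
#' template from the posterior mean.
#'
#' @param system A [particle_system].
#' @param mean Optional precomputed mean (a `grid_function`).
#' @return Non-negative scalar.
#' @export
efr_variance <- function(system, mean = weighted_mean_srvf(system)) {
  w <- particle_weights(system)
  Qmu <- system$basis$Phi %*% t(system$C)
  dev <- sweep(Qmu, 1, mean$values)
  grid <- system$data$grid
  sum(w * vapply(seq_len(ncol(dev)), function(j) trapz(grid, dev[, j]^2),
                 numeric(1)))
}

#' Principal-component directions of template uncertainty
#'
#' Builds the pointwise covariance of the marginal template posterior in SRVF
#' space from the weighted, mean-centered template particles, takes its
#' singular value decomposition, and maps the mean plus/minus `alpha` standard
#' deviations along the `k`-th direction back to the original function space.
#' The start value at `t = 0` is anchored at the sample average of the
#' observed `f_i(0)`.
#'
#' @param system A [particle_system].
#' @param alpha Number of standard deviations (default 1).
#' @param k Component index.
#' @return List with `mean`, `plus` and `minus` (`grid_function`s in the
#'   original space), the singular `values` and the direction matrix `u`.
#' @export
template_pca <- function(system, alpha = 1, k = 1) {
  w <- particle_weights(system)
  Qmu <- system$basis$Phi %*% t(system$C)
  qbar <- as.numeric(Qmu %*% w)
  dev <- sweep(Qmu, 1, qbar)
  Sigma_q <- dev %*% (w * t(dev))
  Sigma_q <- (Sigma_q + t(Sigma_q)) / 2
  sv <- svd(Sigma_q)
  if (k > ncol(sv$u)) stop("template_pca: component index out of range", call. = FALSE)
  f0bar <- mean(system$data$f0)
  grid <- system$data$grid
  mk <- function(v) from_srvf(f0bar, grid_function(grid, v, "q"))
  step <- alpha * sqrt(sv$d[k]) * sv$u[, k]
  list(mean = mk(qbar), plus = mk(qbar + step), minus = mk(qbar - step),
       values = sv$d, u = sv$u)
}

#' Posterior summaries of the phase components
#'
#' Weighted mean increments per function (renormalized to the simplex),
#' pointwise posterior mean and variance of each warp across the grid, and a
#' tidy export of all weighted phase particles for spaghetti plots.
#'
#' @param system A [particle_system].
#' @param grid Evaluation grid for the pointwise summaries; defaults to the
#'   system grid.
#' @return List with `mean` (list of `pl_warp`), `summary` (tibble: `fun`,
#'   `t`, `mean`, `var`) and `samples` (tibble: `fun`, `particle`, `weight`,
#'   `t`, `gamma` at the partition knots).
#' @export
phase_summaries <- function(system, grid = system$data$grid) {
  w <- particle_weights(system)
  s <- system$partition
  K <- length(s) - 1
  n <- dim(system$D)[2]
  J <- dim(system$D)[3]
  mean_warps <- vector("list", n)
  summaries <- vector("list", n)
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    Di <- matrix(system$D[, i, ], nrow = K)
    dbar <- as.numeric(Di %*% w)
    dbar <- dbar / sum(dbar)
    mean_warps[[i]] <- pl_warp(dbar, partition = s)
    # gamma values at grid points for each particle: K+1 node values,
    # interpolated; vectorized across particles
    nodes <- apply(Di, 2, function(d) c(0, cumsum(d)))
    nodes[K + 1, ] <- 1
    G <- apply(nodes, 2, function(v) approx(s, v, xout = grid)$y)
    m <- as.numeric(G %*% w)
    v <- as.numeric((G - m)^2 %*% w)
    summaries[[i]] <- tibble::tibble(fun = i, t = grid, mean = m, var = v)
    samples[[i]] <- tibble::tibble(
      fun = i,
      particle = rep(seq_len(J), each = K + 1),
      weight = rep(w, each = K + 1),
      t = rep(s, J),
      gamma = as.numeric(nodes))
  }
  list(mean = mean_warps,
       summary = dplyr::bind_rows(summaries),
       samples = dplyr::bind_rows(samples))
}

#' Register functions by their posterior mean phases
#'
#' Applies each function's (mean) phase to its time axis: the registered
#' functions are `f_i o gamma_i`, resampled on the grid. Boundary values are
#' preserved.
#'
#' @param data Wide data frame or [reg_data()].
#' @param phases List of warps (e.g. `phase_summaries(fit)$mean`).
#' @return Wide tibble of registered functions.
#' @export
registered_functions <- function(data, phases) {
  data <- reg_data(data)
  n <- ncol(data$F)
  if (length(phases) != n)
    stop("registered_functions: need one phase per function", call. = FALSE)
  R <- vapply(seq_len(n), function(i) {
    gt <- warp_eval(phases[[i]], data$grid)
    approx(data$grid, data$F[, i], xout = pmin(pmax(gt, 0), 1))$y
  }, numeric(length(data$grid)))
  matrix_to_wide(data$grid, matrix(R, ncol = n),
                 names = data$names)
}

# internal: joint log-posterior of each particle (likelihood + priors with
# the uniform-base phase prior); used for the posterior-mode estimator
particle_log_posterior <- function(system) {
  hyper <- system$hyper
  s <- system$partition
  grid <- system$data$grid
  M <- length(grid)
  n <- dim(system$D)[2]
  K <- dim(system$D)[1]
  u <- uniform_base(hyper$M_gamma)
  vapply(seq_len(nrow(system$C)), function(j) {
    qmu <- as.numeric(system$basis$Phi %*% system$C[j, ])
    ss <- sum(ss_functions_cpp(qmu, grid, s,
                               matrix(system$D[, , j], nrow = K),
                               system$data$Q))
    ll <- -n * (M / 2) * log(2 * pi * system$sigma2[j]) -
      ss / (2 * system$sigma2[j])
    lp <- log_prior_template(system$C[j, ], hyper$sigma_c) +
      sum(vapply(seq_len(n), function(i)
        log_prior_phase(system$D[, i, j], hyper$kappa, u), numeric(1))) +
      log_prior_sigma2(system$sigma2[j], hyper$alpha_sigma, hyper$beta_sigma)
    ll + lp
  }, numeric(1))
}

#' Posterior point estimates of template coefficients and phases
#'
#' @param system A [particle_system].
#' @param estimator `"mean"` (weighted posterior mean) or `"mode"`. The mode
#'   is the particle with maximal estimated joint log-posterior
#'   (`mode_method = "map"`) or the per-coordinate argmax of a weighted kernel
#'   density estimate (`"kde"`).
#' @param mode_method See above.
#' @return List with `c` (length-B vector) and `D` (`K x n` matrix).
#' @export
posterior_estimate <- function(system, estimator = c("mean", "mode"),
                               mode_method = c("map", "kde")) {
  estimator <- match.arg(estimator)
  mode_method <- match.arg(mode_method)
  w <- particle_weights(system)
  K <- dim(system$D)[1]; n <- dim(system$D)[2]
  if (estimator == "mean") {
    cbar <- as.numeric(t(system$C) %*% w)
    Dbar <- matrix(0, K, n)
    for (i in seq_len(n)) {
      d <- as.numeric(matrix(system$D[, i, ], nrow = K) %*% w)
      Dbar[, i] <- d / sum(d)
    }
    return(list(c = cbar, D = Dbar))
  }
  if (mode_method == "map") {
    j <- which.max(particle_log_posterior(system))
    return(list(c = system$C[j, ], D = matrix(system$D[, , j], nrow = K)))
  }
  kde_mode <- function(x) {
    de <- stats::density(x, weights = w / sum(w), bw = "nrd0")
    de$x[which.max(de$y)]
  }
  cmode <- apply(system$C, 2, kde_mode)
  Dmode <- matrix(0, K, n)
  for (i in seq_len(n)) {
    d <- apply(matrix(system$D[, i, ], nrow = K), 1, kde_mode)
    d <- pmax(d, 1e-6)
    Dmode[, i] <- d / sum(d)
  }
  list(c = cmode, D = Dmode)
}

#' Mean squared errors of posterior estimates against ground truth
#'
#' For synthetic runs with known truth, computes the MSE (averaged over
#' coordinates) of the posterior mean and posterior mode of the template
#' coefficients and of the phase increments.
#'
#' @param system A [particle_system].
#' @param truth List with `c` and `D` as returned by the generators.
#' @param estimators Which estimators to evaluate.
#' @return Tibble with columns `parameter`, `estimator`, `mse`.
#' @export
evaluate_mse <- function(system, truth, estimators = c("mean", "mode")) {
  K <- dim(system$D)[1]
  if (length(truth$c) != ncol(system$C) || nrow(truth$D) != K ||
      ncol(truth$D) != dim(system$D)[2])
    stop("evaluate_mse: truth dimensions do not match the fit", call. = FALSE)
  rows <- lapply(estimators, function(est) {
    e <- posterior_estimate(system, est)
    tibble::tibble(
      parameter = c("template", "phase"),
      estimator = est,
      mse = c(mean((e$c - truth$c)^2), mean((e$D - truth$D)^2)))
  })
  dplyr::bind_rows(rows)
}

#' Split a bimodal phase posterior into its two modes
#'
#' Particles are clustered by whether the warp at the domain midpoint lies
#' above or below the identity, and a weighted mean warp is reported per
#' cluster, together with each cluster's probability mass.
#'
#' @param system A [particle_system].
#' @param i Function index.
#' @param t0 Split point (default 0.5).
#' @return Tibble with one row per cluster: `cluster`, `mass`, and the mean
#'   increments as a list column `increments`.
#' @export
phase_modes <- function(system, i, t0 = 0.5) {
  w <- particle_weights(system)
  K <- dim(system$D)[1]
  s <- system$partition
  Di <- matrix(system$D[, i, ], nrow = K)
  g0 <- apply(Di, 2, function(d) {
    v <- c(0, cumsum(d)); v[K + 1] <- 1
    approx(s, v, xout = t0)$y
  })
  cl <- ifelse(g0 >= t0, "above", "below")
  purrr::map_dfr(unique(cl), function(lab) {
    idx <- cl == lab
    d <- as.numeric(Di[, idx, drop = FALSE] %*% w[idx]) / sum(w[idx])
    tibble::tibble(cluster = lab, mass = sum(w[idx]),
                   increments = list(d / sum(d)))
  })
}
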