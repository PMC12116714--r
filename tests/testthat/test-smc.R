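# sequential Monte Carlo: ESS, initialization kernel, augmentation weights,
# resampling, perturbation, centering, variance update, full assimilation

test_that("effective sample size follows the reciprocal-sum formula", {
  expect_equal(ess(rep(1 / 8, 8)), 8)
  expect_equal(ess(c(1, 0, 0, 0)), 1)
  expect_equal(ess(c(0.5, 0.5, 0, 0)), 2)
  expect_error(ess(c(0.5, 0.2)), "normalized")
})

test_that("initialization kernel density reduces to a Dirichlet at identity alignment", {
  # when the DP alignment is the identity, the Jacobian product is 1 and the
  # kernel density equals the symmetric Dirichlet density of the perturbation
  s <- seq(0, 1, length.out = 5)
  ghat_id <- rep(0.25, 4)
  set.seed(1)
  for (rep in 1:5) {
    x <- rgamma(4, 30); d <- x / sum(x)
    expect_equal(init_phase_density_cpp(d, ghat_id, s, 100, FALSE),
                 log_prior_phase(d, 100, rep(0.25, 4)), tolerance = 1e-10)
  }
})

test_that("initialization kernel concentrates at the alignment as kappa_ini grows", {
  s <- seq(0, 1, length.out = 5)
  ghat <- c(0.4, 0.3, 0.2, 0.1)
  set.seed(2)
  draw <- init_phase_one_cpp(ghat, s, 1e8, 1e-6, FALSE)
  expect_lt(max(abs(draw$d - ghat)), 1e-3)
})

test_that("initialization kernel density integrates to 1 (and not with the endpoint factor)", {
  # M_gamma = 3: Monte-Carlo integral over the 1-simplex at 1e5 draws
  s <- c(0, 0.5, 1)
  ghat <- c(0.3, 0.7)
  set.seed(3)
  x <- runif(1e5)
  dens <- vapply(x, function(xi)
    exp(init_phase_density_cpp(c(xi, 1 - xi), ghat, s, 50, FALSE)), numeric(1))
  expect_lt(abs(mean(dens) - 1), 0.03)

  # with the endpoint factor included the expression is scaled by the inverse
  # slope of the last segment (here 0.5/0.7), hence does not normalize
  dens_ep <- vapply(x, function(xi)
    exp(init_phase_density_cpp(c(xi, 1 - xi), ghat, s, 50, TRUE)), numeric(1))
  expect_lt(abs(mean(dens_ep) - 0.5 / 0.7), 0.03)
})

test_that("initialization kernel density matches the drawn sample's density", {
  s <- seq(0, 1, length.out = 5)
  set.seed(4)
  for (rep in 1:5) {
    x <- rgamma(4, 20); ghat <- x / sum(x)
    draw <- init_phase_one_cpp(ghat, s, 100, 1e-8, FALSE)
    expect_equal(init_phase_density_cpp(draw$d, ghat, s, 100, FALSE),
                 draw$log_kernel, tolerance = 1e-8)
  }
})

test_that("augmentation weight update matches the importance identity", {
  # discrete oracle: a custom kernel that samples the exact conditional
  # posterior of the new phase on a lattice makes the weight increment equal
  # to each particle's marginal likelihood of the new function
  set.seed(5)
  grid <- unit_grid(50)
  b <- basis_spec(5, grid)
  J <- 6
  C <- matrix(rnorm(J * 5, sd = 1.2), J, 5)
  D0 <- array(0, dim = c(2, 0, J))
  sys <- toy_system(C, D0, sigma2 = rep(0.05, J), grid = grid,
                    hyper = hyperparams(B = 5, M_gamma = 3, J = J, kappa = 4))
  # target function: a warped version of the first particle's template
  qn <- warp_srvf(template_srvf(C[1, ], b), warp_inverse(pl_warp(c(0.6, 0.4))))

  lattice <- seq(0.025, 0.975, length.out = 21)
  width <- diff(lattice)[1]
  u <- c(0.5, 0.5)
  marg <- numeric(J)
  probs <- matrix(0, J, 21)
  for (j in seq_len(J)) {
    lp <- vapply(lattice, function(x) {
      d <- c(x, 1 - x)
      log_likelihood(cbind(qn$values), C[j, ], cbind(d), 0.05, b) +
        log_prior_phase(d, 4, u)
    }, numeric(1))
    probs[j, ] <- exp(lp - max(lp))
    marg[j] <- log(sum(probs[j, ] * width)) + max(lp)
    probs[j, ] <- probs[j, ] / sum(probs[j, ])
  }
  kernel <- function(j, coef, qmu) {
    k <- sample.int(21, 1, prob = probs[j, ])
    list(d = c(lattice[k], 1 - lattice[k]),
         log_kernel = log(probs[j, k] / width))
  }
  aug <- smc_augment(sys, qn, init_kernel = kernel)
  lw <- aug$log_w - sys$log_w  # increment, up to a common normalizing shift
  expect_lt(diff(range(lw - marg)), 1e-8)
})

test_that("augmentation keeps weights normalized and treats duplicates equally", {
  set.seed(6)
  grid <- unit_grid(60)
  C <- matrix(rep(rnorm(5), each = 4), 4, 5)  # identical particles
  sys <- toy_system(C, array(0, dim = c(3, 0, 4)), sigma2 = rep(0.1, 4),
                    grid = grid, hyper = hyperparams(B = 5, M_gamma = 4, J = 4))
  f_new <- from_srvf(0, smooth_srvf(60))
  # shared draw: a deterministic kernel mapping equal particles equally
  kernel <- function(j, coef, qmu) list(d = c(0.3, 0.4, 0.3), log_kernel = 0.7)
  aug <- smc_augment(sys, f_new, init_kernel = kernel)
  w <- particle_weights(aug)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_lt(diff(range(w)), 1e-14)
})

test_that("multinomial resampling matches its weights and resets them", {
  set.seed(7)
  C <- matrix(rnorm(20), 5, 4)
  D <- array(rep(0.25, 4 * 1 * 5), dim = c(4, 1, 5))
  sys <- toy_system(C, D, sigma2 = rep(0.1, 5),
                    log_w = log(c(0.4, 0.3, 0.2, 0.05, 0.05)))

  rs <- resample_particles(sys)
  expect_equal(particle_weights(rs), rep(0.2, 5))

  # a point-mass weight vector duplicates that particle J times
  sys1 <- sys; sys1$log_w <- log(c(1e-300, 1e-300, 1, 1e-300, 1e-300))
  sys1$log_w <- sys1$log_w - seqreg:::logsumexp(sys1$log_w)
  rs1 <- resample_particles(sys1)
  expect_true(all(apply(rs1$C, 1, function(r) all(r == sys$C[3, ]))))

  # empirical resampling frequencies match the weights within 3 SE
  w <- c(0.4, 0.3, 0.2, 0.05, 0.05)
  counts <- numeric(5)
  n_trials <- 400
  for (t in seq_len(n_trials)) {
    r <- resample_particles(sys)
    # count surviving copies of each original particle by matching rows
    for (k in 1:5)
      counts[k] <- counts[k] + sum(apply(r$C, 1, function(x)
        all(x == sys$C[k, ])))
  }
  phat <- counts / (5 * n_trials)
  se <- sqrt(w * (1 - w) / (5 * n_trials))
  expect_true(all(abs(phat - w) < 3.5 * se))
})

test_that("MH perturbation leaves weights untouched and restores diversity", {
  set.seed(8)
  grid <- unit_grid(60)
  b <- basis_spec(5, grid)
  cc <- c(1, 2, -2, -1, 1.5)
  J <- 100
  C <- matrix(rep(cc, each = J), J, 5)
  D <- array(rep(0.25, 4 * J), dim = c(4, 1, J))
  qn <- warp_srvf(template_srvf(cc, b), warp_inverse(warp_identity(4)))
  sys <- toy_system(C, D, sigma2 = rep(0.05, J), grid = grid,
                    hyper = hyperparams(B = 5, M_gamma = 5, J = J))
  sys$data$Q <- cbind(qn$values + rnorm(60, 0, 0.2))
  sys$log_w <- log(runif(J)); sys$log_w <- sys$log_w - seqreg:::logsumexp(sys$log_w)

  pert <- mh_perturb(sys, n_mh = 30)
  expect_identical(pert$log_w, sys$log_w)  # bitwise per the weight identity

  # duplicated particles separate with near certainty
  expect_gte(nrow(unique(round(pert$C, 12))), 0.99 * J)
})

test_that("perturbation does not degrade a tight single-function posterior", {
  # particles start at the posterior mode of a low-noise one-function fit;
  # MH sweeps targeting that posterior must keep the average log-posterior
  # within sampling fluctuation of its starting value
  set.seed(9)
  grid <- unit_grid(60)
  b <- basis_spec(5, grid)
  cc <- c(1, 2, -2, -1, 1.5)
  J <- 60
  C <- matrix(rep(cc, each = J), J, 5)
  D <- array(rep(0.25, 4 * J), dim = c(4, 1, J))
  sys <- toy_system(C, D, sigma2 = rep(0.02, J), grid = grid,
                    hyper = hyperparams(B = 5, M_gamma = 5, J = J,
                                        sigma_c = 20))
  sys$data$Q <- cbind(template_srvf(cc, b)$values + rnorm(60, 0, sqrt(0.02)))
  lp0 <- mean(seqreg:::particle_log_posterior(sys))
  pert <- mh_perturb(sys, n_mh = 30)
  lp1 <- mean(seqreg:::particle_log_posterior(pert))
  # stationarity: the average log-posterior settles near the typical set,
  # a bounded distance below the mode (about dim/2 in log units)
  expect_gt(lp1, lp0 - 15)
})

test_that("centering particles updates weights by the prior ratio", {
  set.seed(10)
  grid <- unit_grid(60)
  J <- 8
  C <- matrix(rnorm(J * 5), J, 5)
  # already centered: mirrored phases around the identity
  D <- array(0, dim = c(4, 2, J))
  for (j in seq_len(J)) {
    x <- rgamma(4, 500); d <- x / sum(x)
    D[, 1, j] <- d
    # reflect in the sqrt-slope representation to keep the mean near identity
    D[, 2, j] <- rev(d)
  }
  sys <- toy_system(C, D, sigma2 = rep(0.05, J), grid = grid,
                    hyper = hyperparams(B = 5, M_gamma = 5, J = J))
  sys$data$Q <- cbind(sys$data$Q[, 1], sys$data$Q[, 1])

  cen <- center_particles(sys)
  w0 <- particle_weights(sys); w1 <- particle_weights(cen)
  # mirrored pairs are nearly centered already: weights barely move
  expect_lt(max(abs(w1 - w0)), 0.02 * max(w0))
  # post-condition: every particle's phase mean is the identity
  for (j in seq_len(J)) {
    gb <- karcher_mean_warps(list(pl_warp(cen$D[, 1, j]),
                                  pl_warp(cen$D[, 2, j])))
    expect_lt(max(abs(warp_eval(gb, grid) - grid)), 1e-3)
  }
})

test_that("per-particle variance update has the conjugate moments", {
  set.seed(11)
  grid <- unit_grid(40)
  J <- 5000
  cc <- c(1, 2, -2, -1, 1.5)
  C <- matrix(rep(cc, each = J), J, 5)
  D <- array(rep(0.25, 4 * J), dim = c(4, 1, J))
  sys <- toy_system(C, D, sigma2 = rep(1, J), grid = grid,
                    hyper = hyperparams(B = 5, M_gamma = 5, J = J,
                                        alpha_sigma = 3, beta_sigma = 0.5))
  b <- basis_spec(5, grid)
  sys$data$Q <- cbind(template_srvf(cc, b)$values)  # zero residuals

  upd <- gibbs_sigma2_particles(sys)
  # zero residuals: sigma2 ~ IG(3 + 1*40/2, 0.5); identify both parameters
  # from the first two moments of the J iid draws
  a_post <- 3 + 20; b_post <- 0.5
  m_th <- b_post / (a_post - 1)
  v_th <- b_post^2 / ((a_post - 1)^2 * (a_post - 2))
  expect_lt(abs(mean(upd$sigma2) - m_th) / m_th, 0.05)
  expect_lt(abs(var(upd$sigma2) - v_th) / v_th, 0.2)
  expect_identical(upd$log_w, sys$log_w)
})

test_that("a two-particle system survives a full assimilation", {
  set.seed(12)
  sim <- simulate_panel(sim_config(n = 3, M = 60, seed = 31))
  hy <- hyperparams(J = 2, M_gamma = 5)
  fit <- fit_sequence(sim, n_init = 2, hyper = hy, n_iter = 400,
                      burn_in = 200)
  expect_equal(dim(fit$D)[2], 3)
  w <- particle_weights(fit)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(fit$sigma2 > 0))
  expect_true(all(abs(apply(fit$D, c(2, 3), sum) - 1) < 1e-8))
})

test_that("assimilating a twin function reproduces its twin's phase posterior", {
  set.seed(13)
  sim <- simulate_panel(sim_config(n = 8, M = 80, seed = 32))
  hy <- hyperparams(J = 150, M_gamma = 5)
  fit <- fit_sequence(sim, n_init = 8, hyper = hy, n_iter = 1500,
                      burn_in = 700)
  # twin of function 8
  fit2 <- assimilate(fit, grid_function(fit$data$grid, sim$truth$Q[, 8], "q"))
  est <- posterior_estimate(fit2, "mean")$D
  expect_lt(max(abs(est[, 9] - est[, 8])), 0.02)
})

test_that("one SMC step matches the exactly enumerated posterior on a lattice toy", {
  # M_gamma = 3, fixed template and variance: after assimilating the first
  # function, the weighted particles of its phase must match the enumerated
  # conditional posterior in total variation
  set.seed(14)
  grid <- unit_grid(50)
  b <- basis_spec(5, grid)
  cc <- c(1.2, 2.1, -1.8, -1.2, 1.6)
  J <- 5000
  C <- matrix(rep(cc, each = J), J, 5)
  sys <- toy_system(C, array(0, dim = c(2, 0, J)), sigma2 = rep(0.05, J),
                    grid = grid,
                    hyper = hyperparams(B = 5, M_gamma = 3, J = J, kappa = 4,
                                        kappa_prop = 400))
  qn <- warp_srvf(template_srvf(cc, b), warp_inverse(pl_warp(c(0.62, 0.38))))
  qn <- grid_function(grid, qn$values + rnorm(50, 0, sqrt(0.05)), "q")

  # exact posterior of d_1 on a fine lattice (sigma2 and template fixed)
  u <- c(0.5, 0.5)
  xs <- seq(0.0005, 0.9995, length.out = 1000)
  lp <- vapply(xs, function(x)
    log_likelihood(cbind(qn$values), cc, cbind(c(x, 1 - x)), 0.05, b) +
      log_prior_phase(c(x, 1 - x), 4, u), numeric(1))
  post <- exp(lp - max(lp)); post <- post / sum(post)

  # one assimilation without centering or variance update (both fixed in the
  # enumeration)
  fit <- assimilate(sys, qn, center = FALSE, update_sigma2 = FALSE)
  xpart <- fit$D[1, 1, ]
  w <- particle_weights(fit)
  # bin particles onto 21 cells and compare in total variation
  breaks <- seq(0, 1, length.out = 22)
  emp <- vapply(seq_len(21), function(k)
    sum(w[xpart > breaks[k] & xpart <= breaks[k + 1]]), numeric(1))
  theo <- vapply(seq_len(21), function(k)
    sum(post[xs > breaks[k] & xs <= breaks[k + 1]]), numeric(1))
  tv <- sum(abs(emp - theo)) / 2
  expect_lt(tv, 0.1)
})

test_that("assimilation logs ESS and keeps it within bounds", {
  set.seed(15)
  sim <- simulate_panel(sim_config(n = 5, M = 60, seed = 33))
  hy <- hyperparams(J = 50, M_gamma = 5)
  fit <- fit_sequence(sim, n_init = 3, hyper = hy, n_iter = 600,
                      burn_in = 300)
  el <- fit$ess_log
  expect_true(all(el$ess >= 1 - 1e-9 & el$ess <= 50 + 1e-9))
  expect_setequal(unique(el$n), c(4, 5))
  expect_true(all(c("augment", "final") %in% el$stage))
})
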