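# batch MCMC kernels: template MH, phase MH, Gibbs variance, centering

make_fixture <- function(n = 3, M = 60, seed = 20) {
  set.seed(seed)
  g <- unit_grid(M)
  b <- basis_spec(6, g)
  cc <- c(1.5, 2, -2, -1.5, 1.8, -1)
  qmu <- template_srvf(cc, b)
  D <- sapply(seq_len(n), function(i) { x <- rgamma(4, 40); x / sum(x) })
  Q <- sapply(seq_len(n), function(i)
    warp_srvf(qmu, warp_inverse(pl_warp(D[, i])))$values +
      rnorm(M, 0, sqrt(0.03)))
  F <- apply(Q, 2, function(q) from_srvf(0, grid_function(g, q, "q"))$values)
  colnames(F) <- paste0("f", seq_len(n))
  list(data = reg_data(seqreg:::matrix_to_wide(g, F), srvf = Q),
       basis = b, c_true = cc, D_true = D,
       hyper = hyperparams(B = 6, M_gamma = 5, J = 10))
}

test_that("template MH accepts everything as the proposal scale vanishes", {
  fx <- make_fixture()
  st <- list(coef = fx$c_true, D = fx$D_true, sigma2 = 0.03)
  set.seed(1)
  acc <- replicate(50, mh_step_template(st, fx$data, fx$basis, fx$hyper,
                                        chol_prop = diag(1e-10, 6))$accepted)
  expect_true(all(acc))
})

test_that("template MH acceptance ratio is antisymmetric (detailed balance)", {
  fx <- make_fixture()
  log_target <- function(cc)
    log_likelihood(fx$data$Q, cc, fx$D_true, 0.03, fx$basis) +
    log_prior_template(cc, fx$hyper$sigma_c)
  set.seed(2)
  c1 <- fx$c_true
  c2 <- c1 + rnorm(6, 0, 0.1)
  expect_equal(log_target(c2) - log_target(c1),
               -(log_target(c1) - log_target(c2)), tolerance = 1e-10)
})

test_that("with the likelihood off, the template chain recovers its prior", {
  fx <- make_fixture()
  s <- seq(0, 1, length.out = 5)
  op <- seqreg:::projection_operator(s)
  keep <- as.integer(seq(5001, 25000, by = 1))
  sigma_c <- c(1, 2, 0.5, 1.5, 1, 0.8)
  set.seed(3)
  r <- mcmc_run_cpp(rep(0, 6), matrix(0.25, 4, 3), 0.1, fx$data$Q,
                    fx$basis$Phi, fx$data$grid, s, sigma_c, 5, rep(0.25, 4),
                    50, 4, 0.01, 25000L, 5000L, keep, 1e-4,
                    FALSE, FALSE, TRUE, TRUE, fx$basis$proj, op$Tmat, op$t0,
                    op$dense, 0.234, log(0.01))
  v <- apply(r$C, 2, var)
  expect_lt(max(abs(v / sigma_c - 1)), 0.15)
  expect_lt(max(abs(colMeans(r$C))), 0.15)
})

test_that("with the likelihood off, the phase chain recovers its prior mean", {
  fx <- make_fixture()
  s <- seq(0, 1, length.out = 5)
  op <- seqreg:::projection_operator(s)
  keep <- as.integer(seq(2001, 22000, by = 1))
  set.seed(4)
  r <- mcmc_run_cpp(rep(0, 6), matrix(0.25, 4, 3), 0.1, fx$data$Q,
                    fx$basis$Phi, fx$data$grid, s, fx$hyper$sigma_c, 5,
                    rep(0.25, 4), 30, 4, 0.01, 22000L, 2000L, keep, 1e-4,
                    FALSE, FALSE, TRUE, TRUE, fx$basis$proj, op$Tmat, op$t0,
                    op$dense, 0.234, log(0.01))
  Dm <- apply(r$D, c(1, 2), mean)
  expect_lt(max(abs(Dm - 0.25)), 0.02)
})

test_that("phase proposal density matches the exact two-segment closed form", {
  # M_gamma = 3: the proposal is a Beta draw pushed through the warp; its
  # density has two branches with slope Jacobians 2x and 2(1 - x)
  a <- 100
  x <- 0.7
  branch_density <- function(base, target) {
    if (target <= base) log(dbeta(target / (2 * base), a, a) / (2 * base))
    else log(dbeta(0.5 + (target - base) / (2 * (1 - base)), a, a) /
               (2 * (1 - base)))
  }
  set.seed(5)
  for (rep in 1:10) {
    pr <- seqreg:::phase_propose(c(x, 1 - x), kappa_prop = 2 * a,
                                 eps_d = 1e-10)
    expect_equal(pr$log_fwd, branch_density(x, pr$d[1]), tolerance = 1e-6)
    expect_equal(pr$log_rev, branch_density(pr$d[1], x), tolerance = 1e-6)
  }
})

test_that("phase MH leaves a Dirichlet target invariant", {
  # run the kernel with likelihood off against a skewed Dirichlet prior and
  # compare the chain's quantiles with the exact Beta marginals
  set.seed(6)
  alpha <- c(2.5, 1.5)
  d <- c(0.5, 0.5)
  keep <- numeric(3e4)
  for (t in seq_along(keep)) {
    pr <- seqreg:::phase_propose(d, kappa_prop = 20, eps_d = 1e-8)
    if (!is.null(pr)) {
      delta <- sum((alpha - 1) * log(pr$d / d)) + pr$log_rev - pr$log_fwd
      if (log(runif(1)) < delta) d <- pr$d
    }
    keep[t] <- d[1]
  }
  keep <- keep[5001:3e4]
  expect_lt(abs(mean(keep) - 2.5 / 4), 0.015)
  expect_lt(abs(var(keep) - 2.5 * 1.5 / (16 * 5)), 0.006)
  qq <- quantile(keep, c(0.25, 0.5, 0.75))
  expect_lt(max(abs(qq - qbeta(c(0.25, 0.5, 0.75), 2.5, 1.5))), 0.02)
})

test_that("Gibbs variance update follows the conjugate closed form", {
  fx <- make_fixture(n = 1, M = 60)
  # force exact zero residuals: data equals the warped template
  Q0 <- cbind(warp_srvf(template_srvf(fx$c_true, fx$basis),
                        warp_inverse(pl_warp(fx$D_true[, 1])))$values)
  dat0 <- fx$data; dat0$Q <- Q0
  hy <- hyperparams(B = 6, M_gamma = 5, alpha_sigma = 2, beta_sigma = 1)
  st <- list(coef = fx$c_true, D = fx$D_true[, 1, drop = FALSE], sigma2 = 1)
  set.seed(7)
  draws <- replicate(2e4, gibbs_sigma2(st, dat0, fx$basis, hy)$sigma2)
  # SS = 0: posterior is IG(2 + 30, 1); check both moments
  a_post <- 2 + 30; b_post <- 1
  expect_lt(abs(mean(draws) - b_post / (a_post - 1)) / (b_post / (a_post - 1)),
            0.02)
  expect_lt(abs(var(draws) / (b_post^2 / ((a_post - 1)^2 * (a_post - 2))) - 1),
            0.1)

  # hand-computed residuals: SS = 2 with alpha = 2, beta = 1 gives IG(a + M/2, 2)
  dat1 <- dat0
  dat1$Q <- Q0 + c(1, 1, rep(0, 58))
  draws1 <- replicate(2e4, gibbs_sigma2(st, dat1, fx$basis, hy)$sigma2)
  expect_lt(abs(mean(draws1) - 2 / (a_post - 1)) / (2 / (a_post - 1)), 0.02)

  # strict printed form uses SS instead of SS/2
  hy2 <- hyperparams(B = 6, M_gamma = 5, alpha_sigma = 2, beta_sigma = 1,
                     strict_paper_gibbs = TRUE)
  draws2 <- replicate(2e4, gibbs_sigma2(st, dat1, fx$basis, hy2)$sigma2)
  expect_lt(abs(mean(draws2) - 3 / (a_post - 1)) / (3 / (a_post - 1)), 0.02)
})

test_that("centering fixes the phase mean at the identity and preserves the fit", {
  # data-consistent states: likelihood invariance of centering holds to
  # second order in the distance of the phase mean from the identity (the
  # partition and basis projections are exact only at the identity)
  set.seed(8)
  g <- unit_grid(80)
  b <- basis_spec(6, g)
  cc <- c(1.5, 2, -2, -1.5, 1.8, -1)
  qmu <- template_srvf(cc, b)
  hy <- hyperparams(B = 6, M_gamma = 5)
  dll <- c()
  for (conc in c(2e3, 2e8)) {
    D <- sapply(1:4, function(i) { x <- rgamma(4, conc); x / sum(x) })
    Q <- sapply(1:4, function(i)
      warp_srvf(qmu, warp_inverse(pl_warp(D[, i])))$values +
        rnorm(80, 0, sqrt(0.03)))
    F <- apply(Q, 2, function(q) from_srvf(0, grid_function(g, q, "q"))$values)
    colnames(F) <- paste0("f", 1:4)
    dat <- reg_data(seqreg:::matrix_to_wide(g, F), srvf = Q)
    st <- list(coef = cc, D = D, sigma2 = 0.03)
    ll0 <- log_likelihood(Q, cc, D, 0.03, b)
    st2 <- center_state(st, dat, b, hy)

    gb <- karcher_mean_warps(lapply(1:4, function(i) pl_warp(st2$D[, i])))
    expect_lt(max(abs(warp_eval(gb, g) - g)), 1e-3)

    ll1 <- log_likelihood(Q, st2$coef, st2$D, st2$sigma2, b)
    dll <- c(dll, abs(ll1 - ll0))
  }
  expect_lt(dll[2], 1e-3)   # nearly centered: invariance to 1e-3 log units
  expect_gt(dll[1], dll[2]) # error shrinks as states approach centering
  expect_lt(dll[1], 1)      # and is already small for moderate warps

  # fixed point: an already-centered state is (nearly) unchanged
  fx <- make_fixture(n = 4, M = 80)
  D <- sapply(1:4, function(i) { x <- rgamma(4, 2e3); x / sum(x) })
  st2 <- center_state(list(coef = fx$c_true, D = D, sigma2 = 0.03),
                      fx$data, fx$basis, fx$hyper)
  st3 <- center_state(st2, fx$data, fx$basis, fx$hyper)
  expect_lt(max(abs(st3$coef - st2$coef)), 1e-4)
  expect_lt(max(abs(st3$D - st2$D)), 1e-4)
  st <- st2  # reuse below for the compiled-path comparison

  # compiled centering agrees with the R path
  s <- seq(0, 1, length.out = 5)
  op <- seqreg:::projection_operator(s)
  cpp <- center_one_cpp(st$coef, st$D, fx$basis$Phi, fx$basis$proj,
                        fx$data$grid, s, op$Tmat, op$t0, op$dense, 1e-4)
  expect_equal(cpp$c, st3$coef, tolerance = 1e-8)
  expect_equal(unname(cpp$D), unname(st3$D), tolerance = 1e-8)
})

test_that("run_mcmc validates its configuration and is deterministic", {
  fx <- make_fixture(n = 2, M = 50)
  dat <- seqreg:::matrix_to_wide(fx$data$grid, fx$data$F)
  expect_error(mcmc_config(n_iter = 100, burn_in = 100))
  expect_error(run_mcmc(dat, fx$hyper,
                        mcmc_config(n_iter = 20, burn_in = 10, n_keep = 50)),
               "n_keep")

  hy <- hyperparams(B = 6, M_gamma = 5, J = 20)
  f1 <- run_mcmc(dat, hy, mcmc_config(n_iter = 300, burn_in = 100, seed = 42))
  f2 <- run_mcmc(dat, hy, mcmc_config(n_iter = 300, burn_in = 100, seed = 42))
  expect_identical(f1$C, f2$C)
  expect_identical(f1$D, f2$D)
  expect_identical(f1$sigma2, f2$sigma2)
})

test_that("run_mcmc recovers the phase of a single unwarped function", {
  set.seed(9)
  g <- unit_grid(80)
  b <- basis_spec(6, g)
  cc <- c(1.5, 2, -2, -1.5, 1.8, -1)
  q1 <- template_srvf(cc, b)$values + rnorm(80, 0, 0.05)
  F <- cbind(f1 = from_srvf(0, grid_function(g, q1, "q"))$values)
  dat <- reg_data(seqreg:::matrix_to_wide(g, F), srvf = cbind(q1))
  hy <- hyperparams(B = 6, M_gamma = 5, J = 100)
  fit <- run_mcmc(dat, hy, mcmc_config(n_iter = 2000, burn_in = 1000))
  dbar <- posterior_estimate(fit, "mean")$D[, 1]
  expect_lt(max(abs(dbar - 0.25)), 0.05)
})
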