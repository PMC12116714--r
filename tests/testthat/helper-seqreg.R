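# shared fixtures: everything is generated in code at test time

unit_grid <- function(M = 101) seq(0, 1, length.out = M)

# a smooth non-trivial SRVF on a grid
smooth_srvf <- function(M = 101, freq = 2) {
  g <- unit_grid(M)
  grid_function(g, sin(freq * pi * g) + 0.5 * cos(pi * g), "q")
}

# small particle system built directly from arrays (uses the internal
# constructor; data Q is arbitrary but consistent)
toy_system <- function(C, D, sigma2, log_w = NULL, grid = unit_grid(50),
                       hyper = hyperparams(B = ncol(C), M_gamma = dim(D)[1] + 1,
                                           J = max(2, nrow(C)))) {
  J <- nrow(C)
  n <- dim(D)[2]
  basis <- basis_spec(ncol(C), grid)
  Q <- matrix(0, length(grid), n)
  F <- matrix(0, length(grid), n)
  for (i in seq_len(n)) {
    Q[, i] <- as.numeric(basis$Phi %*% C[1, ])
    F[, i] <- from_srvf(0, grid_function(grid, Q[, i], "q"))$values
  }
  data <- structure(list(grid = grid, F = F, Q = Q, f0 = rep(0, n),
                         names = paste0("f", seq_len(n))),
                    class = "reg_data")
  if (is.null(log_w)) log_w <- rep(-log(J), J)
  seqreg:::new_particle_system(
    C = C, D = D, sigma2 = sigma2, log_w = log_w, data = data, basis = basis,
    hyper = hyper, partition = seq(0, 1, length.out = dim(D)[1] + 1))
}

# fit a small system to simulated data: MCMC init on the first n_init
# functions, SMC assimilation of the rest (SRVFs fed directly, as the
# observation model is on SRVF values)
fit_sequence <- function(sim, n_init, hyper, n_iter = 2000, burn_in = 1000,
                         ...) {
  n_tot <- ncol(sim$truth$Q)
  dat <- reg_data(sim$data[, seq_len(n_init + 1)],
                  srvf = sim$truth$Q[, seq_len(n_init), drop = FALSE])
  fit <- run_mcmc(dat, hyper, mcmc_config(n_iter = n_iter, burn_in = burn_in))
  if (n_tot > n_init) {
    for (i in (n_init + 1):n_tot)
      fit <- assimilate(fit, grid_function(fit$data$grid, sim$truth$Q[, i], "q"),
                        ...)
  }
  fit
}
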