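# seqreg: sequential Bayesian registration of functional data

Functional data — annual climate trajectories, ECG beat complexes, growth
curves — mix two kinds of variability: *amplitude* (how large the features
are) and *phase* (when they occur). Registration separates them by warping
each curve's time axis toward a common template. `seqreg` is for analysts
whose curves arrive **sequentially**: it maintains a weighted-particle
approximation of the joint Bayesian posterior over the template, every
curve's warp, and the noise level, and updates it curve by curve instead of
refitting the whole model.

## The model and algorithm

On the square-root-velocity scale, `q = sign(f') sqrt(|f'|)`, the elastic
(extended Fisher–Rao) distance between curves is the ordinary L2 distance
and is invariant to simultaneous warping. The hierarchical model is

- observation: `q_i([t]) | q_mu, gamma_i, sigma2 ~ N((q_mu, gamma_i^{-1})([t]), sigma2 I_M)`,
- template: `q_mu = sum_b c_b phi_b`, cubic B-splines, `c ~ N(0, Sigma_c)`,
- phase: piecewise-linear warps with Dirichlet increments
  `d_i ~ Dir(kappa u)` on a fixed partition (a point in the open simplex),
- noise: `sigma2 ~ Inverse-Gamma(alpha_sigma, beta_sigma)` (conjugate).

Inference combines a batch Gibbs/adaptive-Metropolis sampler
(`run_mcmc()`) with a sequential Monte Carlo resample–move update
(`assimilate()`): each new curve is aligned to every particle's template by
dynamic programming to initialize its new phase component, importance
weights are updated by the likelihood × prior / kernel identity, particles
are resampled when the effective sample size falls below J/2, rejuvenated
by 30 Metropolis–Hastings sweeps, re-centered for identifiability (mean
warp to the identity), and the variance is refreshed by its conjugate full
conditional.

## Worked example

```r
library(seqreg)

# 40 noisy, randomly warped copies of a two-peak template
sim <- simulate_panel(sim_config(n = 40, seed = 21))

# batch initialization on the first 20 curves
# (the generated SRVFs are passed directly: the observation model lives on
#  SRVF values; use plain wide data frames for real, smooth recordings)
set.seed(99)
fit <- run_mcmc(reg_data(sim$data[, 1:21], srvf = sim$truth$Q[, 1:20]),
                hyperparams(J = 500),
                mcmc_config(n_iter = 3000, burn_in = 1500))

# assimilate the remaining curves one at a time
for (i in 21:40)
  fit <- assimilate(fit, grid_function(fit$data$grid, sim$truth$Q[, i], "q"))

glance(fit)
#> # A tibble: 1 × 5
#>       J n_functions   ess sigma2_mean template_efr_var
#>   <int>       <int> <dbl>       <dbl>            <dbl>
#> 1   500          40  500.      0.0345        0.0000241

evaluate_mse(fit, sim$truth)
#> # A tibble: 4 × 3
#>   parameter estimator       mse
#>   <chr>     <chr>         <dbl>
#> 1 template  mean      0.0544
#> 2 phase     mean      0.0000480
#> 3 template  mode      0.0510
#> 4 phase     mode      0.0000555

srvf_distance(weighted_mean_srvf(fit),
              template_srvf(sim$truth$c, sim$truth$basis))
#> [1] 0.1021685
```

Reading the output: the effective sample size stays at its maximum (no
weight degeneracy after the resample–move cycle); the posterior mean of the
noise variance (0.035) recovers the generating value 0.03; the per-coordinate
mean squared errors of the posterior mean/mode are ~0.05 for the 8 template
coefficients and ~5e-5 for the 160 phase increments; and the posterior-mean
template sits 0.10 from the truth in eFR distance. `phase_summaries()`,
`template_pca()`, `registered_functions()`, `tidy()`, and
`autoplot(fit, type = "template" | "phase" | "ess")` give the standard
posterior views, and `reg_cli()` (also installed as an `exec/seqreg`
script) exposes a `simulate / init / assimilate / summarize / evaluate`
pipeline over CSV files with reproducibility manifests.

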