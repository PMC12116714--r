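#include "seqreg.h"
using namespace Rcpp;

// ---------------------------------------------------------------------------
// small dense linear algebra (B is tiny: a handful of basis coefficients)

static void matvec(const NumericMatrix& A, const NumericVector& x,
                   NumericVector& out) {
  int nr = A.nrow(), nc = A.ncol();
  for (int i = 0; i < nr; ++i) {
    double acc = 0.0;
    for (int j = 0; j < nc; ++j) acc += A(i, j) * x[j];
    out[i] = acc;
  }
}

// in-place lower Cholesky of SPD matrix stored row-major in a; returns false
// on failure
static bool chol_lower(std::vector<double>& a, int n) {
  for (int j = 0; j < n; ++j) {
    double d = a[j * n + j];
    for (int k = 0; k < j; ++k) d -= a[j * n + k] * a[j * n + k];
    if (d <= 0.0) return false;
    d = std::sqrt(d);
    a[j * n + j] = d;
    for (int i = j + 1; i < n; ++i) {
      double v = a[i * n + j];
      for (int k = 0; k < j; ++k) v -= a[i * n + k] * a[j * n + k];
      a[i * n + j] = v / d;
    }
    for (int i = 0; i < j; ++i) a[i * n + j] = 0.0;
  }
  return true;
}

// ---------------------------------------------------------------------------
// Karcher (Frechet) mean of PL warps under the Fisher-Rao geometry: warps are
// represented by piecewise-constant sqrt-slopes psi on the unit sphere of
// L2([0,1]); intrinsic mean iterated from the normalized extrinsic start.

static NumericVector karcher_incr(const NumericMatrix& D,
                                  const NumericVector& s,
                                  int max_iter, double tol, bool intrinsic,
                                  bool* converged) {
  int K = D.nrow(), n = D.ncol();
  std::vector<double> w(K), psi(K * n);
  for (int k = 0; k < K; ++k) w[k] = s[k + 1] - s[k];
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k)
      psi[k + K * i] = std::sqrt(D(k, i) / w[k]);

  // extrinsic start: normalized pointwise mean
  std::vector<double> mu(K, 0.0);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) mu[k] += psi[k + K * i] / n;
  double nrm = 0.0;
  for (int k = 0; k < K; ++k) nrm += mu[k] * mu[k] * w[k];
  nrm = std::sqrt(nrm);
  for (int k = 0; k < K; ++k) mu[k] /= nrm;

  *converged = true;
  if (intrinsic) {
    *converged = false;
    std::vector<double> vbar(K);
    for (int it = 0; it < max_iter; ++it) {
      std::fill(vbar.begin(), vbar.end(), 0.0);
      for (int i = 0; i < n; ++i) {
        double ca = 0.0;
        for (int k = 0; k < K; ++k) ca += mu[k] * psi[k + K * i] * w[k];
        if (ca > 1.0) ca = 1.0;
        if (ca < -1.0) ca = -1.0;
        double th = std::acos(ca);
        if (th < 1e-14) continue;
        double fac = th / std::sin(th);
        for (int k = 0; k < K; ++k)
          vbar[k] += fac * (psi[k + K * i] - ca * mu[k]) / n;
      }
      double nv = 0.0;
      for (int k = 0; k < K; ++k) nv += vbar[k] * vbar[k] * w[k];
      nv = std::sqrt(nv);
      if (nv < tol) { *converged = true; break; }
      double cn = std::cos(nv), sn = std::sin(nv);
      double nn = 0.0;
      for (int k = 0; k < K; ++k) {
        mu[k] = cn * mu[k] + sn * vbar[k] / nv;
        nn += mu[k] * mu[k] * w[k];
      }
      nn = std::sqrt(nn);
      for (int k = 0; k < K; ++k) mu[k] /= nn;
    }
  }

  NumericVector dbar(K);
  double tot = 0.0;
  for (int k = 0; k < K; ++k) { dbar[k] = mu[k] * mu[k] * w[k]; tot += dbar[k]; }
  for (int k = 0; k < K; ++k) dbar[k] /= tot;
  return dbar;
}

// [[Rcpp::export]]
List karcher_incr_cpp(NumericMatrix D, NumericVector s, int max_iter,
                      double tol, bool intrinsic) {
  bool conv = true;
  NumericVector dbar = karcher_incr(D, s, max_iter, tol, intrinsic, &conv);
  return List::create(_["increments"] = dbar, _["converged"] = conv);
}

// ---------------------------------------------------------------------------
// initialization kernel for a new phase (DP-aligned warp composed with a
// concentrated Dirichlet perturbation) and its sampling density

// log Jacobian term: sum over interior partition points of
// log (ghat^{-1})'(gamma*(s_m)) = -log slope_ghat(P_m); optionally the
// endpoint m = M_gamma factor as printed in some accounts (not a proper
// density; off by default).
static double init_log_jacobian(const NumericVector& ghat,
                                const NumericVector& s,
                                const NumericVector& P,
                                bool endpoint) {
  int K = ghat.size();
  double lj = 0.0;
  int hi = endpoint ? K : (K - 1);
  for (int m = 1; m <= hi; ++m) {
    double x = (m == K) ? 1.0 : P[m];
    int k = seg_index(s, x);
    if (m == K) k = K - 1;
    lj -= std::log(ghat[k] / (s[k + 1] - s[k]));
  }
  return lj;
}

// [[Rcpp::export]]
List init_phase_one_cpp(NumericVector ghat, NumericVector s, double kappa_ini,
                        double eps_d, bool endpoint) {
  int K = ghat.size();
  double a = kappa_ini / K;
  NumericVector dp = rdirichlet_sym(K, a, eps_d);
  NumericVector P = warp_nodes(dp);
  NumericVector Vh = warp_nodes(ghat);
  NumericVector dnew(K);
  double prev = 0.0;
  for (int m = 1; m <= K; ++m) {
    double v = (m == K) ? 1.0 : pl_eval(s, Vh, P[m]);
    dnew[m - 1] = v - prev;
    prev = v;
  }
  clip_simplex(dnew, eps_d);
  NumericVector alpha(K, a);
  double lk = log_dirichlet(dp, alpha) + init_log_jacobian(ghat, s, P, endpoint);
  return List::create(_["d"] = dnew, _["log_kernel"] = lk);
}

// [[Rcpp::export]]
double init_phase_density_cpp(NumericVector dnew, NumericVector ghat,
                              NumericVector s, double kappa_ini,
                              bool endpoint) {
  int K = ghat.size();
  NumericVector Vh = warp_nodes(ghat);
  NumericVector Vn = warp_nodes(dnew);
  NumericVector P(K + 1), dp(K);
  P[0] = 0.0; P[K] = 1.0;
  for (int m = 1; m < K; ++m) P[m] = pl_inv_eval(s, Vh, Vn[m]);
  for (int k = 0; k < K; ++k) dp[k] = P[k + 1] - P[k];
  for (int k = 0; k < K; ++k) if (dp[k] <= 0.0) return R_NegInf;
  NumericVector alpha(K, kappa_ini / K);
  return log_dirichlet(dp, alpha) + init_log_jacobian(ghat, s, P, endpoint);
}

// ---------------------------------------------------------------------------
// Metropolis-Hastings kernels

// one composition-proposal MH move for a single phase-increment vector;
// updates d and ss in place, returns acceptance. alpha_prior holds the
// Dirichlet prior parameters; normalizing constants cancel in the
// acceptance ratio except through the (a - 1) exponents, so only the
// exponent terms are evaluated.
static bool phase_mh(NumericVector& d, double& ss,
                     const NumericVector& qmu, const NumericVector& grid,
                     const NumericVector& s, const double* qobs,
                     double sigma2, double kappa_prop,
                     const NumericVector& alpha_prior,
                     double eps_d, bool use_lik) {
  int K = d.size();
  if (K >= 63) stop("phase_mh: partition too large");
  double a = kappa_prop / K;
  double dp[64], V[64], P[64], dnew[64], Vn[64], Prev[64], dprev[64];

  // dp ~ Dir(a 1_K), clipped
  {
    double tot = 0.0;
    for (int k = 0; k < K; ++k) { dp[k] = R::rgamma(a, 1.0); tot += dp[k]; }
    if (tot <= 0.0) { for (int k = 0; k < K; ++k) dp[k] = 1.0; tot = K; }
    double tot2 = 0.0;
    for (int k = 0; k < K; ++k) {
      dp[k] /= tot;
      if (dp[k] < eps_d) dp[k] = eps_d;
      tot2 += dp[k];
    }
    for (int k = 0; k < K; ++k) dp[k] /= tot2;
  }
  V[0] = P[0] = 0.0;
  for (int k = 0; k < K; ++k) {
    V[k + 1] = V[k] + d[k];
    P[k + 1] = P[k] + dp[k];
  }
  V[K] = P[K] = 1.0;

  // compose: dnew = increments of gamma(P); partition is uniform within
  // segments, walk segments of s
  double prev = 0.0;
  for (int m = 1; m <= K; ++m) {
    double v;
    if (m == K) v = 1.0;
    else {
      int k = 0;
      while (k < K - 1 && s[k + 1] < P[m]) ++k;
      v = V[k] + (P[m] - s[k]) * d[k] / (s[k + 1] - s[k]);
    }
    dnew[m - 1] = v - prev;
    prev = v;
  }
  {
    double tot = 0.0;
    for (int k = 0; k < K; ++k) {
      if (dnew[k] < eps_d) dnew[k] = eps_d;
      tot += dnew[k];
    }
    for (int k = 0; k < K; ++k) dnew[k] /= tot;
  }
  Vn[0] = 0.0;
  for (int k = 0; k < K; ++k) Vn[k + 1] = Vn[k] + dnew[k];
  Vn[K] = 1.0;

  // reverse draw: increments of gamma_new^{-1} o gamma at partition points
  Prev[0] = 0.0; Prev[K] = 1.0;
  for (int m = 1; m < K; ++m) {
    double t = V[m];
    int k = 0;
    while (k < K - 1 && Vn[k + 1] < t) ++k;
    Prev[m] = s[k] + (t - Vn[k]) * (s[k + 1] - s[k]) / dnew[k];
  }
  for (int k = 0; k < K; ++k) {
    dprev[k] = Prev[k + 1] - Prev[k];
    if (dprev[k] <= 0.0) return false;
  }

  // log ratio: Dirichlet normalizers of the proposal cancel; Jacobians and
  // exponent terms remain. Work with products to minimize log calls.
  double prod_fwd = 1.0, prod_rev = 1.0;
  for (int k = 0; k < K; ++k) {
    prod_fwd *= dp[k];
    prod_rev *= dprev[k];
  }
  double delta = (a - 1.0) * (std::log(prod_rev) - std::log(prod_fwd));
  for (int m = 1; m < K; ++m) {
    int kf = 0, kr = 0;
    while (kf < K - 1 && s[kf + 1] < P[m]) ++kf;
    while (kr < K - 1 && s[kr + 1] < Prev[m]) ++kr;
    // forward Jacobian uses slopes of gamma, reverse those of gamma_new
    delta += std::log(d[kf] / (s[kf + 1] - s[kf])) -
             std::log(dnew[kr] / (s[kr + 1] - s[kr]));
  }
  for (int k = 0; k < K; ++k)
    delta += (alpha_prior[k] - 1.0) * std::log(dnew[k] / d[k]);

  double ss_new = ss;
  if (use_lik) {
    NumericVector dn(K);
    for (int k = 0; k < K; ++k) dn[k] = dnew[k];
    ss_new = ss_one(qmu, grid, s, dn, qobs);
    delta += -(ss_new - ss) / (2.0 * sigma2);
  }
  if (std::log(unif_rand()) < delta) {
    for (int k = 0; k < K; ++k) d[k] = dnew[k];
    ss = ss_new;
    return true;
  }
  return false;
}

// one Gaussian random-walk MH move for the template coefficients; updates c,
// qmu and the per-function residual sums in place
static bool templ_mh(NumericVector& c, NumericVector& qmu, NumericVector& ssv,
                     const NumericMatrix& Phi, const NumericVector& grid,
                     const NumericVector& s, const NumericMatrix& D,
                     const NumericMatrix& Q, double sigma2,
                     const NumericVector& sigma_c_diag,
                     const std::vector<double>& L, bool use_lik) {
  int B = c.size(), M = grid.size(), n = Q.ncol();
  NumericVector z(B), cprop(B);
  for (int b = 0; b < B; ++b) z[b] = norm_rand();
  for (int b = 0; b < B; ++b) {
    double acc = c[b];
    for (int k = 0; k <= b; ++k) acc += L[b * B + k] * z[k];
    cprop[b] = acc;
  }
  NumericVector qprop(M);
  matvec(Phi, cprop, qprop);
  double delta = 0.0;
  std::vector<double> ssp(n);
  if (use_lik) {
    double tot = 0.0, tot0 = 0.0;
    for (int i = 0; i < n; ++i) {
      NumericVector di = const_cast<NumericMatrix&>(D)(_, i);
      ssp[i] = ss_one(qprop, grid, s, di, &Q(0, i));
      tot += ssp[i];
      tot0 += ssv[i];
    }
    delta += -(tot - tot0) / (2.0 * sigma2);
  }
  for (int b = 0; b < B; ++b)
    delta += -0.5 * (cprop[b] * cprop[b] - c[b] * c[b]) / sigma_c_diag[b];
  if (std::log(unif_rand()) < delta) {
    for (int b = 0; b < B; ++b) c[b] = cprop[b];
    for (int m = 0; m < M; ++m) qmu[m] = qprop[m];
    if (use_lik) for (int i = 0; i < n; ++i) ssv[i] = ssp[i];
    return true;
  }
  return false;
}

// [[Rcpp::export]]
List mh_sweeps_one_cpp(NumericVector c, NumericMatrix D, double sigma2,
                       NumericMatrix Q, NumericMatrix Phi, NumericVector grid,
                       NumericVector s, NumericVector sigma_c_diag,
                       double kappa_prior, NumericVector u_base,
                       double kappa_prop, NumericMatrix Lprop, int n_sweeps,
                       double eps_d, bool use_lik) {
  int B = c.size(), n = Q.ncol(), K = D.nrow(), M = grid.size();
  NumericVector cc = clone(c);
  NumericMatrix DD = clone(D);
  NumericVector qmu(M);
  matvec(Phi, cc, qmu);
  NumericVector ssv(n);
  for (int i = 0; i < n; ++i) {
    NumericVector di = DD(_, i);
    ssv[i] = ss_one(qmu, grid, s, di, &Q(0, i));
  }
  NumericVector alpha_prior(K);
  for (int k = 0; k < K; ++k) alpha_prior[k] = kappa_prior * u_base[k];
  std::vector<double> L(B * B);
  for (int i = 0; i < B; ++i)
    for (int j = 0; j < B; ++j) L[i * B + j] = Lprop(i, j);

  int acc_c = 0, acc_d = 0;
  for (int sw = 0; sw < n_sweeps; ++sw) {
    if (templ_mh(cc, qmu, ssv, Phi, grid, s, DD, Q, sigma2, sigma_c_diag, L,
                 use_lik))
      ++acc_c;
    for (int i = 0; i < n; ++i) {
      NumericVector di = DD(_, i);
      double ssi = ssv[i];
      if (phase_mh(di, ssi, qmu, grid, s, &Q(0, i), sigma2, kappa_prop,
                   alpha_prior, eps_d, use_lik)) {
        DD(_, i) = di;
        ssv[i] = ssi;
        ++acc_d;
      }
    }
  }
  return List::create(_["c"] = cc, _["D"] = DD, _["acc_c"] = acc_c,
                      _["acc_d"] = acc_d, _["n_c"] = n_sweeps,
                      _["n_d"] = n_sweeps * n);
}

// ---------------------------------------------------------------------------
// centering: make the Karcher mean of the phases the identity by warping the
// template and all phases by the mean warp / its inverse

static void center_internal(NumericVector& c, NumericMatrix& D,
                            NumericVector& qmu,
                            const NumericMatrix& Phi,
                            const NumericMatrix& Pphi,
                            const NumericVector& grid, const NumericVector& s,
                            const NumericMatrix& Tproj,
                            const NumericVector& tproj0,
                            const NumericVector& dense, double eps_d) {
  int K = D.nrow(), n = D.ncol(), M = grid.size(), Nd = dense.size();
  bool conv;
  NumericVector dbar = karcher_incr(D, s, 200, 1e-12, true, &conv);
  NumericVector Vbar = warp_nodes(dbar);

  std::vector<double> y(Nd);
  for (int i = 0; i < n; ++i) {
    NumericVector Vi = warp_nodes(D(_, i));
    for (int j = 0; j < Nd; ++j)
      y[j] = pl_eval(s, Vi, pl_inv_eval(s, Vbar, dense[j]));
    NumericVector e(K);
    for (int k = 0; k < K; ++k) {
      double acc = tproj0[k];
      for (int j = 0; j < Nd; ++j) acc += Tproj(k, j) * y[j];
      e[k] = acc;
    }
    clip_simplex(e, eps_d);
    D(_, i) = e;
  }

  // template: the mean warp's inverse acts on the template, so that
  // (q_tilde, gamma_tilde_i^{-1}) == (q_mu, gamma_i^{-1}) and the likelihood
  // is unchanged; re-projected onto the basis span
  NumericVector qt(M);
  int kk = 0;
  for (int m = 0; m < M; ++m) {
    double t = grid[m];
    while (kk < K - 1 && Vbar[kk + 1] < t) ++kk;
    double ds = s[kk + 1] - s[kk];
    double x = s[kk] + (t - Vbar[kk]) * ds / dbar[kk];
    qt[m] = interp_lin(grid, qmu, x) * std::sqrt(ds / dbar[kk]);
  }
  matvec(Pphi, qt, c);
  matvec(Phi, c, qmu);
}

// [[Rcpp::export]]
List center_one_cpp(NumericVector c, NumericMatrix D, NumericMatrix Phi,
                    NumericMatrix Pphi, NumericVector grid, NumericVector s,
                    NumericMatrix Tproj, NumericVector tproj0,
                    NumericVector dense, double eps_d) {
  NumericVector cc = clone(c);
  NumericMatrix DD = clone(D);
  NumericVector qmu(grid.size());
  matvec(Phi, cc, qmu);
  center_internal(cc, DD, qmu, Phi, Pphi, grid, s, Tproj, tproj0, dense,
                  eps_d);
  return List::create(_["c"] = cc, _["D"] = DD);
}

// ---------------------------------------------------------------------------
// batch MCMC: Gibbs + adaptive random-walk Metropolis over (c, d_{1:n}, s2)

// [[Rcpp::export]]
List mcmc_run_cpp(NumericVector c0, NumericMatrix D0, double s20,
                  NumericMatrix Q, NumericMatrix Phi, NumericVector grid,
                  NumericVector s, NumericVector sigma_c_diag,
                  double kappa_prior, NumericVector u_base, double kappa_prop,
                  double alpha_sig, double beta_sig, int n_iter, int burn_in,
                  IntegerVector keep_iters, double eps_d, bool use_lik,
                  bool do_center, bool gibbs_half, bool update_sigma2,
                  NumericMatrix Pphi, NumericMatrix Tproj,
                  NumericVector tproj0, NumericVector dense,
                  double target_acc, double init_log_scale) {
  int B = c0.size(), M = grid.size(), n = Q.ncol(), K = D0.nrow();
  int n_keep = keep_iters.size();

  NumericVector c = clone(c0);
  NumericMatrix D = clone(D0);
  double s2 = s20;
  NumericVector qmu(M);
  matvec(Phi, c, qmu);
  NumericVector ssv(n);
  for (int i = 0; i < n; ++i) {
    NumericVector di = D(_, i);
    ssv[i] = ss_one(qmu, grid, s, di, &Q(0, i));
  }
  NumericVector alpha_prior(K);
  for (int k = 0; k < K; ++k) alpha_prior[k] = kappa_prior * u_base[k];

  // adaptive proposal state
  double ls = init_log_scale;
  std::vector<double> mvec(B, 0.0), Msum(B * B, 0.0), cov(B * B, 0.0);
  std::vector<double> L(B * B, 0.0);
  for (int b = 0; b < B; ++b) L[b * B + b] = std::exp(0.5 * ls);

  NumericMatrix Ckeep(n_keep, B);
  NumericVector S2keep(n_keep);
  NumericVector Dkeep(n_keep * K * n);
  Dkeep.attr("dim") = IntegerVector::create(K, n, n_keep);

  std::vector<int> ord(n);
  long acc_c = 0, acc_d = 0, try_c = 0, try_d = 0;
  int kp = 0;

  for (int t = 1; t <= n_iter; ++t) {
    bool a = templ_mh(c, qmu, ssv, Phi, grid, s, D, Q, s2, sigma_c_diag, L,
                      use_lik);
    if (a) ++acc_c;
    ++try_c;

    // phase updates in random scan order
    for (int i = 0; i < n; ++i) ord[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(ord[i], ord[j]);
    }
    for (int ii = 0; ii < n; ++ii) {
      int i = ord[ii];
      NumericVector di = D(_, i);
      double ssi = ssv[i];
      if (phase_mh(di, ssi, qmu, grid, s, &Q(0, i), s2, kappa_prop,
                   alpha_prior, eps_d, use_lik)) {
        D(_, i) = di;
        ssv[i] = ssi;
        ++acc_d;
      }
      ++try_d;
    }

    if (update_sigma2) {
      double sstot = 0.0;
      for (int i = 0; i < n; ++i) sstot += ssv[i];
      if (!use_lik) sstot = 0.0;
      double shape = alpha_sig + 0.5 * n * M * (use_lik ? 1.0 : 0.0);
      double rate = beta_sig + (gibbs_half ? 0.5 * sstot : sstot);
      s2 = 1.0 / R::rgamma(shape, 1.0 / rate);
    }

    if (do_center) {
      center_internal(c, D, qmu, Phi, Pphi, grid, s, Tproj, tproj0, dense,
                      eps_d);
      if (use_lik)
        for (int i = 0; i < n; ++i) {
          NumericVector di = D(_, i);
          ssv[i] = ss_one(qmu, grid, s, di, &Q(0, i));
        }
    }

    // adapt the template proposal during burn-in only
    if (t <= burn_in) {
      double eta = 5.0 / std::sqrt((double)t);
      if (eta > 0.1) eta = 0.1;
      ls += eta * ((a ? 1.0 : 0.0) - target_acc);
      std::vector<double> delta(B), delta2(B);
      for (int b = 0; b < B; ++b) delta[b] = c[b] - mvec[b];
      for (int b = 0; b < B; ++b) mvec[b] += delta[b] / t;
      for (int b = 0; b < B; ++b) delta2[b] = c[b] - mvec[b];
      for (int i = 0; i < B; ++i)
        for (int j = 0; j < B; ++j) Msum[i * B + j] += delta[i] * delta2[j];
      if (t >= 100 && t % 50 == 0) {
        double sc = std::exp(ls);
        for (int i = 0; i < B; ++i)
          for (int j = 0; j < B; ++j) {
            cov[i * B + j] = sc * Msum[i * B + j] / (t - 1);
            if (i == j) cov[i * B + j] += sc * 1e-8 + 1e-12;
          }
        std::vector<double> A = cov;
        if (chol_lower(A, B)) L = A;
      } else if (t < 100) {
        for (int b = 0; b < B; ++b) L[b * B + b] = std::exp(0.5 * ls);
      }
    }

    if (kp < n_keep && t == keep_iters[kp]) {
      for (int b = 0; b < B; ++b) Ckeep(kp, b) = c[b];
      S2keep[kp] = s2;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k)
          Dkeep[k + K * (i + n * (R_xlen_t)kp)] = D(k, i);
      ++kp;
    }
  }

  return List::create(_["C"] = Ckeep, _["D"] = Dkeep, _["sigma2"] = S2keep,
                      _["acc_template"] = (double)acc_c / try_c,
                      _["acc_phase"] = (double)acc_d / try_d,
                      _["log_scale"] = ls);
}
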