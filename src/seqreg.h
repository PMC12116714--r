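#ifndef SEQREG_H
#define SEQREG_H

#include <Rcpp.h>
#include <cmath>
#include <vector>

// Linear interpolation of (x, y) at t, clamped to the range of x.
// x must be strictly increasing.
inline double interp_lin(const Rcpp::NumericVector& x,
                         const Rcpp::NumericVector& y,
                         double t) {
  int n = x.size();
  if (t <= x[0]) return y[0];
  if (t >= x[n - 1]) return y[n - 1];
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (x[mid] <= t) lo = mid; else hi = mid;
  }
  double w = (t - x[lo]) / (x[lo + 1] - x[lo]);
  return y[lo] + w * (y[lo + 1] - y[lo]);
}

// Index k of the segment [knots[k], knots[k+1]] containing t (right-open,
// last segment right-closed). knots strictly increasing.
inline int seg_index(const Rcpp::NumericVector& knots, double t) {
  int n = knots.size();
  if (t <= knots[0]) return 0;
  if (t >= knots[n - 2]) return n - 2;
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (knots[mid] <= t) lo = mid; else hi = mid;
  }
  return lo;
}

// Cumulative node values V (length K+1) of a piecewise-linear warp with
// increments d (length K): V[0] = 0, V[K] = 1 exactly.
inline Rcpp::NumericVector warp_nodes(const Rcpp::NumericVector& d) {
  int K = d.size();
  Rcpp::NumericVector V(K + 1);
  V[0] = 0.0;
  for (int k = 0; k < K; ++k) V[k + 1] = V[k] + d[k];
  V[K] = 1.0;
  return V;
}

// Evaluate the PL warp with nodes (s, V) at t.
inline double pl_eval(const Rcpp::NumericVector& s,
                      const Rcpp::NumericVector& V,
                      double t) {
  int k = seg_index(s, t);
  double w = (t - s[k]) / (s[k + 1] - s[k]);
  return V[k] + w * (V[k + 1] - V[k]);
}

// Evaluate the inverse of the PL warp with nodes (s, V) at t in [0,1].
inline double pl_inv_eval(const Rcpp::NumericVector& s,
                          const Rcpp::NumericVector& V,
                          double t) {
  int k = seg_index(V, t);
  double w = (t - V[k]) / (V[k + 1] - V[k]);
  return s[k] + w * (s[k + 1] - s[k]);
}

// log Dirichlet(d; alpha) density on the open simplex.
inline double log_dirichlet(const Rcpp::NumericVector& d,
                            const Rcpp::NumericVector& alpha) {
  double s = 0.0, asum = 0.0;
  int K = d.size();
  for (int k = 0; k < K; ++k) {
    if (d[k] <= 0.0) return R_NegInf;
    s += (alpha[k] - 1.0) * std::log(d[k]) - R::lgammafn(alpha[k]);
    asum += alpha[k];
  }
  return s + R::lgammafn(asum);
}

// Draw Dirichlet(alpha 1_K) with symmetric concentration, clipped away from
// the simplex boundary by eps and renormalized.
inline Rcpp::NumericVector rdirichlet_sym(int K, double alpha, double eps) {
  Rcpp::NumericVector d(K);
  double tot = 0.0;
  for (int k = 0; k < K; ++k) {
    d[k] = R::rgamma(alpha, 1.0);
    tot += d[k];
  }
  if (tot <= 0.0) { for (int k = 0; k < K; ++k) d[k] = 1.0; tot = K; }
  double tot2 = 0.0;
  for (int k = 0; k < K; ++k) {
    d[k] = d[k] / tot;
    if (d[k] < eps) d[k] = eps;
    tot2 += d[k];
  }
  for (int k = 0; k < K; ++k) d[k] /= tot2;
  return d;
}

// Clip increments below eps and renormalize to the simplex.
inline void clip_simplex(Rcpp::NumericVector& d, double eps) {
  int K = d.size();
  double tot = 0.0;
  for (int k = 0; k < K; ++k) {
    if (d[k] < eps) d[k] = eps;
    tot += d[k];
  }
  for (int k = 0; k < K; ++k) d[k] /= tot;
}

// Residual sum of squares of one observed SRVF against the template warped by
// the inverse of the PL warp with increments d on partition s:
//   SS = sum_m ( qobs[m] - qmu(ginv(t_m)) * sqrt(ginv'(t_m)) )^2.
inline double ss_one(const Rcpp::NumericVector& qmu,
                     const Rcpp::NumericVector& grid,
                     const Rcpp::NumericVector& s,
                     const Rcpp::NumericVector& d,
                     const double* qobs) {
  int M = grid.size();
  int K = d.size();
  double Vbuf[64];
  if (K >= 63) Rcpp::stop("ss_one: partition too large");
  Vbuf[0] = 0.0;
  for (int k = 0; k < K; ++k) Vbuf[k + 1] = Vbuf[k] + d[k];
  Vbuf[K] = 1.0;
  const double* V = Vbuf;
  double ss = 0.0;
  int k = 0;
  int g = 0;  // walking pointer into the grid: x is monotone in m
  double sq = std::sqrt((s[1] - s[0]) / d[0]);
  for (int m = 0; m < M; ++m) {
    double t = grid[m];
    while (k < K - 1 && V[k + 1] < t) {
      ++k;
      sq = std::sqrt((s[k + 1] - s[k]) / d[k]);
    }
    double x = s[k] + (t - V[k]) * (s[k + 1] - s[k]) / d[k];
    while (g < M - 2 && grid[g + 1] <= x) ++g;
    while (g > 0 && grid[g] > x) --g;
    double w = (x - grid[g]) / (grid[g + 1] - grid[g]);
    if (w < 0.0) w = 0.0;
    if (w > 1.0) w = 1.0;
    double val = (qmu[g] + w * (qmu[g + 1] - qmu[g])) * sq;
    double r = qobs[m] - val;
    ss += r * r;
  }
  return ss;
}

#endif
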