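#include "seqreg.h"
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector interp_lin_cpp(NumericVector x, NumericVector y, NumericVector t) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = interp_lin(x, y, t[i]);
  return out;
}

// Evaluate a piecewise-linear warp with increments d over partition s.
// [[Rcpp::export]]
NumericVector pl_warp_eval_cpp(NumericVector d, NumericVector s, NumericVector t) {
  NumericVector V = warp_nodes(d);
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = pl_eval(s, V, t[i]);
  return out;
}

// The warped template (q_mu, gamma^{-1}) evaluated on the observation grid,
// gamma the PL warp with increments d on partition s.
// [[Rcpp::export]]
NumericVector warped_template_cpp(NumericVector qmu, NumericVector grid,
                                  NumericVector s, NumericVector d) {
  int M = grid.size();
  int K = d.size();
  NumericVector V = warp_nodes(d);
  NumericVector out(M);
  int k = 0;
  for (int m = 0; m < M; ++m) {
    double t = grid[m];
    while (k < K - 1 && V[k + 1] < t) ++k;
    double ds = s[k + 1] - s[k];
    double x = s[k] + (t - V[k]) * ds / d[k];
    out[m] = interp_lin(grid, qmu, x) * std::sqrt(ds / d[k]);
  }
  return out;
}

// Residual sums of squares of each observed SRVF (columns of Q) against the
// template warped by the inverse of the corresponding phase (columns of D).
// [[Rcpp::export]]
NumericVector ss_functions_cpp(NumericVector qmu, NumericVector grid,
                               NumericVector s, NumericMatrix D,
                               NumericMatrix Q) {
  int n = Q.ncol();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    NumericVector d = D(_, i);
    out[i] = ss_one(qmu, grid, s, d, &Q(0, i));
  }
  return out;
}

// Dynamic-programming elastic alignment: finds the monotone lattice path
// minimizing || qref - (q o gamma) sqrt(gamma') ||^2 over PL warps whose
// segments have slopes l/k for steps (k, l) in the neighbourhood set.
// Ties are broken toward slope 1 by visiting the (1,1) step first and
// replacing only on strict improvement.
//
// Interpolated values of q along every admissible edge depend only on the
// step and the edge's start row, so they are precomputed once (uniform grid)
// and shared across reference templates in dp_align_many.

struct DPTables {
  int M, P;
  std::vector<int> kk, ll;
  // qe[p][j*M + b]: sqrt(slope_p) * q at row position b + l*j/k, j = 0..k
  std::vector<std::vector<double>> qe;
  // wt[p][j]: trapezoid weight of offset j within the step
  std::vector<std::vector<double>> wt;
};

static void dp_build_tables(const NumericVector& q, const NumericVector& grid,
                            const IntegerMatrix& steps, DPTables& T) {
  int M = grid.size();
  int P = steps.nrow();
  double h = grid[1] - grid[0];
  T.M = M; T.P = P;
  T.kk.resize(P); T.ll.resize(P);
  T.qe.assign(P, std::vector<double>());
  T.wt.assign(P, std::vector<double>());
  for (int p = 0; p < P; ++p) {
    int k = steps(p, 0), l = steps(p, 1);
    T.kk[p] = k; T.ll[p] = l;
    double slope = (double)l / k;
    double sq = std::sqrt(slope);
    T.qe[p].assign((k + 1) * M, 0.0);
    T.wt[p].assign(k + 1, h);
    T.wt[p][0] = T.wt[p][k] = h / 2.0;
    for (int j = 0; j <= k; ++j) {
      double frac = slope * j;
      int f0 = (int)std::floor(frac + 1e-12);
      double wf = frac - f0;
      for (int b = 0; b < M; ++b) {
        int i0 = b + f0;
        double v;
        if (i0 >= M - 1) v = q[M - 1];
        else v = q[i0] + wf * (q[i0 + 1] - q[i0]);
        T.qe[p][j * M + b] = sq * v;
      }
    }
  }
}

static NumericVector dp_solve(const double* qref, const NumericVector& grid,
                              const DPTables& T) {
  int M = T.M, P = T.P;
  std::vector<double> E(M * M, R_PosInf);
  std::vector<int> pred(M * M, -1);
  E[0] = 0.0;
  for (int j = 1; j < M; ++j) {    // row: y index
    for (int i = 1; i < M; ++i) {  // column: x index
      double best = R_PosInf;
      int bestp = -1;
      for (int p = 0; p < P; ++p) {
        int k = T.kk[p], l = T.ll[p];
        int a = i - k, b = j - l;
        if (a < 0 || b < 0) continue;
        double Eprev = E[a + M * b];
        if (!R_finite(Eprev)) continue;
        const std::vector<double>& qe = T.qe[p];
        const std::vector<double>& wt = T.wt[p];
        double cost = 0.0;
        for (int jj = 0; jj <= k; ++jj) {
          double r = qref[a + jj] - qe[jj * M + b];
          cost += wt[jj] * r * r;
        }
        double tot = Eprev + cost;
        if (tot < best) { best = tot; bestp = a + M * b; }
      }
      E[i + M * j] = best;
      pred[i + M * j] = bestp;
    }
  }
  std::vector<int> px, py;
  int cur = (M - 1) + M * (M - 1);
  if (!R_finite(E[cur])) stop("dp_align: no admissible path");
  while (cur >= 0) {
    px.push_back(cur % M);
    py.push_back(cur / M);
    cur = pred[cur];
  }
  int np = px.size();
  NumericVector kx(np), ky(np);
  for (int a = 0; a < np; ++a) {
    kx[a] = grid[px[np - 1 - a]];
    ky[a] = grid[py[np - 1 - a]];
  }
  NumericVector out(M);
  for (int m = 0; m < M; ++m) out[m] = interp_lin(kx, ky, grid[m]);
  out[0] = 0.0;
  out[M - 1] = 1.0;
  return out;
}

// [[Rcpp::export]]
NumericVector dp_align_cpp(NumericVector qref, NumericVector q,
                           NumericVector grid, IntegerMatrix steps) {
  int M = grid.size();
  double h = grid[1] - grid[0];
  for (int m = 1; m < M; ++m)
    if (std::abs(grid[m] - grid[m - 1] - h) > 1e-9 * (1.0 + std::abs(h)))
      stop("dp_align: grid must be uniform");
  DPTables T;
  dp_build_tables(q, grid, steps, T);
  return dp_solve(&qref[0], grid, T);
}

// Align one function to many reference templates (columns of Qref), sharing
// the precomputed interpolation tables; returns warps as columns.
// [[Rcpp::export]]
NumericMatrix dp_align_many_cpp(NumericMatrix Qref, NumericVector q,
                                NumericVector grid, IntegerMatrix steps) {
  int M = grid.size(), J = Qref.ncol();
  DPTables T;
  dp_build_tables(q, grid, steps, T);
  NumericMatrix out(M, J);
  for (int j = 0; j < J; ++j) {
    NumericVector g = dp_solve(&Qref(0, j), grid, T);
    for (int m = 0; m < M; ++m) out(m, j) = g[m];
  }
  return out;
}
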