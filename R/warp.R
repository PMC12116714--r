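#' Piecewise-linear warping function with simplex increments
#'
#' A boundary-preserving, strictly increasing piecewise-linear time warp on
#' `[0, 1]`, stored as the vector of its rises (increments) over a fixed
#' partition. The increments are positive and sum to one, so each warp is a
#' point in the open probability simplex; the identity warp has all increments
#' equal. This is the low-dimensional phase representation used throughout
#' the hierarchical model.
#'
#' @param increments Positive numeric vector summing to 1 (renormalized if
#'   within 1e-6 of 1).
#' @param partition Increasing vector of knots `0 = s_1 < ... < s_K+1 = 1`;
#'   defaults to the uniform partition.
#' @return An object of class `pl_warp`.
#' @examples
#' w <- pl_warp(c(0.3, 0.2, 0.5))
#' warp_eval(w, c(0, 0.5, 1))
#' @export
pl_warp <- function(increments, partition = NULL) {
  increments <- as.numeric(increments)
  K <- length(increments)
  if (K < 2) stop("pl_warp: need at least 2 increments", call. = FALSE)
  if (is.null(partition)) partition <- seq(0, 1, length.out = K + 1)
  partition <- as.numeric(partition)
  if (length(partition) != K + 1 || any(diff(partition) <= 0) ||
      abs(partition[1]) > 1e-10 || abs(partition[K + 1] - 1) > 1e-10)
    stop("pl_warp: invalid partition", call. = FALSE)
  partition[1] <- 0; partition[K + 1] <- 1
  if (any(increments <= 0))
    stop("pl_warp: increments must be positive", call. = FALSE)
  s <- sum(increments)
  if (abs(s - 1) > 1e-6)
    stop("pl_warp: increments must sum to 1", call. = FALSE)
  structure(list(partition = partition, increments = increments / s),
            class = "pl_warp")
}

#' Identity warp on a partition
#' @param K Number of increments (partition has `K + 1` knots).
#' @return A `pl_warp` with equal increments.
#' @export
warp_identity <- function(K) pl_warp(rep(1 / K, K))

#' Monotone warp sampled on a grid
#'
#' Represents a warp by its values on a (fine) grid, e.g. the output of
#' dynamic-programming alignment before projection onto a partition.
#'
#' @param grid Increasing time points spanning `[0, 1]`.
#' @param values Warp values: `values[1] = 0`, last value 1, strictly
#'   increasing.
#' @return An object of class `grid_warp`.
#' @export
grid_warp <- function(grid, values) {
  grid <- as.numeric(grid); values <- as.numeric(values)
  M <- length(grid)
  if (length(values) != M || M < 2)
    stop("grid_warp: lengths differ or too short", call. = FALSE)
  if (any(diff(grid) <= 0)) stop("grid_warp: grid not increasing", call. = FALSE)
  if (abs(values[1]) > 1e-8 || abs(values[M] - 1) > 1e-8)
    stop("grid_warp: boundary values must be 0 and 1", call. = FALSE)
  if (any(diff(values) <= 0))
    stop("grid_warp: values must be strictly increasing", call. = FALSE)
  values[1] <- 0; values[M] <- 1
  structure(list(grid = grid, values = values), class = "grid_warp")
}

# internal: knot representation (x, y) of any warp
warp_knots <- function(w) {
  if (inherits(w, "pl_warp")) {
    list(x = w$partition, y = c(0, cumsum(w$increments)))
  } else if (inherits(w, "grid_warp")) {
    list(x = w$grid, y = w$values)
  } else stop("not a warp", call. = FALSE)
}

#' Evaluate a warp
#' @param w A `pl_warp` or `grid_warp`.
#' @param t Points in `[0, 1]`.
#' @return `gamma(t)`.
#' @export
warp_eval <- function(w, t) {
  k <- warp_knots(w)
  approx(k$x, k$y, xout = pmin(pmax(t, 0), 1), ties = "ordered")$y
}

# internal: piecewise-constant derivative of a warp evaluated at t
# (slope of the segment containing t, right-continuous; last segment at t = 1)
warp_deriv <- function(w, t) {
  k <- warp_knots(w)
  seg <- findInterval(t, k$x, rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1L), length(k$x) - 1L)
  diff(k$y)[seg] / diff(k$x)[seg]
}

#' Group action of a warp on an SRVF
#'
#' Computes `(q, gamma) = (q o gamma) sqrt(gamma')`, the SRVF of the warped
#' function, sampled on `q`'s grid; `q o gamma` uses linear interpolation and
#' `gamma'` is the piecewise-constant slope of the warp's segments. The action
#' is an isometry of L2, which is why the eFR distance is invariant to
#' simultaneous warping.
#'
#' @param q A `grid_function` in SRVF space.
#' @param w A `pl_warp` or `grid_warp`.
#' @return A `grid_function` in SRVF space on `q`'s grid.
#' @export
warp_srvf <- function(q, w) {
  stopifnot(inherits(q, "grid_function"))
  if (q$space != "q") stop("warp_srvf: q must be in SRVF space", call. = FALSE)
  k <- warp_knots(w)
  if (any(diff(k$y) <= 0)) stop("warp_srvf: warp is not strictly increasing", call. = FALSE)
  gt <- warp_eval(w, q$grid)
  gd <- warp_deriv(w, q$grid)
  qv <- approx(q$grid, q$values, xout = pmin(pmax(gt, 0), 1), ties = "ordered")$y
  grid_function(q$grid, qv * sqrt(gd), "q")
}

#' Compose two warps
#'
#' `(gamma1 o gamma2)(t) = gamma1(gamma2(t))`, evaluated exactly at the output
#' grid points and returned as a `grid_warp` (linear interpolation between
#' them). Boundary values are preserved exactly.
#'
#' @param w1,w2 Warps on `[0, 1]`.
#' @param out_grid Evaluation grid for the result; defaults to a 201-point
#'   uniform grid refined by the knots of `w2`.
#' @return A `grid_warp`.
#' @export
warp_compose <- function(w1, w2, out_grid = NULL) {
  if (is.null(out_grid)) {
    out_grid <- sort(unique(c(seq(0, 1, length.out = 201), warp_knots(w2)$x)))
  }
  v <- warp_eval(w1, warp_eval(w2, out_grid))
  v[1] <- 0; v[length(v)] <- 1
  grid_warp(out_grid, v)
}

#' Invert a warp
#'
#' For a `pl_warp` the inverse is exact: a piecewise-linear warp whose
#' partition is the cumulative increments and whose increments are the
#' original partition gaps. For a `grid_warp`, the axes are swapped and the
#' result re-interpolated onto the original grid.
#'
#' @param w A warp.
#' @return A warp of the same class.
#' @export
warp_inverse <- function(w) {
  if (inherits(w, "pl_warp")) {
    k <- warp_knots(w)
    pl_warp(diff(k$x), partition = k$y)
  } else {
    v <- approx(w$values, w$grid, xout = w$grid, ties = "ordered")$y
    v[1] <- 0; v[length(v)] <- 1
    grid_warp(w$grid, v)
  }
}

# ---------------------------------------------------------------------------
# projection of an arbitrary warp onto the piecewise-linear family

# internal: equality-constrained least-squares projection machinery for a
# fixed partition: increments e minimize ||R e - y||^2 s.t. sum(e) = 1,
# where R holds the ramp functions of the partition on a dense grid.
# Returns T, t0 with e = T y + t0, plus the pieces needed for active-set
# refinement.
projection_operator <- function(partition, n_dense = 1000) {
  K <- length(partition) - 1
  dense <- seq(0, 1, length.out = n_dense)
  R <- vapply(seq_len(K), function(k) {
    pmin(pmax((dense - partition[k]) / (partition[k + 1] - partition[k]), 0), 1)
  }, numeric(n_dense))
  G <- solve(crossprod(R))
  g1 <- G %*% rep(1, K)
  denom <- sum(g1)
  Tmat <- (G - tcrossprod(g1) / denom) %*% t(R)
  t0 <- as.numeric(g1 / denom)
  list(K = K, dense = dense, R = R, Tmat = Tmat, t0 = t0)
}

# internal: active-set solve of min ||R e - y||^2, sum(e) = total, e >= eps
solve_simplex_ls <- function(R, y, eps, total = 1) {
  K <- ncol(R)
  active <- rep(FALSE, K)
  for (iter in seq_len(K)) {
    free <- which(!active)
    if (length(free) == 0L) break
    yr <- y - R[, active, drop = FALSE] %*% rep(eps, sum(active))
    Rf <- R[, free, drop = FALSE]
    G <- solve(crossprod(Rf))
    g1 <- G %*% rep(1, length(free))
    et <- G %*% crossprod(Rf, yr)
    tot_free <- total - eps * sum(active)
    e_free <- et - g1 * ((sum(et) - tot_free) / sum(g1))
    if (all(e_free >= eps - 1e-12)) {
      e <- rep(eps, K)
      e[free] <- as.numeric(e_free)
      return(e / sum(e) * total)
    }
    active[free[e_free < eps]] <- TRUE
  }
  e <- rep(eps, K)
  e / sum(e) * total
}

#' Project a warp onto a piecewise-linear partition
#'
#' Finds the piecewise-linear warp with knots at `partition` closest to `w`
#' in L2, by constrained least squares on a dense evaluation grid with the
#' increment-sum and positivity (`>= eps`) constraints enforced.
#'
#' @param w A warp (typically the finely sampled output of [dp_align()]).
#' @param partition Target partition (vector of knots).
#' @param eps Lower bound on increments (default `1e-4`), needed for a valid
#'   strictly increasing warp.
#' @param n_dense Size of the dense evaluation grid.
#' @return A `pl_warp` on `partition`.
#' @export
project_to_partition <- function(w, partition, eps = 1e-4, n_dense = 1000) {
  op <- projection_operator(partition, n_dense)
  y <- warp_eval(w, op$dense)
  e <- as.numeric(op$Tmat %*% y + op$t0)
  if (any(e < eps)) e <- solve_simplex_ls(op$R, y, eps)
  pl_warp(e / sum(e), partition = partition)
}

#' Karcher mean of piecewise-linear warps
#'
#' Computes the Frechet mean of a set of warps under the Fisher-Rao geometry
#' of the warping group: each warp is represented by the square root of its
#' slope, a point on the unit sphere in L2, and the intrinsic (geodesic) mean
#' is iterated from the normalized extrinsic start. The mean warp is the
#' cumulative integral of the squared mean representative. Used by the
#' centering steps that resolve template/phase non-identifiability.
#'
#' @param warps List of `pl_warp`s sharing one partition, or a matrix with
#'   one increment vector per column.
#' @param intrinsic If `FALSE`, return the (normalized) extrinsic mean
#'   directly.
#' @param max_iter,tol Iteration controls for the intrinsic mean; on
#'   non-convergence a warning is issued and the extrinsic mean returned.
#' @return A `pl_warp` on the shared partition.
#' @export
karcher_mean_warps <- function(warps, intrinsic = TRUE, max_iter = 50,
                               tol = 1e-6) {
  if (is.list(warps)) {
    if (length(warps) == 0L) stop("karcher_mean_warps: empty input", call. = FALSE)
    partition <- warps[[1]]$partition
    for (w in warps) {
      if (max(abs(w$partition - partition)) > 1e-10)
        stop("karcher_mean_warps: partitions differ", call. = FALSE)
    }
    D <- vapply(warps, function(w) w$increments,
                numeric(length(warps[[1]]$increments)))
    D <- matrix(D, ncol = length(warps))
  } else {
    D <- as.matrix(warps)
    partition <- seq(0, 1, length.out = nrow(D) + 1)
  }
  res <- karcher_incr_cpp(D, partition, max_iter, tol, intrinsic)
  if (intrinsic && !res$converged) {
    warning("karcher_mean_warps: intrinsic mean did not converge; ",
            "returning extrinsic mean")
    res <- karcher_incr_cpp(D, partition, max_iter, tol, FALSE)
  }
  pl_warp(res$increments, partition = partition)
}

# internal: Fisher-Rao distance between two warps on a shared partition
# (arc length between their sqrt-slope representatives on the sphere)
warp_fr_distance <- function(w1, w2) {
  ds <- diff(w1$partition)
  p1 <- sqrt(w1$increments / ds)
  p2 <- sqrt(w2$increments / ds)
  acos(min(1, max(-1, sum(p1 * p2 * ds))))
}
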