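# dynamic-programming elastic alignment

# internal: integer lattice steps (dx, dy) for a set of admissible slopes,
# slope 1 first so that ties break toward the identity
slope_steps <- function(slopes) {
  steps <- t(vapply(slopes, function(s) {
    # rational approximation with small denominator
    for (den in 1:12) {
      num <- s * den
      if (abs(num - round(num)) < 1e-9) return(c(den, as.integer(round(num))))
    }
    stop("dp_align: slope ", s, " has no small rational representation",
         call. = FALSE)
  }, numeric(2)))
  storage.mode(steps) <- "integer"
  ord <- order(abs(log(slopes)))  # slope 1 first
  steps[ord, , drop = FALSE]
}

#' Optimal elastic alignment by dynamic programming
#'
#' Finds the warp minimizing `|| q_ref - (q o gamma) sqrt(gamma') ||^2` over
#' monotone lattice paths on the grid whose segments have slopes in a fixed
#' admissible set. The identity path is always admissible, so the optimized
#' objective never exceeds the objective at the identity. Degenerate inputs
#' (either SRVF numerically zero) return the identity warp.
#'
#' @param q_ref,q `grid_function`s in SRVF space on the same grid; `q` is
#'   warped towards `q_ref`.
#' @param slopes Admissible segment slopes (positive rationals with small
#'   denominators).
#' @return A `grid_warp` holding the optimal warp sampled on the grid.
#' @examples
#' g <- seq(0, 1, length.out = 101)
#' q <- grid_function(g, sin(2 * pi * g), "q")
#' w <- dp_align(q, q)  # self-alignment: close to the identity
#' @export
dp_align <- function(q_ref, q,
                     slopes = c(1/4, 1/3, 1/2, 2/3, 1, 3/2, 2, 3, 4)) {
  stopifnot(inherits(q_ref, "grid_function"), inherits(q, "grid_function"))
  if (q_ref$space != "q" || q$space != "q")
    stop("dp_align: inputs must be SRVFs", call. = FALSE)
  if (length(q_ref$grid) != length(q$grid) ||
      max(abs(q_ref$grid - q$grid)) > 1e-10)
    stop("dp_align: grids differ", call. = FALSE)
  if (srvf_norm(q) < 1e-10 || srvf_norm(q_ref) < 1e-10)
    return(grid_warp(q$grid, q$grid))
  v <- dp_align_cpp(q_ref$values, q$values, q$grid, slope_steps(slopes))
  grid_warp(q$grid, v)
}
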