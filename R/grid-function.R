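#' Discretely observed function on a common grid
#'
#' A `grid_function` holds one function sampled on a fine grid over the unit
#' interval, either in the original function space (`space = "f"`) or in the
#' square-root-velocity-function space (`space = "q"`). All registration
#' machinery in the package operates on these objects.
#'
#' @param grid Numeric vector of at least 3 strictly increasing time points
#'   with `grid[1] == 0` and `grid[length(grid)] == 1`.
#' @param values Numeric vector of function values, same length as `grid`.
#' @param space `"f"` for the original space, `"q"` for SRVF space.
#' @return An object of class `grid_function`.
#' @examples
#' g <- seq(0, 1, length.out = 101)
#' f <- grid_function(g, g^2)
#' q <- to_srvf(f)
#' @export
grid_function <- function(grid, values, space = c("f", "q")) {
  space <- match.arg(space)
  grid <- as.numeric(grid)
  values <- as.numeric(values)
  M <- length(grid)
  if (M < 3) stop("grid_function: need at least 3 grid points", call. = FALSE)
  if (length(values) != M)
    stop("grid_function: values and grid lengths differ", call. = FALSE)
  if (any(diff(grid) <= 0))
    stop("grid_function: grid must be strictly increasing", call. = FALSE)
  if (abs(grid[1]) > 1e-8 || abs(grid[M] - 1) > 1e-8)
    stop("grid_function: grid must span [0, 1]", call. = FALSE)
  grid[1] <- 0; grid[M] <- 1
  if (!all(is.finite(values)))
    stop("grid_function: values must be finite", call. = FALSE)
  structure(list(grid = grid, values = values, space = space),
            class = "grid_function")
}

#' @export
print.grid_function <- function(x, ...) {
  cat(sprintf("<grid_function [%s], M = %d, range [%.3g, %.3g]>\n",
              x$space, length(x$grid), min(x$values), max(x$values)))
  invisible(x)
}

#' Square-root velocity transform
#'
#' Maps a function `f` to its SRVF `q = sign(f') sqrt(|f'|)`. The derivative
#' is approximated by central finite differences at interior grid points and
#' one-sided differences at the boundaries. Under this transform the extended
#' Fisher-Rao distance between functions becomes the ordinary L2 distance
#' between their SRVFs, which is what makes elastic registration tractable.
#'
#' @param f A `grid_function` in the original space.
#' @return A `grid_function` in SRVF space on the same grid.
#' @seealso [from_srvf()] for the inverse map.
#' @export
to_srvf <- function(f) {
  stopifnot(inherits(f, "grid_function"))
  if (f$space != "f") stop("to_srvf: input must be in the original space F", call. = FALSE)
  g <- f$grid; y <- f$values; M <- length(g)
  fdot <- numeric(M)
  fdot[1] <- (y[2] - y[1]) / (g[2] - g[1])
  fdot[M] <- (y[M] - y[M - 1]) / (g[M] - g[M - 1])
  idx <- 2:(M - 1)
  fdot[idx] <- (y[idx + 1] - y[idx - 1]) / (g[idx + 1] - g[idx - 1])
  grid_function(g, sign(fdot) * sqrt(abs(fdot)), "q")
}

#' Inverse square-root velocity transform
#'
#' Reconstructs `f(t) = f0 + int_0^t q(s) |q(s)| ds` from an SRVF and the
#' starting value, using trapezoidal quadrature; `f(0)` equals `f0` exactly.
#'
#' @param f0 Starting value `f(0)`.
#' @param q A `grid_function` in SRVF space.
#' @return A `grid_function` in the original space.
#' @export
from_srvf <- function(f0, q) {
  stopifnot(inherits(q, "grid_function"))
  if (q$space != "q") stop("from_srvf: input must be in SRVF space Q", call. = FALSE)
  grid_function(q$grid, f0 + cumtrapz(q$grid, q$values * abs(q$values)), "f")
}

#' L2 distance between two SRVFs (the eFR distance between functions)
#'
#' @param q1,q2 `grid_function`s in SRVF space on the same grid.
#' @return Non-negative scalar `sqrt(int (q1 - q2)^2 dt)` (trapezoidal).
#' @export
srvf_distance <- function(q1, q2) {
  stopifnot(inherits(q1, "grid_function"), inherits(q2, "grid_function"))
  if (length(q1$grid) != length(q2$grid) ||
      max(abs(q1$grid - q2$grid)) > 1e-10)
    stop("srvf_distance: grids differ", call. = FALSE)
  sqrt(trapz(q1$grid, (q1$values - q2$values)^2))
}

#' L2 norm of an SRVF
#' @param q A `grid_function` in SRVF space.
#' @return `sqrt(int q^2 dt)`.
#' @export
srvf_norm <- function(q) {
  sqrt(trapz(q$grid, q$values^2))
}

# internal: matrix of function columns + grid from a wide data frame
# (first column = grid, remaining columns = functions)
wide_to_matrix <- function(df) {
  df <- as.data.frame(df)
  if (ncol(df) < 2) stop("need a grid column and at least one function column", call. = FALSE)
  grid <- as.numeric(df[[1]])
  F <- as.matrix(df[-1])
  storage.mode(F) <- "double"
  list(grid = grid, F = F)
}

# internal: wide tibble from grid + matrix
matrix_to_wide <- function(grid, F, names = colnames(F)) {
  if (is.null(names)) names <- paste0("f", seq_len(ncol(F)))
  out <- tibble::as_tibble(as.data.frame(F))
  names(out) <- names
  dplyr::bind_cols(tibble::tibble(t = grid), out)
}
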