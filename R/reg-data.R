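#' Prepare a panel of functions for registration
#'
#' Takes a wide data frame (first column: grid in `[0, 1]`, one column per
#' function), validates it and computes the SRVF of each function. All model
#' fitting functions accept either the data frame or the prepared object.
#'
#' @param data Wide data frame or tibble.
#' @param srvf Optional `M x n` matrix of SRVF values to use directly instead
#'   of finite differencing. The observation model is Gaussian on SRVF
#'   values, so when data are generated (or observed) in SRVF space this
#'   avoids the differencing error that kinked warped functions incur.
#' @return An object of class `reg_data` with the grid, the function matrix
#'   `F`, the SRVF matrix `Q` and the starting values `f0`.
#' @export
reg_data <- function(data, srvf = NULL) {
  if (inherits(data, "reg_data")) return(data)
  m <- wide_to_matrix(data)
  if (any(!is.finite(m$F))) stop("reg_data: non-finite function values", call. = FALSE)
  if (any(diff(m$grid) <= 0)) stop("reg_data: grid must be strictly increasing", call. = FALSE)
  if (abs(m$grid[1]) > 1e-8 || abs(m$grid[length(m$grid)] - 1) > 1e-8)
    stop("reg_data: grid must span [0, 1]; see read_functions() for rescaling", call. = FALSE)
  grid <- m$grid; grid[1] <- 0; grid[length(grid)] <- 1
  if (is.null(srvf)) {
    Q <- vapply(seq_len(ncol(m$F)), function(i)
      to_srvf(grid_function(grid, m$F[, i], "f"))$values,
      numeric(length(grid)))
    Q <- matrix(Q, ncol = ncol(m$F))
  } else {
    Q <- as.matrix(srvf)
    if (!all(dim(Q) == dim(m$F)))
      stop("reg_data: srvf dimensions do not match the data", call. = FALSE)
  }
  structure(list(grid = grid, F = m$F, Q = Q, f0 = m$F[1, ],
                 names = colnames(m$F)),
            class = "reg_data")
}

#' @export
print.reg_data <- function(x, ...) {
  cat(sprintf("<reg_data: %d functions on %d grid points>\n",
              ncol(x$F), length(x$grid)))
  invisible(x)
}
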