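#' Cubic B-spline basis for the SRVF template
#'
#' The latent template SRVF is modelled as a linear combination of `B` cubic
#' B-spline basis functions with equally spaced knots over `[0, 1]`. `B`
#' controls how many amplitude features (local extrema) the template can
#' express; it should be large enough for the prominent features of the data
#' but not so large as to absorb noise.
#'
#' @param B Number of basis functions (`>= 4` for cubic splines).
#' @param grid Evaluation grid on `[0, 1]`.
#' @return An object of class `basis_spec` holding the `M x B` evaluation
#'   matrix `Phi` and its least-squares projector.
#' @export
basis_spec <- function(B, grid) {
  if (B < 4) stop("basis_spec: cubic B-splines need B >= 4", call. = FALSE)
  interior <- if (B > 4) seq(0, 1, length.out = B - 2)[2:(B - 3)] else numeric(0)
  knots <- c(rep(0, 4), interior, rep(1, 4))
  Phi <- splines::splineDesign(knots, grid, ord = 4)
  if (qr(Phi)$rank < B)
    stop("basis_spec: basis matrix is rank deficient on this grid", call. = FALSE)
  proj <- solve(crossprod(Phi), t(Phi))  # (Phi' Phi)^{-1} Phi'
  structure(list(B = B, grid = grid, knots = knots, Phi = Phi, proj = proj),
            class = "basis_spec")
}

#' Template SRVF from basis coefficients
#'
#' @param coef Coefficient vector of length `B`.
#' @param basis A [basis_spec()].
#' @return A `grid_function` in SRVF space: `q_mu = Phi %*% coef`.
#' @export
template_srvf <- function(coef, basis) {
  stopifnot(inherits(basis, "basis_spec"))
  if (length(coef) != basis$B)
    stop("template_srvf: coefficient length does not match basis", call. = FALSE)
  grid_function(basis$grid, as.numeric(basis$Phi %*% coef), "q")
}
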