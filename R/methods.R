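#' Tidy a particle system
#'
#' One row per particle: weight, error variance and template coefficients.
#'
#' @param x A [particle_system].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.particle_system <- function(x, ...) {
  C <- as.data.frame(x$C)
  names(C) <- paste0("c", seq_len(ncol(C)))
  dplyr::bind_cols(
    tibble::tibble(particle = seq_len(nrow(x$C)),
                   weight = particle_weights(x),
                   sigma2 = x$sigma2),
    tibble::as_tibble(C))
}

#' One-row summary of a particle system
#'
#' @param x A [particle_system].
#' @param ... Unused.
#' @return A tibble with particle count, number of assimilated functions,
#'   effective sample size, weighted mean error variance and posterior eFR
#'   variance of the template.
#' @export
glance.particle_system <- function(x, ...) {
  w <- particle_weights(x)
  tibble::tibble(J = nrow(x$C), n_functions = dim(x$D)[2], ess = ess(w),
                 sigma2_mean = sum(w * x$sigma2),
                 template_efr_var = efr_variance(x))
}

#' Plot a particle system
#'
#' Spaghetti plots of the posterior: `"template"` shows every particle's
#' template SRVF with transparency proportional to its weight, `"phase"` the
#' weighted phase particles of one function against the identity, and
#' `"ess"` the effective-sample-size trajectory across assimilations.
#'
#' @param object A [particle_system].
#' @param type One of `"template"`, `"phase"`, `"ess"`.
#' @param fun Function index for `type = "phase"`.
#' @param max_particles Subsample cap for plotting speed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.particle_system <- function(object, type = c("template", "phase", "ess"),
                                     fun = 1, max_particles = 200, ...) {
  type <- match.arg(type)
  w <- particle_weights(object)
  J <- length(w)
  keep <- if (J > max_particles)
    sort(sample.int(J, max_particles, prob = w)) else seq_len(J)
  if (type == "template") {
    Qmu <- object$basis$Phi %*% t(object$C[keep, , drop = FALSE])
    df <- tibble::tibble(
      t = rep(object$data$grid, length(keep)),
      q = as.numeric(Qmu),
      particle = rep(keep, each = length(object$data$grid)),
      weight = rep(w[keep], each = length(object$data$grid)))
    return(ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$q,
                                            group = .data$particle,
                                            alpha = .data$weight)) +
             ggplot2::geom_line() +
             ggplot2::scale_alpha(range = c(0.02, 0.5), guide = "none") +
             ggplot2::labs(x = "t", y = expression(q[mu](t)),
                           title = "Marginal posterior of the template SRVF") +
             ggplot2::theme_minimal())
  }
  if (type == "phase") {
    s <- object$partition
    K <- length(s) - 1
    Di <- matrix(object$D[, fun, keep], nrow = K)
    df <- tibble::tibble(
      t = rep(s, length(keep)),
      gamma = as.numeric(apply(Di, 2, function(d) c(0, pmin(cumsum(d), 1)))),
      particle = rep(keep, each = K + 1),
      weight = rep(w[keep], each = K + 1))
    return(ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$gamma,
                                            group = .data$particle,
                                            alpha = .data$weight)) +
             ggplot2::geom_line() +
             ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red",
                                  linetype = 2) +
             ggplot2::scale_alpha(range = c(0.05, 0.6), guide = "none") +
             ggplot2::labs(x = "t", y = expression(gamma(t)),
                           title = sprintf("Phase posterior, function %d", fun)) +
             ggplot2::theme_minimal())
  }
  df <- object$ess_log
  ggplot2::ggplot(df, ggplot2::aes(.data$n, .data$ess, colour = .data$stage)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(x = "functions assimilated", y = "ESS",
                  title = "Effective sample size per assimilation") +
    ggplot2::theme_minimal()
}
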