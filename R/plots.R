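# Quick-look plots; all return ggplot objects the caller can restyle.

#' Plot a density profile
#'
#' Log-density versus height, the standard view in which an exponential
#' sedimentation profile is a straight line of slope \eqn{-1/\lambda}.
#'
#' @param object A `density_profile`.
#' @param log Use a log y-scale (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.density_profile <- function(object, log = TRUE, ...) {
  d <- dplyr::filter(tibble::as_tibble(object), .data$rho > 0)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$z, y = .data$rho)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "z", y = expression(rho(z)))
  if (log) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a velocity-fluctuation profile
#' @param object A `fluctuation_profile`.
#' @param ... Unused.
#' @export
autoplot.fluctuation_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$z, y = .data$sigma2)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z", y = expression(sigma^2 * (z)))
}

#' Plot joint elevation-orientation statistics
#'
#' Colour map of \eqn{P(z, \hat e_z)}.
#'
#' @param object An `orientation_stats`.
#' @param ... Unused.
#' @export
autoplot.orientation_stats <- function(object, ...) {
  ggplot2::ggplot(object$joint,
                  ggplot2::aes(x = .data$ez, y = .data$z, fill = .data$p)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = expression(hat(e)[z]), y = "z",
                  fill = expression(P(z, hat(e)[z])))
}

#' Plot the mean-height series of a run
#'
#' \eqn{h(t)} with the detected steady window shaded, the diagnostic used to
#' declare a statistically steady state.
#'
#' @param run An `rtp_run` or `lb_run`.
#' @param window,tol Passed to [detect_steady_state()]; `window` defaults to
#'   ten run times.
#' @return A ggplot.
#' @export
plot_h_series <- function(run, window = 10 * run$params$tau, tol = 0.05) {
  ss <- detect_steady_state(run$h_series, window = window, tol = tol)
  p <- ggplot2::ggplot(run$h_series, ggplot2::aes(x = .data$t, y = .data$h)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "t", y = "h(t)")
  if (ss$converged)
    p <- p + ggplot2::annotate("rect", xmin = ss$start, xmax = ss$end,
                               ymin = -Inf, ymax = Inf, alpha = 0.15)
  p
}

#' @importFrom rlang .data
NULL
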