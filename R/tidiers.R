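#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a sedimentation-length fit
#'
#' @param x A `sed_fit` from [fit_sedimentation_length()].
#' @param ... Unused.
#' @return A one-row tibble with `term`, `estimate`, `std.error`.
#' @export
tidy.sed_fit <- function(x, ...) {
  tibble::tibble(term = "lambda", estimate = x$lambda, std.error = x$se)
}

#' @rdname tidy.sed_fit
#' @export
glance.sed_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, std.error = x$se,
                 r.squared = x$r_squared, n.bins = x$n_bins,
                 fit.lo = x$fit_range[1], fit.hi = x$fit_range[2],
                 exponential.ok = x$ok)
}

#' Tidy an effective-temperature constant fit
#'
#' @param x An `alpha_fit` from [fit_alpha()].
#' @param ... Unused.
#' @export
tidy.alpha_fit <- function(x, ...) {
  tibble::tibble(term = "alpha", estimate = x$alpha)
}

#' @rdname tidy.alpha_fit
#' @export
glance.alpha_fit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, residual = x$residual,
                 n.bins = x$n_bins, mode = x$mode)
}
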