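#' Synthetic or measured fluid velocity-fluctuation profile
#'
#' Wraps a tabulated profile of fluid velocity fluctuations
#' \eqn{\sigma^2(z)} (slab variance of the fluid velocity about the slab
#' mean) into the tibble consumed by the effective-temperature solver.
#'
#' @param z Strictly increasing height grid.
#' @param sigma2 Non-negative fluctuation values, same length as `z`.
#' @param source `"simulated"` or `"synthetic"` provenance tag.
#' @return A tibble `(z, sigma2)` of class `fluctuation_profile` with a
#'   `source` attribute.
#' @export
fluctuation_profile <- function(z, sigma2, source = c("synthetic", "simulated")) {
  source <- match.arg(source)
  stopifnot(length(z) == length(sigma2), length(z) >= 2,
            all(diff(z) > 0), all(is.finite(sigma2)))
  if (any(sigma2 < 0)) stop("sigma2 must be non-negative everywhere")
  out <- tibble::tibble(z = as.numeric(z), sigma2 = as.numeric(sigma2))
  class(out) <- c("fluctuation_profile", class(out))
  attr(out, "source") <- source
  out
}

#' Height-dependent effective sedimentation length
#'
#' Builds the local sedimentation length \eqn{\lambda_{eff}(z) =
#' k_B T_{eff}(z)/F_g} entering the steady Smoluchowski balance, from a
#' velocity-fluctuation profile \eqn{\sigma^2(z)}. The effective temperature
#' has a single-particle part (self-propulsion) and a collective part
#' proportional to the fluid agitation:
#' \itemize{
#'   \item swimmer mode: \eqn{\lambda_{eff}(z) = \lambda_{1p}\,(1 +
#'     \alpha_1\,\sigma^2(z)/v_p^2)}, reducing to the bare exponential when
#'     \eqn{\sigma^2 \to 0};
#'   \item shaker mode: the single-particle part vanishes (\eqn{v_p = 0}) and
#'     \eqn{\lambda_{eff}(z) = \alpha_2\,\ell_T\,\sigma^2(z)/v_{B2}^2}, where
#'     `ell_T` is the reference length converting the dimensionless
#'     collective temperature into a local length (default the particle
#'     radius).
#' }
#'
#' The profile is interpolated onto `grid` piecewise-linearly;
#' beyond the measured range values are held constant and the result is
#' flagged (`extrapolated` attribute).
#'
#' @param fluct A [fluctuation_profile()] (any data frame with `z`, `sigma2`).
#' @param mode `"swimmer"` or `"shaker"`.
#' @param alpha Free proportionality constant (\eqn{\alpha_1} or
#'   \eqn{\alpha_2}).
#' @param v_ref Reference speed: \eqn{v_p} (swimmer) or \eqn{v_{B2}} (shaker),
#'   `> 0`.
#' @param lambda_1p Single-particle sedimentation length (swimmer mode,
#'   `> 0`); see [sedimentation_length_theory()].
#' @param ell_T Reference length for the shaker collective temperature.
#' @param grid Height grid for the output (default the profile's own grid).
#' @return A tibble `(z, lambda_eff)` of class `lambda_eff_profile` with
#'   attributes `mode`, `alpha`, `lambda_1p`, `v_ref`, `ell_T`, `degenerate`
#'   (`TRUE` when the shaker profile has \eqn{\lambda_{eff} = 0} regions).
#' @export
lambda_eff_profile <- function(fluct, mode = c("swimmer", "shaker"),
                               alpha = 1, v_ref, lambda_1p = NULL,
                               ell_T = 1, grid = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(v_ref), v_ref > 0, alpha >= 0, ell_T > 0)
  if (mode == "swimmer" && (is.null(lambda_1p) || lambda_1p <= 0))
    stop("swimmer mode requires lambda_1p > 0")
  z_out <- if (is.null(grid)) fluct$z else sort(grid)
  s2 <- approx(fluct$z, fluct$sigma2, xout = z_out, rule = 2)$y
  extrapolated <- any(z_out < min(fluct$z)) || any(z_out > max(fluct$z))
  lam <- if (mode == "swimmer") {
    lambda_1p * (1 + alpha * s2 / v_ref^2)
  } else {
    alpha * ell_T * s2 / v_ref^2
  }
  degenerate <- mode == "shaker" && any(lam == 0)
  if (mode == "shaker" && all(lam == 0))
    warning("shaker mode with sigma2 identically zero: gravitational collapse (lambda_eff = 0)")
  out <- tibble::tibble(z = z_out, lambda_eff = lam)
  class(out) <- c("lambda_eff_profile", class(out))
  attr(out, "mode") <- mode
  attr(out, "alpha") <- alpha
  attr(out, "lambda_1p") <- lambda_1p
  attr(out, "v_ref") <- v_ref
  attr(out, "ell_T") <- ell_T
  attr(out, "degenerate") <- degenerate
  attr(out, "extrapolated") <- extrapolated
  out
}

#' Steady sedimentation profile from the zero-flux Smoluchowski balance
#'
#' In steady state the vertical flux \eqn{J = -\tilde D\,\partial_z\rho -
#' \tilde\mu F_g \rho} vanishes at the walls and hence everywhere, giving
#' \deqn{\rho(z) = C\,\exp\left(-\int_0^z \frac{dz'}{\lambda_{eff}(z')}\right),}
#' with \eqn{\lambda_{eff} = \tilde D/(\tilde\mu F_g)} the local
#' effective-temperature length and \eqn{C} fixed by normalisation
#' \eqn{\int_0^H \rho\,dz = 1}. The cumulative integral is evaluated by the
#' trapezoid rule on the supplied grid; \eqn{\lambda_{eff}} is floored at
#' `floor_eps` to keep the integral finite across shaker dead zones (the
#' result is flagged `degenerate` when the floor was active).
#'
#' @param lam A [lambda_eff_profile()] (any data frame with `z`,
#'   `lambda_eff`) covering the full height.
#' @param floor_eps Lower floor on \eqn{\lambda_{eff}}; default
#'   `1e-6 * diff(range(z))`.
#' @return A tibble `(z, rho)` of class `density_profile` with attributes
#'   `h` (mean height \eqn{\int z\rho\,dz}), `H`, `floor_eps`, `degenerate`.
#' @examples
#' z <- seq(0, 80, by = 0.5)
#' lam <- tibble::tibble(z = z, lambda_eff = rep(10, length(z)))
#' rho <- steady_density(lam)
#' attr(rho, "h")   # ~10 for H >> lambda
#' @export
steady_density <- function(lam, floor_eps = NULL) {
  z <- lam$z
  stopifnot(length(z) >= 2, all(diff(z) > 0))
  H <- diff(range(z))
  if (is.null(floor_eps)) floor_eps <- 1e-6 * H
  le <- pmax(lam$lambda_eff, floor_eps)
  degenerate <- any(lam$lambda_eff < floor_eps)
  I <- pracma::cumtrapz(z, 1 / le)[, 1]
  lrho <- -I
  rho <- exp(lrho - max(lrho))           # stabilised before normalisation
  Z <- pracma::trapz(z, rho)
  if (!is.finite(Z) || Z <= 0) stop("degenerate profile: normalisation failed")
  rho <- rho / Z
  out <- tibble::tibble(z = z, rho = rho)
  class(out) <- c("density_profile", class(out))
  attr(out, "h") <- pracma::trapz(z, z * rho)
  attr(out, "H") <- max(z)
  attr(out, "floor_eps") <- floor_eps
  attr(out, "degenerate") <- degenerate
  out
}

#' Fit the effective-temperature proportionality constant
#'
#' Least-squares estimate of the free parameter \eqn{\alpha} (\eqn{\alpha_1}
#' for swimmers, \eqn{\alpha_2} for shakers) by matching the model profile
#' [steady_density()] built from a measured \eqn{\sigma^2(z)} to an observed
#' density profile, minimising
#' \eqn{\sum_i (\ln\rho_{model}(z_i) - \ln\rho_{obs}(z_i))^2} over the bins
#' in `fit_range` with \eqn{\rho_{obs}} above `rho_floor`.
#'
#' @param observed A density profile (data frame with `z`, `rho`).
#' @param fluct A [fluctuation_profile()] on a compatible height range.
#' @param mode,v_ref,lambda_1p,ell_T As in [lambda_eff_profile()].
#' @param fit_range Height interval `c(lo, hi)` used in the fit (default the
#'   full observed range).
#' @param rho_floor Bins with observed density at or below this are excluded.
#' @param alpha_max Upper end of the search bracket.
#' @return An object of class `alpha_fit`: list with `alpha`, `residual`
#'   (sum of squared log-residuals), `n_bins`, `mode`, and the model profile
#'   at the fitted alpha. Has [tidy()] and [glance()] methods.
#' @examples
#' z <- seq(0, 80, by = 0.5)
#' fl <- fluctuation_profile(z, 0.5 * exp(-z / 20))
#' lam <- lambda_eff_profile(fl, "shaker", alpha = 4.4, v_ref = 1, ell_T = 1)
#' obs <- steady_density(lam)
#' fit_alpha(obs, fl, mode = "shaker", v_ref = 1, ell_T = 1)$alpha  # ~4.4
#' @export
fit_alpha <- function(observed, fluct, mode = c("swimmer", "shaker"),
                      v_ref, lambda_1p = NULL, ell_T = 1,
                      fit_range = NULL, rho_floor = 0, alpha_max = 100) {
  mode <- match.arg(mode)
  if (is.null(fit_range)) fit_range <- range(observed$z)
  sel <- observed$z >= fit_range[1] & observed$z <= fit_range[2] &
    observed$rho > rho_floor
  if (sum(sel) < 5)
    stop("fewer than 5 usable bins in fit_range; widen the range or lower rho_floor")
  z_obs <- observed$z[sel]
  lrho_obs <- log(observed$rho[sel])
  obj <- function(a) {
    lam <- lambda_eff_profile(fluct, mode, alpha = a, v_ref = v_ref,
                              lambda_1p = lambda_1p, ell_T = ell_T)
    rho_m <- suppressWarnings(steady_density(lam))
    lrho_m <- approx(rho_m$z, log(rho_m$rho), xout = z_obs, rule = 2)$y
    sum((lrho_m - lrho_obs)^2)
  }
  opt <- optimize(obj, interval = c(0, alpha_max), tol = 1e-8)
  # refine around the optimum (optimize() on a wide bracket can be coarse)
  lo <- max(0, opt$minimum * 0.8); hi <- min(alpha_max, opt$minimum * 1.25 + 1e-6)
  opt <- optimize(obj, interval = c(lo, hi), tol = 1e-10)
  lam <- lambda_eff_profile(fluct, mode, alpha = opt$minimum, v_ref = v_ref,
                            lambda_1p = lambda_1p, ell_T = ell_T)
  structure(
    list(alpha = opt$minimum, residual = opt$objective, n_bins = sum(sel),
         mode = mode, model = suppressWarnings(steady_density(lam)),
         fit_range = fit_range),
    class = "alpha_fit"
  )
}

#' @export
print.alpha_fit <- function(x, ...) {
  cat(sprintf("<alpha_fit> mode = %s: alpha = %.4g (residual %.3g over %d bins)\n",
              x$mode, x$alpha, x$residual, x$n_bins))
  invisible(x)
}
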