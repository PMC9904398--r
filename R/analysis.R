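#' Normalised particle density profile along the gravity axis
#'
#' Histograms particle-centre heights into half-open bins \eqn{[z, z+\Delta z)}
#' covering \eqn{[0, H]} and normalises so that \eqn{\int_0^H \rho\,dz = 1}
#' (\eqn{\rho(z)dz} is the probability of finding a particle centred between
#' \eqn{z} and \eqn{z + dz}).
#'
#' @param data A data frame with a `z` column (e.g. one snapshot, or many
#'   pooled steady-state snapshots, of a trajectory tibble), or a numeric
#'   vector of heights.
#' @param H Box height; bins cover `[0, H]`.
#' @param bin_width Bin width \eqn{\Delta z} (default `H/160`, i.e. `R/2`
#'   for the standard `H = 80R` box).
#' @return A tibble `(z, rho, count)` of class `density_profile` (`z` is the
#'   bin midpoint) with attributes `H`, `dz`, `n` (total observations), `h`
#'   (mean height \eqn{\int z\rho\,dz} computed from the raw samples).
#' @export
density_profile <- function(data, H, bin_width = H / 160) {
  z <- if (is.data.frame(data)) data$z else as.numeric(data)
  if (length(z) == 0) stop("empty input: no particle heights to bin")
  stopifnot(H > 0, bin_width > 0)
  breaks <- seq(0, H, by = bin_width)
  if (tail(breaks, 1) < H) breaks <- c(breaks, H)
  idx <- pmin(findInterval(z, breaks, rightmost.closed = TRUE), length(breaks) - 1L)
  count <- tabulate(idx, nbins = length(breaks) - 1L)
  dz <- diff(breaks)
  rho <- count / (sum(count) * dz)
  out <- tibble::tibble(z = (head(breaks, -1) + tail(breaks, -1)) / 2,
                        rho = rho, count = count)
  class(out) <- c("density_profile", class(out))
  attr(out, "H") <- H
  attr(out, "dz") <- bin_width
  attr(out, "n") <- length(z)
  attr(out, "h") <- mean(z)
  out
}

#' Mean height of a density profile
#'
#' \eqn{h = \int_0^H z\,\rho(z)\,dz}, by the trapezoid rule (or exactly from
#' the raw samples when the profile carries them).
#'
#' @param profile A `density_profile`.
#' @return The mean height.
#' @export
mean_height <- function(profile) {
  h <- attr(profile, "h", exact = TRUE)
  if (!is.null(h)) return(h)
  pracma::trapz(profile$z, profile$z * profile$rho)
}

#' Detect the statistically steady state from the mean-height series
#'
#' The run is considered statistically steady over the longest final time
#' interval on which the mean height \eqn{h(t)} fluctuates by less than
#' `tol` about its mean: the earliest start \eqn{t^*} such that
#' \eqn{\max_t |h(t) - \bar h| / \bar h < tol} over all \eqn{t \ge t^*}. A
#' minimum interval length `window` (in time units) is required for the
#' verdict.
#'
#' @param h_series A tibble/data frame with columns `t` and `h` (e.g. the
#'   `h_series` of a simulation run), time-ordered.
#' @param window Minimum steady-interval duration.
#' @param tol Relative fluctuation tolerance (default 0.05, i.e. 5%).
#' @return A list with `converged` (logical), `start`, `end` (times; `NA` if
#'   not converged) and `n_samples` in the steady interval.
#' @export
detect_steady_state <- function(h_series, window, tol = 0.05) {
  t <- h_series$t; h <- h_series$h
  stopifnot(length(t) == length(h), !is.unsorted(t))
  n <- length(h)
  # suffix criterion via reverse cumulative extrema and means
  rev_mean <- rev(cumsum(rev(h))) / (n - seq_len(n) + 1L)
  rev_max <- rev(cummax(rev(h)))
  rev_min <- rev(cummin(rev(h)))
  ok <- pmax(rev_max - rev_mean, rev_mean - rev_min) / rev_mean < tol
  starts <- which(ok & (t[n] - t) >= window)
  if (!length(starts))
    return(list(converged = FALSE, start = NA_real_, end = NA_real_, n_samples = 0L))
  i0 <- min(starts)
  list(converged = TRUE, start = t[i0], end = t[n], n_samples = n - i0 + 1L)
}

#' Fit the sedimentation length of an exponential density profile
#'
#' Weighted linear least squares of \eqn{\ln\rho} on \eqn{z} over the chosen
#' fit range; the sedimentation length is \eqn{\lambda = -1/\mathrm{slope}}.
#' Bins are weighted by their counts when available (Poisson weighting of the
#' log-density). The default range starts at `4R` — excluding the
#' crystalline layers that form against the bottom wall — and ends at the
#' last bin with at least `min_count` observations.
#'
#' @param profile A `density_profile` (binned, with counts, or a model
#'   profile with `rho` only).
#' @param fit_range Optional `c(lo, hi)` height interval.
#' @param R Particle radius, used for the default lower bound `4R`.
#' @param min_count Count floor defining the default upper bound and the
#'   usable bins (ignored for count-free model profiles).
#' @return An object of class `sed_fit`: list with `lambda`, `se` (standard
#'   error of lambda via error propagation from the slope), `r_squared`,
#'   `n_bins`, `fit_range`, `ok` (`FALSE`, with the value still returned,
#'   when \eqn{R^2 < 0.9}: the profile is not a single exponential), and
#'   `data` (the bins used). Has [tidy()] and [glance()] methods.
#' @examples
#' z <- seq(0.25, 80, by = 0.5)
#' prof <- tibble::tibble(z = z, rho = exp(-z / 10) / 10, count = rep(100, length(z)))
#' class(prof) <- c("density_profile", class(prof))
#' fit_sedimentation_length(prof, R = 1)$lambda  # 10
#' @export
fit_sedimentation_length <- function(profile, fit_range = NULL, R = 1,
                                     min_count = 10) {
  has_counts <- "count" %in% names(profile)
  if (is.null(fit_range)) {
    hi <- if (has_counts && any(profile$count >= min_count))
      max(profile$z[profile$count >= min_count]) else max(profile$z)
    fit_range <- c(4 * R, hi)
  }
  d <- profile[profile$z >= fit_range[1] & profile$z <= fit_range[2] &
                 profile$rho > 0, ]
  if (has_counts) d <- d[d$count >= 1, ]
  if (nrow(d) < 5)
    stop("fewer than 5 usable bins in the fit range")
  w <- if (has_counts) d$count else rep(1, nrow(d))
  fit <- lm(log(rho) ~ z, data = d, weights = w)
  slope <- coef(fit)[["z"]]
  se_slope <- summary(fit)$coefficients["z", "Std. Error"]
  r2 <- summary(fit)$r.squared
  if (slope >= 0)
    warning("non-decaying profile: fitted slope is non-negative")
  lambda <- -1 / slope
  structure(
    list(lambda = lambda, se = se_slope / slope^2, r_squared = r2,
         n_bins = nrow(d), fit_range = fit_range, ok = r2 >= 0.9,
         data = tibble::as_tibble(d), fit = fit),
    class = "sed_fit"
  )
}

#' @export
print.sed_fit <- function(x, ...) {
  cat(sprintf("<sed_fit> lambda = %.4g +/- %.2g (R^2 = %.3f, %d bins%s)\n",
              x$lambda, x$se, x$r_squared, x$n_bins,
              if (x$ok) "" else "; WARNING: poor exponential fit"))
  invisible(x)
}

#' Detect near-wall crystalline layering
#'
#' At low propulsion/gravity ratio the sediment orders into layers: the
#' density profile develops regularly spaced peaks near the bottom wall,
#' displaced by about one particle diameter (\eqn{2R}). This finds local
#' maxima of \eqn{\rho} below `z_max` whose prominence over the neighbouring
#' minima exceeds `prominence` times the global maximum, and reports their
#' spacings.
#'
#' @param profile A `density_profile` with bin width below `R/2` near the
#'   wall.
#' @param R Particle radius.
#' @param z_max Search region (default `10R`).
#' @param prominence Relative prominence threshold (default 0.05).
#' @param min_sep Minimum separation between reported peaks (default `R`:
#'   layers cannot sit closer than one radius); of two closer maxima the
#'   higher one is kept.
#' @return A list with `peaks` (heights of the detected maxima), `spacing`
#'   (successive differences; empty when fewer than 2 peaks) and
#'   `mean_spacing` (`NA` when undefined).
#' @export
detect_layering <- function(profile, R, z_max = 10 * R, prominence = 0.05,
                            min_sep = R) {
  d <- profile[profile$z <= z_max, ]
  rho <- d$rho; z <- d$z
  n <- length(rho)
  if (n < 3) return(list(peaks = numeric(0), spacing = numeric(0), mean_spacing = NA_real_))
  thr <- prominence * max(profile$rho)
  peaks <- numeric(0)
  for (i in 2:(n - 1)) {
    if (rho[i] > rho[i - 1] && rho[i] >= rho[i + 1]) {
      # prominence: drop to the lower of the two flanking minima
      left_min <- min(rho[1:(i - 1)][cummax(rho[1:(i - 1)]) <= rho[i]], rho[i - 1])
      right_min <- min(rho[(i + 1):n], na.rm = TRUE)
      if (rho[i] - max(min(left_min, right_min), 0) >= thr)
        peaks <- c(peaks, z[i])
    }
  }
  if (length(peaks) >= 2) {
    # enforce minimum separation, keeping the higher of two close maxima
    heights <- rho[match(peaks, z)]
    keep <- order(heights, decreasing = TRUE)
    chosen <- numeric(0)
    for (i in keep)
      if (!length(chosen) || all(abs(peaks[i] - chosen) >= min_sep))
        chosen <- c(chosen, peaks[i])
    peaks <- sort(chosen)
  }
  spacing <- if (length(peaks) >= 2) diff(peaks) else numeric(0)
  list(peaks = peaks, spacing = spacing,
       mean_spacing = if (length(spacing)) mean(spacing) else NA_real_)
}

#' Supernatant metrics of a sedimentation profile
#'
#' Pullers and positive-activity shakers can develop a distal region of
#' roughly constant density — a supernatant floating above the sediment.
#' This measures:
#' \itemize{
#'   \item `zeta0`: the minimum height above which the density stays below
#'     `density_floor` (the top of the occupied region);
#'   \item `plateau`: the maximal distal interval below `zeta0` where the
#'     density is above the floor and locally flat, \eqn{|d\ln\rho/dz| <}
#'     `slope_tol` (the log-slope criterion distinguishes a true shelf,
#'     where it vanishes, from the tail of an exponential, where it is the
#'     constant \eqn{1/\lambda});
#'   \item `X_sn`: the particle fraction in the plateau,
#'     \eqn{\int_{plateau}\rho\,dz} (0 when no plateau exists).
#' }
#'
#' @param profile A normalised `density_profile`.
#' @param slope_tol Log-slope flatness threshold; default 10% of the mean
#'   \eqn{|d\ln\rho/dz|} over the occupied range (when that mean is zero —
#'   a uniform profile — the whole occupied range counts as plateau).
#' @param density_floor Density below which a bin counts as empty; default
#'   one tenth of a single observation's bin weight, `1/(10 n dz)`, falling
#'   back to `1e-4 * max(rho)` for count-free model profiles.
#' @param min_bins Minimum plateau length in bins (default 3).
#' @return A list with `zeta0`, `plateau` (`c(lo, hi)` or `NULL`), `X_sn`.
#' @export
supernatant_metrics <- function(profile, slope_tol = NULL, density_floor = NULL,
                                min_bins = 3L) {
  z <- profile$z; rho <- profile$rho
  n_obs <- attr(profile, "n", exact = TRUE)
  dz <- attr(profile, "dz", exact = TRUE) %||% mean(diff(z))
  if (is.null(density_floor)) {
    density_floor <- if (!is.null(n_obs)) 1 / (10 * n_obs * dz) else 1e-4 * max(rho)
  }
  occupied <- rho >= density_floor
  if (!any(occupied))
    return(list(zeta0 = 0, plateau = NULL, X_sn = 0))
  i_top <- max(which(occupied))
  zeta0 <- if (i_top == length(z)) attr(profile, "H", exact = TRUE) %||% max(z)
           else z[i_top] + dz / 2
  # log-slope on occupied bins
  lr <- log(pmax(rho, .Machine$double.xmin))
  dlog <- abs(c(diff(lr) / diff(z), NA))
  occ_idx <- which(occupied)
  mean_slope <- mean(dlog[occ_idx[-length(occ_idx)]], na.rm = TRUE)
  if (is.null(slope_tol)) {
    slope_tol <- 0.1 * mean_slope
    if (!is.finite(slope_tol) || slope_tol == 0) slope_tol <- 1e-12
  }
  flat <- occupied & (dlog <= slope_tol | (is.na(dlog) & occupied))
  flat[is.na(flat)] <- FALSE
  # maximal distal run of flat bins at or below i_top
  runs <- rle(flat[seq_len(i_top)])
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values & runs$lengths >= min_bins)
  if (!length(cand))
    return(list(zeta0 = zeta0, plateau = NULL, X_sn = 0))
  k <- max(cand)   # distal-most
  # require the plateau to reach the top of the occupied region (a shelf,
  # not a flat patch buried inside the sediment)
  if (ends[k] < i_top - 1L)
    return(list(zeta0 = zeta0, plateau = NULL, X_sn = 0))
  lo <- z[starts[k]] - dz / 2; hi <- z[ends[k]] + dz / 2
  sel <- seq(starts[k], ends[k])
  X_sn <- sum(rho[sel]) * dz
  list(zeta0 = zeta0, plateau = c(lo, hi), X_sn = min(X_sn, 1))
}

#' Joint elevation-orientation statistics
#'
#' Estimates the joint probability density \eqn{P(z, \hat e_z)} of particle
#' elevation and the vertical component of the orientation vector, normalised
#' so \eqn{\sum P\,\Delta z\,\Delta\hat e_z = 1}, together with the
#' conditional orientation PDFs \eqn{P(z^*, \hat e_z)/\rho(z^*)} at requested
#' heights and the polar-order profile \eqn{m(z) = \langle \hat e_z\rangle_z}.
#' Sedimenting run-and-tumble suspensions at long run length develop a
#' height-dependent polar order: downward-oriented particles are
#' over-represented near the bottom wall while in the bulk particles
#' preferentially swim upwards.
#'
#' @param data A data frame with columns `z` and `ez` (e.g. pooled
#'   steady-state snapshots of a trajectory tibble).
#' @param H Box height.
#' @param bin_width Elevation bin width.
#' @param e_bins Number of \eqn{\hat e_z} bins over \eqn{[-1, 1]}.
#' @param z_stars Heights at which to extract conditional orientation PDFs.
#' @return An object of class `orientation_stats`: list with
#'   \item{joint}{tibble `(z, ez, p)` — the joint density on the bin grid;}
#'   \item{conditionals}{tibble `(z_star, ez, p, missing)`;}
#'   \item{polar_order}{tibble `(z, m, count)`;}
#'   \item{marginal_z}{tibble `(z, rho)` — marginal over orientation, equal
#'     bin-for-bin to [density_profile()] of the same data.}
#' @export
orientation_statistics <- function(data, H, bin_width = H / 160, e_bins = 20L,
                                   z_stars = numeric(0)) {
  stopifnot(all(c("z", "ez") %in% names(data)))
  z <- data$z; ez <- pmin(pmax(data$ez, -1), 1)
  zb <- seq(0, H, by = bin_width)
  if (tail(zb, 1) < H) zb <- c(zb, H)
  eb <- seq(-1, 1, length.out = e_bins + 1L)
  iz <- pmin(findInterval(z, zb, rightmost.closed = TRUE), length(zb) - 1L)
  ie <- pmin(findInterval(ez, eb, rightmost.closed = TRUE), e_bins)
  cnt <- matrix(0, nrow = length(zb) - 1L, ncol = e_bins)
  for (k in seq_along(iz)) cnt[iz[k], ie[k]] <- cnt[iz[k], ie[k]] + 1
  dz <- diff(zb); de <- diff(eb)[1]
  P <- cnt / (sum(cnt) * outer(dz, rep(de, e_bins)))
  zmid <- (head(zb, -1) + tail(zb, -1)) / 2
  emid <- (head(eb, -1) + tail(eb, -1)) / 2
  joint <- tibble::tibble(
    z = rep(zmid, times = e_bins),
    ez = rep(emid, each = length(zmid)),
    p = as.vector(P)
  )
  conds <- purrr::map_dfr(z_stars, function(zs) {
    i <- pmin(findInterval(zs, zb, rightmost.closed = TRUE), length(zb) - 1L)
    row <- cnt[i, ]
    if (sum(row) == 0)
      return(tibble::tibble(z_star = zs, ez = emid, p = NA_real_, missing = TRUE))
    tibble::tibble(z_star = zs, ez = emid, p = row / (sum(row) * de),
                   missing = FALSE)
  })
  rowc <- rowSums(cnt)
  polar <- tibble::tibble(
    z = zmid,
    m = ifelse(rowc > 0, as.vector(cnt %*% emid) / rowc, NA_real_),
    count = rowc
  )
  marg <- tibble::tibble(z = zmid, rho = rowc / (sum(cnt) * dz))
  structure(list(joint = joint, conditionals = conds, polar_order = polar,
                 marginal_z = marg, H = H, dz = bin_width, de = de),
            class = "orientation_stats")
}

#' @export
print.orientation_stats <- function(x, ...) {
  cat(sprintf("<orientation_stats> %d z-bins x %d ez-bins; %d conditionals\n",
              length(unique(x$joint$z)), length(unique(x$joint$ez)),
              length(unique(x$conditionals$z_star))))
  invisible(x)
}
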