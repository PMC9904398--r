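#' Draw random tumble orientations
#'
#' Resamples orientation unit vectors after a tumble. `sphere_uniform` draws
#' uniformly on the unit sphere (isotropic); `polar_uniform` draws the polar
#' angle uniformly on \eqn{[0, \pi]} and the azimuth uniformly on
#' \eqn{[0, 2\pi)}. Both modes fully decorrelate the run direction
#' (\eqn{\langle \hat e_{before}\cdot\hat e_{after}\rangle = 0}); they differ
#' in the marginal distribution of \eqn{\hat e_z} (uniform vs
#' arcsine-weighted).
#'
#' @param n Number of orientations to draw.
#' @param mode `"sphere_uniform"` or `"polar_uniform"`.
#' @return An `n x 3` matrix of unit vectors.
#' @export
tumble_orientation <- function(n, mode = c("sphere_uniform", "polar_uniform")) {
  mode <- match.arg(mode)
  if (n == 0L) return(matrix(numeric(0), 0, 3))
  if (mode == "sphere_uniform") {
    ez <- runif(n, -1, 1)
    phi <- runif(n, 0, 2 * pi)
    s <- sqrt(pmax(0, 1 - ez^2))
    cbind(s * cos(phi), s * sin(phi), ez)
  } else {
    th <- runif(n, 0, pi)
    phi <- runif(n, 0, 2 * pi)
    cbind(sin(th) * cos(phi), sin(th) * sin(phi), cos(th))
  }
}

#' Waiting times to the next tumble
#'
#' `poisson` draws exponential waiting times with mean `tau`; with
#' `fixed_interval` every waiting time is exactly `tau` (tumbles fall at
#' multiples of `tau`). The two protocols give run-and-tumble diffusivities
#' differing by a factor two (\eqn{v_p^2\tau/3} vs \eqn{v_p^2\tau/6}).
#'
#' @param n Number of waiting times.
#' @param tau Mean (or exact) run duration.
#' @param mode `"poisson"` or `"fixed_interval"`.
#' @return Numeric vector of length `n`.
#' @export
tumble_waiting_times <- function(n, tau, mode = c("poisson", "fixed_interval")) {
  mode <- match.arg(mode)
  stopifnot(tau > 0)
  if (mode == "poisson") rexp(n, rate = 1 / tau) else rep(tau, n)
}

#' Simulate dry run-and-tumble sedimentation
#'
#' Integrates `N` non-interacting run-and-tumble point particles that
#' self-propel at \eqn{v_p} along their orientation \eqn{\hat e} and settle at
#' \eqn{v_g = \mu F_g} along \eqn{-z}:
#' \deqn{\dot X = v_p \hat e - v_g \hat z,}
#' with tumbles per the swimmer's tumble settings. The box is periodic in
#' `x, y`; in `z` it either has reflecting walls at `0` and `H` (positions
#' specularly reflected, orientations unchanged) or is periodic
#' (`periodic_z = TRUE`, used with `Fg = 0` for diffusivity estimation).
#' There is no hydrodynamics, no excluded volume and no thermal noise: this
#' is the analytic reference model whose steady profile is exponential with
#' \eqn{\lambda = v_p^2\tau/(3 v_g)} (Poisson tumbling, \eqn{\chi_1 \gg 1}).
#'
#' @param params A [swimmer_params()].
#' @param env A [fluid_environment()].
#' @param box A [box_geometry()].
#' @param dt Time step; must satisfy `dt < tau/10` and `v_p*dt < R`.
#' @param n_steps Number of steps to integrate.
#' @param record_stride Record a trajectory snapshot every this many steps.
#' @param periodic_z Use periodic `z` instead of walls (requires `Fg = 0`).
#' @param init Optional list with matrices `X` (`N x 3`) and `E` (`N x 3`)
#'   to continue a run; defaults to uniform positions, isotropic orientations.
#' @param unwrap Keep unwrapped coordinates (for mean-square-displacement
#'   analysis). Default `periodic_z`.
#' @return An object of class `rtp_run` with elements:
#'   \item{trajectory}{tibble `(t, id, x, y, z, ex, ey, ez)` at the recorded
#'     strides (unwrapped coordinates if `unwrap`).}
#'   \item{h_series}{tibble `(t, h)` of the mean height at every step.}
#'   \item{state}{final `X`, `E`, `next_tumble`, `t`.}
#'   \item{params, env, box, dt}{the inputs.}
#' @examples
#' sw <- swimmer_params(B1 = 1.5, R = 1, tau = 4.3)      # v_p = 1
#' env <- fluid_environment(eta = 1 / (6 * pi), Fg = 0.1) # v_g = 0.1
#' box <- box_geometry(L = 20, H = 60, R = 1, N = 50)
#' set.seed(1)
#' run <- simulate_rtp(sw, env, box, dt = 0.2, n_steps = 500)
#' @export
simulate_rtp <- function(params, env, box, dt, n_steps,
                         record_stride = 10L, periodic_z = FALSE,
                         init = NULL, unwrap = periodic_z) {
  v_p <- swim_speed(params)
  v_g <- settling_speed(env, params$R)
  if (dt >= params$tau / 10)
    stop("dt must be < tau/10 to resolve the run-and-tumble dynamics")
  if (v_p * dt >= params$R && v_p > 0)
    stop("v_p * dt must be < R (displacement per step under one radius)")
  if (periodic_z && env$Fg > 0)
    stop("periodic_z requires Fg = 0 (no walls to balance settling)")
  N <- box$N; H <- box$H; L <- box$L

  if (is.null(init)) {
    X <- cbind(runif(N, 0, L), runif(N, 0, L), runif(N, 0, H))
    E <- tumble_orientation(N, params$tumble_angle_mode)
    next_tumble <- tumble_waiting_times(N, params$tau, params$tumble_mode)
    t0 <- 0
  } else {
    X <- init$X; E <- init$E
    t0 <- init$t %||% 0
    next_tumble <- init$next_tumble %||%
      (t0 + tumble_waiting_times(N, params$tau, params$tumble_mode))
  }
  Xu <- if (unwrap) X else NULL

  n_rec <- length(seq_len(n_steps)[seq_len(n_steps) %% record_stride == 0L])
  rec <- vector("list", n_rec)
  h <- numeric(n_steps)
  if (is.null(init)) next_tumble <- t0 + next_tumble
  k <- 0L
  t <- t0
  for (step in seq_len(n_steps)) {
    # drift
    dX <- v_p * dt * E
    dX[, 3] <- dX[, 3] - v_g * dt
    X <- X + dX
    if (unwrap) Xu <- Xu + dX
    # lateral wrap
    X[, 1] <- X[, 1] %% L
    X[, 2] <- X[, 2] %% L
    # z boundary
    if (periodic_z) {
      X[, 3] <- X[, 3] %% H
    } else {
      z <- X[, 3]
      z <- ifelse(z < 0, -z, z)
      z <- ifelse(z > H, 2 * H - z, z)
      X[, 3] <- pmin(pmax(z, 0), H)   # guards a double bounce at extreme dt
    }
    t <- t + dt
    # tumbles due in (t-dt, t]  (absolute event times)
    due <- which(next_tumble <= t)
    if (length(due)) {
      E[due, ] <- tumble_orientation(length(due), params$tumble_angle_mode)
      next_tumble[due] <- next_tumble[due] +
        tumble_waiting_times(length(due), params$tau, params$tumble_mode)
    }
    h[step] <- mean(X[, 3])
    if (step %% record_stride == 0L) {
      k <- k + 1L
      P <- if (unwrap) Xu else X
      rec[[k]] <- cbind(t, seq_len(N), P, E)
    }
  }
  traj <- if (k > 0) do.call(rbind, rec[seq_len(k)]) else
    matrix(numeric(0), 0, 8)
  colnames(traj) <- c("t", "id", "x", "y", "z", "ex", "ey", "ez")
  structure(
    list(trajectory = tibble::as_tibble(as.data.frame(traj)),
         h_series = tibble::tibble(t = t0 + dt * seq_len(n_steps), h = h),
         state = list(X = X, E = E, next_tumble = next_tumble, t = t),
         params = params, env = env, box = box, dt = dt,
         periodic_z = periodic_z),
    class = "rtp_run"
  )
}

#' @export
print.rtp_run <- function(x, ...) {
  cat(sprintf("<rtp_run> N = %d particles, %d snapshots, t in [%g, %g]\n",
              x$box$N, length(unique(x$trajectory$t)),
              min(x$trajectory$t), max(x$trajectory$t)))
  invisible(x)
}

#' Estimate the run-and-tumble diffusivity from trajectories
#'
#' Fits the long-time mean-square displacement \eqn{MSD(t) = 6Dt} of a
#' gravity-free, fully periodic run (unwrapped coordinates) over lags
#' \eqn{t \gg \tau}, where the motion has decorrelated into a random walk.
#' For Poisson tumbling the expected value is \eqn{D = v_p^2\tau/3}; for
#' fixed-interval tumbling it is \eqn{v_p^2\tau/6}.
#'
#' @param run An [simulate_rtp()] result with `periodic_z = TRUE`, `Fg = 0`
#'   and `unwrap = TRUE`.
#' @param lag_range Lag window, in units of `tau`, over which to fit
#'   (default `c(5, 20)`).
#' @return A list with `D` (fitted diffusivity), `msd` (tibble `lag, msd`),
#'   and `sufficient` (`FALSE`, with a warning, when the trajectory is
#'   shorter than twice the upper fit lag).
#' @export
estimate_diffusivity <- function(run, lag_range = c(5, 20)) {
  stopifnot(inherits(run, "rtp_run"))
  if (!run$periodic_z || run$env$Fg > 0)
    stop("diffusivity estimation requires a gravity-free, fully periodic run")
  tau <- run$params$tau
  tr <- run$trajectory
  times <- sort(unique(tr$t))
  dt_snap <- times[2] - times[1]
  ord <- order(tr$t, tr$id)
  # rows ordered by (t, id) -> fill [time, id, coord]
  m <- as.matrix(tr[ord, c("x", "y", "z")])
  pos <- array(NA_real_, c(length(times), run$box$N, 3))
  for (d in 1:3) pos[, , d] <- matrix(m[, d], nrow = length(times), byrow = TRUE)

  lags <- unique(round(seq(lag_range[1] * tau, lag_range[2] * tau, length.out = 12) / dt_snap))
  lags <- lags[lags >= 1 & lags < length(times)]
  sufficient <- length(lags) >= 4 &&
    (max(times) - min(times)) >= 2 * lag_range[2] * tau
  if (!sufficient)
    warning("sampling window too short for a reliable MSD fit at t >> tau")
  msd <- vapply(lags, function(l) {
    d <- pos[seq_len(length(times) - l) + l, , , drop = FALSE] -
      pos[seq_len(length(times) - l), , , drop = FALSE]
    mean(apply(d^2, c(1, 2), sum))
  }, numeric(1))
  lag_t <- lags * dt_snap
  fit <- lm(msd ~ lag_t)
  list(D = unname(coef(fit)[2]) / 6,
       msd = tibble::tibble(lag = lag_t, msd = msd),
       sufficient = sufficient)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
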