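#' Squirmer surface slip velocity
#'
#' The tangential surface velocity of the squirmer at surface direction
#' \eqn{\hat r_s}: \eqn{u_s = (B_1 + B_2(\hat e\cdot\hat r_s))\,
#' ((\hat e\cdot\hat r_s)\hat r_s - \hat e)}. Its magnitude is
#' \eqn{(B_1 + B_2\cos\theta)\sin\theta} with
#' \eqn{\cos\theta = \hat e\cdot\hat r_s}, and it is orthogonal to
#' \eqn{\hat r_s} (purely tangential, axisymmetric about \eqn{\hat e}).
#'
#' @param e_hat Unit orientation vector (length 3).
#' @param r_hat Unit surface direction (length 3).
#' @param params A [swimmer_params()] supplying `B1`, `B2`.
#' @return The slip-velocity 3-vector.
#' @export
slip_velocity <- function(e_hat, r_hat, params) {
  if (abs(sum(e_hat^2) - 1) > 1e-8 || abs(sum(r_hat^2) - 1) > 1e-8)
    stop("e_hat and r_hat must be unit vectors")
  cth <- sum(e_hat * r_hat)
  (params$B1 + params$B2 * cth) * (cth * r_hat - e_hat)
}

#' Lattice-Boltzmann simulation configuration
#'
#' Sets up a D3Q19 lattice of `L x L x H` nodes (lattice units: spacing and
#' step are 1) with no-slip walls at `z = 0` and `z = H` (periodic when
#' `walls = FALSE`) and periodic `x, y`. The fluid relaxes with BGK time
#' `tau_lb`, giving kinematic viscosity \eqn{\nu = c_s^2(\tau_{LB} - 1/2)},
#' \eqn{c_s^2 = 1/3}. Swimmer parameters are in lattice units; the radius
#' must resolve the sphere (`R >= 2.3`). Gravity acts on the bodies only, as
#' a constant external force `Fg` along \eqn{-z}; bodies are neutrally
#' buoyant. A short-range Hookean repulsion (stiffness `spring_k`, onset gap
#' `gap_on`) guards body-body and body-wall contacts.
#'
#' @param L,H Lattice dimensions (nodes).
#' @param swimmer A [swimmer_params()] in lattice units.
#' @param Fg Gravity force per body.
#' @param N,phi Particle count or target volume fraction (see
#'   [box_geometry()]).
#' @param tau_lb BGK relaxation time (`> 0.5`).
#' @param spring_k,gap_on Contact-guard stiffness and onset gap. The onset
#'   keeps at least one lattice spacing of fluid in body-body and body-wall
#'   gaps, where the link set would otherwise degenerate (unresolved
#'   lubrication); the default stiffness supports a stacked sediment column
#'   under the default gravities.
#' @param walls No-slip walls in `z` (default `TRUE`).
#' @param fluid_force Optional uniform body force per fluid node (3-vector),
#'   used for drag calibration flows.
#' @return An object of class `lb_config`.
#' @export
lb_config <- function(L, H, swimmer, Fg = 0, N = NULL, phi = NULL,
                      tau_lb = 1, spring_k = 2, gap_on = 1,
                      walls = TRUE, fluid_force = c(0, 0, 0)) {
  stopifnot(L >= 4, H >= 4, tau_lb > 0.5)
  if (swimmer$R < 2.3)
    stop("R must be >= 2.3 lattice units to resolve the sphere")
  cs <- 1 / sqrt(3)
  u_max <- max(abs(swimmer$B1), (abs(swimmer$B1) + abs(swimmer$B2)) / 2)
  if (u_max > 0.3 * cs)
    stop("surface slip speed too large for a stable lattice (Mach limit)")
  if (u_max > 0.1 * cs)
    warning("surface slip speed above Mach 0.1; compressibility errors may be visible")
  env <- fluid_environment(eta = (tau_lb - 0.5) / 3, rho_f = 1, Fg = Fg)
  box <- if (is.null(N) && is.null(phi)) box_geometry(L, H, swimmer$R, N = 1L)
         else box_geometry(L, H, swimmer$R, phi = phi, N = N)
  structure(list(L = as.integer(L), H = as.integer(H), swimmer = swimmer,
                 env = env, box = box, Fg = Fg, tau_lb = tau_lb,
                 spring_k = spring_k, gap_on = gap_on, walls = walls,
                 fluid_force = fluid_force),
            class = "lb_config")
}

body_matrix <- function(X, E, U = NULL, W = NULL) {
  n <- nrow(X)
  B <- matrix(0, n, 18)
  B[, 1:3] <- X
  if (!is.null(U)) B[, 4:6] <- U
  if (!is.null(W)) B[, 7:9] <- W
  B[, 10:12] <- E
  B
}

#' Place non-overlapping bodies in the box
#'
#' Rejection sampling of `N` sphere centres with pairwise surface gaps of at
#' least `min_gap` (periodic minimum image laterally) and wall clearance
#' `R + min_gap` in `z`.
#'
#' @param config An [lb_config()].
#' @param N Number of bodies (default the config's box count).
#' @param min_gap Minimum surface-to-surface gap.
#' @param max_tries Attempts per body before giving up.
#' @return An `N x 3` matrix of centres.
#' @export
place_bodies <- function(config, N = config$box$N, min_gap = 0.6,
                         max_tries = 5000) {
  L <- config$L; H <- config$H; R <- config$swimmer$R
  X <- matrix(NA_real_, N, 3)
  dmin2 <- (2 * R + min_gap)^2
  for (b in seq_len(N)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- c(runif(1, 0, L), runif(1, 0, L),
                runif(1, R + min_gap, H - R - min_gap))
      ok <- TRUE
      if (b > 1) {
        dx <- (X[1:(b - 1), 1] - cand[1]); dx <- dx - L * round(dx / L)
        dy <- (X[1:(b - 1), 2] - cand[2]); dy <- dy - L * round(dy / L)
        dz <- X[1:(b - 1), 3] - cand[3]
        ok <- all(dx^2 + dy^2 + dz^2 > dmin2)
      }
      if (ok) { X[b, ] <- cand; placed <- TRUE; break }
    }
    if (!placed) stop(sprintf("could not place body %d of %d: box too crowded", b, N))
  }
  X
}

#' Initialise a lattice-Boltzmann state
#'
#' Builds the population field at rest equilibrium (or at a prescribed
#' velocity field), carves out the solid mask for the given bodies, and
#' returns the mutable simulation state advanced by [lb_advance()].
#'
#' @param config An [lb_config()].
#' @param X Body centres (`N x 3`; default [place_bodies()] when the config
#'   declares particles, none otherwise).
#' @param E Body orientations (`N x 3` unit rows; default isotropic random).
#' @param U Initial body velocities (default 0).
#' @param mobile Integer per body: 1 free (default), 0 frozen in place,
#'   2 prescribed constant velocity.
#' @param u0 Optional initial fluid velocity field: list of arrays/vectors
#'   `ux, uy, uz` over nodes (default rest).
#' @return An object of class `lb_state`.
#' @export
lb_initialize <- function(config, X = NULL, E = NULL, U = NULL,
                          mobile = NULL, u0 = NULL) {
  L <- config$L; H <- config$H
  nnode <- L * L * H
  if (is.null(u0)) {
    f <- lb_equilibrium(L, L, H, 1, 0, 0, 0)
  } else {
    f <- lb_equilibrium(L, L, H, u0$rho %||% 1, u0$ux %||% 0,
                        u0$uy %||% 0, u0$uz %||% 0)
  }
  if (is.null(X)) X <- matrix(numeric(0), 0, 3)
  n <- nrow(X)
  if (is.null(E)) E <- if (n) tumble_orientation(n, "sphere_uniform") else matrix(numeric(0), 0, 3)
  B <- body_matrix(X, E, U)
  mask <- if (n) lb_make_mask(L, L, H, B, config$swimmer$R, as.integer(config$walls))
          else rep(-1L, nnode)
  if (n) {
    solid <- which(mask >= 0L)
    if (length(solid)) {
      kill <- as.vector(outer(1:19, (solid - 1L) * 19L, `+`))
      f[kill] <- 0
    }
  }
  structure(list(f = f, mask = mask, bodies = B,
                 mobile = if (is.null(mobile)) rep(1L, n) else as.integer(mobile),
                 config = config, t = 0,
                 budget = list(to_walls = c(0, 0, 0), to_bodies = c(0, 0, 0))),
            class = "lb_state")
}

#' Advance a lattice-Boltzmann state
#'
#' Runs `n_steps` of the fused update: BGK collision, streaming with Ladd
#' bounce-back-on-links at body surfaces (boundary velocity = rigid motion +
#' squirmer slip) and half-way bounce-back walls, Newton-Euler body update
#' with gravity and the contact guard, and mask refresh with cover/uncover
#' mass/momentum bookkeeping. Hydrodynamic forces are averaged over two
#' successive steps before being applied (the standard stabilisation against
#' impulsive cover/uncover noise).
#'
#' @param state An `lb_state`.
#' @param n_steps Steps to advance.
#' @return The updated `lb_state`; element `diag` holds the conservation
#'   diagnostics of this chunk (mass and momentum budgets, wall and body
#'   momentum exchange).
#' @export
lb_advance <- function(state, n_steps) {
  cfg <- state$config
  out <- lb_run_chunk(state$f, state$mask, state$bodies, state$mobile,
                      cfg$L, cfg$L, cfg$H, cfg$tau_lb,
                      cfg$swimmer$B1, cfg$swimmer$B2, cfg$swimmer$R,
                      cfg$Fg, cfg$spring_k, cfg$gap_on,
                      as.integer(cfg$walls), cfg$fluid_force, as.integer(n_steps))
  state$f <- out$f
  state$mask <- out$mask
  state$bodies <- out$bodies
  state$t <- state$t + n_steps
  state$diag <- out$diag
  state
}

#' @export
print.lb_state <- function(x, ...) {
  cat(sprintf("<lb_state> %d x %d x %d lattice, %d bodies, t = %g\n",
              x$config$L, x$config$L, x$config$H, nrow(x$bodies), x$t))
  invisible(x)
}

#' Macroscopic fluid fields of an LB state
#'
#' @param state An `lb_state`.
#' @return A tibble `(x, y, z, rho, ux, uy, uz)` over fluid nodes (solid
#'   nodes excluded).
#' @export
lb_fields <- function(state) {
  cfg <- state$config
  m <- lb_macroscopics(state$f, state$mask, cfg$L, cfg$L, cfg$H)
  idx <- which(state$mask < 0L)
  nx <- cfg$L; ny <- cfg$L
  i0 <- idx - 1L
  tibble::tibble(
    x = (i0 %% nx) + 0.5,
    y = ((i0 %/% nx) %% ny) + 0.5,
    z = (i0 %/% (nx * ny)) + 0.5,
    rho = m$rho[idx], ux = m$ux[idx], uy = m$uy[idx], uz = m$uz[idx]
  )
}

#' Slab profile of fluid velocity fluctuations
#'
#' For each z-slab of fluid nodes (nodes inside bodies excluded), the
#' variance of the fluid velocity about the slab mean,
#' \eqn{\sigma^2(z) = \langle|u - \langle u\rangle_z|^2\rangle_z}. Slabs with
#' no fluid nodes are marked missing (`NA`), not zero.
#'
#' @param state An `lb_state`.
#' @return A [fluctuation_profile()] tibble `(z, sigma2)` (tagged
#'   `simulated`) with an `n_nodes` column; `NA` rows flag empty slabs.
#' @export
lb_fluct_profile <- function(state) {
  cfg <- state$config
  M <- lb_slab_moments(state$f, state$mask, cfg$L, cfg$L, cfg$H)
  n <- M[, 1]
  s2 <- ifelse(n > 0, M[, 5] / n - (M[, 2]^2 + M[, 3]^2 + M[, 4]^2) / n^2, NA_real_)
  out <- tibble::tibble(z = seq_len(cfg$H) - 0.5, sigma2 = pmax(s2, 0),
                        n_nodes = n)
  class(out) <- c("fluctuation_profile", class(out))
  attr(out, "source") <- "simulated"
  out
}

#' Simulate a sedimenting squirmer suspension
#'
#' Full resolved-hydrodynamics run: squirmers under gravity between no-slip
#' walls, with run-and-tumble reorientation. The lattice state is advanced
#' in chunks; at chunk boundaries tumble events are applied (per-body
#' schedules per the swimmer's `tumble_mode`/`tumble_angle_mode`), body
#' snapshots and the mean height are recorded, and — after `sigma2_after`
#' steps — slab velocity-fluctuation profiles are accumulated and
#' time-averaged.
#'
#' @param config An [lb_config()] with `N` (or `phi`) and `Fg` set.
#' @param n_steps Total steps.
#' @param stride Chunk length in steps (also the tumble-event resolution and
#'   the recording stride); keep below `tau/5`.
#' @param sigma2_after Step count after which fluctuation profiles are
#'   accumulated (set `>= n_steps` to skip).
#' @param sigma2_every Accumulate a fluctuation snapshot every this many
#'   chunks.
#' @param X,E Optional initial centres and orientations.
#' @return An object of class `lb_run`: list with `trajectory` (tibble
#'   `t, id, x, y, z, ex, ey, ez`), `h_series` (tibble `t, h`), `sigma2`
#'   (time-averaged [fluctuation_profile()] or `NULL`), `state` (final
#'   `lb_state`), `params`, `config`.
#' @export
simulate_lb <- function(config, n_steps, stride = 20L,
                        sigma2_after = n_steps, sigma2_every = 5L,
                        X = NULL, E = NULL) {
  sw <- config$swimmer
  if (is.null(X)) X <- place_bodies(config)
  n <- nrow(X)
  state <- lb_initialize(config, X = X, E = E)
  next_tumble <- tumble_waiting_times(n, sw$tau, sw$tumble_mode)
  n_chunks <- ceiling(n_steps / stride)
  rec <- vector("list", n_chunks)
  hs <- numeric(n_chunks); ts <- numeric(n_chunks)
  s2_acc <- NULL; s2_n <- 0L
  for (ch in seq_len(n_chunks)) {
    state <- lb_advance(state, stride)
    due <- which(next_tumble <= state$t)
    if (length(due)) {
      state$bodies[due, 10:12] <- tumble_orientation(length(due), sw$tumble_angle_mode)
      next_tumble[due] <- next_tumble[due] +
        tumble_waiting_times(length(due), sw$tau, sw$tumble_mode)
    }
    ts[ch] <- state$t
    hs[ch] <- mean(state$bodies[, 3])
    rec[[ch]] <- cbind(state$t, seq_len(n), state$bodies[, 1:3, drop = FALSE],
                       state$bodies[, 10:12, drop = FALSE])
    if (state$t > sigma2_after && ch %% sigma2_every == 0L) {
      fp <- lb_fluct_profile(state)
      s2_acc <- if (is.null(s2_acc)) fp$sigma2 else s2_acc + fp$sigma2
      s2_n <- s2_n + 1L
    }
  }
  traj <- do.call(rbind, rec)
  colnames(traj) <- c("t", "id", "x", "y", "z", "ex", "ey", "ez")
  sigma2 <- if (s2_n > 0) {
    out <- tibble::tibble(z = seq_len(config$H) - 0.5, sigma2 = s2_acc / s2_n)
    class(out) <- c("fluctuation_profile", class(out))
    attr(out, "source") <- "simulated"
    out
  } else NULL
  structure(
    list(trajectory = tibble::as_tibble(as.data.frame(traj)),
         h_series = tibble::tibble(t = ts, h = hs),
         sigma2 = sigma2, state = state,
         params = sw, config = config),
    class = "lb_run"
  )
}

#' @export
print.lb_run <- function(x, ...) {
  cat(sprintf("<lb_run> %d bodies, %d snapshots, t = %g lattice steps\n",
              nrow(x$state$bodies), length(x$h_series$t), x$state$t))
  invisible(x)
}

#' Calibrate the effective hydrodynamic radius
#'
#' A staircase sphere of nominal radius `R` on the lattice has an effective
#' hydrodynamic radius \eqn{R_{eff} \ne R}. This measures it from the Stokes
#' drag on a frozen sphere in a fully periodic box driven by a uniform body
#' force on the fluid: at steady state the drag equals the total injected
#' momentum flux, and the mean flow relates to it through the Stokes law
#' with the periodic-array (Hasimoto) correction
#' \eqn{F = 6\pi\eta R_{eff}\,\bar u / (1 - 2.837\,R_{eff}/L)}.
#'
#' @param R Sphere radius (lattice units, `>= 2.3`).
#' @param L Periodic box size (nodes).
#' @param tau_lb BGK relaxation time.
#' @param g Body-force density on the fluid.
#' @param n_steps Relaxation steps (several viscous box times).
#' @return A list with `R_eff`, `drag` (measured force), `u_mean`,
#'   `mobility` (the bare-lattice `u_mean / drag`, i.e. including periodic
#'   images — reusable only in the same geometry).
#' @export
calibrate_r_eff <- function(R = 2.3, L = 24, tau_lb = 1, g = 1e-5,
                            n_steps = 4000) {
  sw <- swimmer_params(B1 = 0, B2 = 0, R = R, tau = 1e9)
  cfg <- lb_config(L, L, sw, Fg = 0, N = 1, walls = FALSE,
                   fluid_force = c(g, 0, 0), tau_lb = tau_lb)
  X <- matrix(c(L / 2, L / 2, L / 2), 1, 3)
  st <- lb_initialize(cfg, X = X, E = matrix(c(0, 0, 1), 1, 3), mobile = 0L)
  st <- lb_advance(st, n_steps)
  drag <- st$bodies[1, 13]           # hydrodynamic force on the body along x
  flds <- lb_fields(st)
  u_mean <- mean(flds$ux)
  eta <- (tau_lb - 0.5) / 3
  root <- function(Re) drag * (1 - 2.837297 * Re / L) - 6 * pi * eta * Re * u_mean
  R_eff <- stats::uniroot(root, c(0.5 * R, 2.5 * R))$root
  list(R_eff = R_eff, drag = drag, u_mean = u_mean, mobility = u_mean / drag)
}
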