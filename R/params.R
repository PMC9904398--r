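#' activesed: sedimentation of run-and-tumble squirmer suspensions
#'
#' Simulators and analysis tools for gravitational sedimentation of active
#' particles: a resolved D3Q19 lattice-Boltzmann squirmer engine, a dry
#' run-and-tumble reference model, and a steady-state Smoluchowski solver
#' with a height-dependent effective temperature.
#'
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx integrate lm optimize rexp rnorm runif setNames
#'   weighted.mean coef
#' @importFrom utils head tail
#' @useDynLib activesed, .registration = TRUE
#' @keywords internal
"_PACKAGE"

#' Squirmer swimming parameters
#'
#' A squirmer is a spherical microswimmer whose motion is driven by a
#' prescribed tangential slip velocity on its surface,
#' \eqn{u_s(\theta) = (B_1 + B_2\cos\theta)\sin\theta}, where \eqn{\theta} is
#' the polar angle from the swimming direction \eqn{\hat e}. The first mode
#' \eqn{B_1 \ge 0} sets the propulsion speed \eqn{v_p = 2B_1/3}; the signed
#' second mode \eqn{B_2} sets the stresslet (the far-field flow), classifying
#' swimmers as pushers (\eqn{\beta = B_2/B_1 < 0}), pullers (\eqn{\beta > 0}),
#' potential swimmers (\eqn{\beta = 0}) and shakers (\eqn{B_1 = 0}, which stir
#' the fluid without net self-propulsion).
#'
#' Orientations are randomised ("tumbled") at characteristic interval
#' `tau`, either at exact multiples of `tau` (`fixed_interval`) or as a
#' Poisson process with mean waiting time `tau` (`poisson`, the default:
#' it reproduces the textbook run-and-tumble diffusivity
#' \eqn{D = v_p^2\tau/3} exactly). The new orientation is drawn either
#' uniformly on the unit sphere (`sphere_uniform`, default) or with the polar
#' angle uniform on \eqn{[0, \pi]} (`polar_uniform`); both fully decorrelate
#' successive runs.
#'
#' @param B1 First squirming mode (speed units), `>= 0`.
#' @param B2 Second squirming mode (speed units), signed.
#' @param R Particle radius (length units), `> 0`.
#' @param tau Run duration between tumbles (time units), `> 0`.
#' @param tumble_mode `"poisson"` or `"fixed_interval"`.
#' @param tumble_angle_mode `"sphere_uniform"` or `"polar_uniform"`.
#' @return An object of class `swimmer_params`.
#' @examples
#' sw <- swimmer_params(B1 = 30, B2 = -200, R = 1, tau = 1)
#' swim_speed(sw)              # 20
#' shaker_reference_speed(sw)  # 66.7
#' @export
swimmer_params <- function(B1, B2 = 0, R = 1, tau = 1,
                           tumble_mode = c("poisson", "fixed_interval"),
                           tumble_angle_mode = c("sphere_uniform", "polar_uniform")) {
  tumble_mode <- match.arg(tumble_mode)
  tumble_angle_mode <- match.arg(tumble_angle_mode)
  stopifnot(is.numeric(B1), length(B1) == 1L, is.finite(B1),
            is.numeric(B2), length(B2) == 1L, is.finite(B2),
            is.numeric(R), length(R) == 1L, R > 0,
            is.numeric(tau), length(tau) == 1L, tau > 0)
  if (B1 < 0) stop("B1 must be >= 0 (the propulsion mode is non-negative)")
  structure(
    list(B1 = B1, B2 = B2, R = R, tau = tau,
         tumble_mode = tumble_mode, tumble_angle_mode = tumble_angle_mode),
    class = "swimmer_params"
  )
}

#' @export
print.swimmer_params <- function(x, ...) {
  cat("<swimmer_params>\n")
  cat(sprintf("  B1 = %g, B2 = %g  (beta = %s)\n", x$B1, x$B2,
              if (x$B1 > 0) format(x$B2 / x$B1) else ifelse(x$B2 == 0, "undefined", "+/-Inf")))
  cat(sprintf("  R = %g, tau = %g, tumbling: %s / %s\n",
              x$R, x$tau, x$tumble_mode, x$tumble_angle_mode))
  invisible(x)
}

#' Fluid environment and gravity
#'
#' The solvent is described by its dynamic viscosity `eta` and density
#' `rho_f` (kinematic viscosity `nu = eta / rho_f`); gravity enters through
#' the force magnitude `Fg` on one particle, directed along \eqn{-z}.
#' Particles are athermal: thermal fluctuations are negligible at these sizes,
#' so no temperature is carried. The reference settling speed of a passive
#' particle is \eqn{v_g = \mu F_g} with Stokes mobility
#' \eqn{\mu = 1/(6\pi\eta R)}.
#'
#' @param eta Dynamic viscosity, `> 0`.
#' @param rho_f Fluid density, `> 0` (default 1, lattice convention).
#' @param Fg Gravity force magnitude per particle, `>= 0`.
#' @return An object of class `fluid_environment` with fields `eta`, `nu`,
#'   `rho_f`, `Fg`.
#' @seealso [mobility()], [settling_speed()]
#' @export
fluid_environment <- function(eta, rho_f = 1, Fg = 0) {
  stopifnot(is.numeric(eta), eta > 0, is.numeric(rho_f), rho_f > 0,
            is.numeric(Fg), Fg >= 0)
  structure(list(eta = eta, nu = eta / rho_f, rho_f = rho_f, Fg = Fg),
            class = "fluid_environment")
}

#' Stokes mobility of a sphere
#' @param env A [fluid_environment()].
#' @param R Particle radius.
#' @return \eqn{\mu = 1/(6\pi\eta R)}.
#' @export
mobility <- function(env, R) 1 / (6 * pi * env$eta * R)

#' Passive settling speed \eqn{v_g = \mu F_g}
#' @inheritParams mobility
#' @export
settling_speed <- function(env, R) mobility(env, R) * env$Fg

#' Simulation box geometry
#'
#' A laterally periodic box of size \eqn{L \times L \times H} with solid
#' no-slip walls at \eqn{z = 0} and \eqn{z = H}; gravity acts along \eqn{-z}.
#' The aspect ratio is \eqn{\Gamma = L/H}. Either the particle count `N` or
#' the volume fraction `phi` may be given; the other is derived from the
#' particle volume \eqn{(4/3)\pi R^3}.
#'
#' @param L Lateral box size (periodic directions).
#' @param H Box height (wall-to-wall).
#' @param R Particle radius, used to convert between `N` and `phi`.
#' @param phi Target volume fraction (used if `N` missing).
#' @param N Particle count (takes precedence if supplied).
#' @return An object of class `box_geometry` with fields `L`, `H`, `Gamma`,
#'   `R`, `N`, `phi` (the realised volume fraction for integer `N`).
#' @export
box_geometry <- function(L, H, R = 1, phi = NULL, N = NULL) {
  stopifnot(L > 0, H > 0, R > 0)
  vol1 <- 4 / 3 * pi * R^3
  if (is.null(N)) {
    if (is.null(phi)) stop("supply either `phi` or `N`")
    N <- max(1L, as.integer(round(phi * L^2 * H / vol1)))
  }
  structure(list(L = L, H = H, Gamma = L / H, R = R, N = as.integer(N),
                 phi = N * vol1 / (L^2 * H)),
            class = "box_geometry")
}

#' Propulsion speed of a squirmer
#'
#' The steady swimming speed of an isolated squirmer is set by the first
#' squirming mode alone: \eqn{v_p = 2B_1/3}.
#'
#' @param params A [swimmer_params()].
#' @return The propulsion speed (same units as `B1`).
#' @export
swim_speed <- function(params) 2 * params$B1 / 3

#' Shaker reference speed
#'
#' A shaker (\eqn{B_1 = 0}) generates flow but no net motion; its natural
#' velocity scale is the surface average of the slip-speed magnitude,
#' \eqn{v_{B2} = \frac{1}{4\pi}\oint |B_2\cos\theta\sin\theta|\, d\Omega
#' = |B_2|/3}.
#'
#' @param params A [swimmer_params()].
#' @return \eqn{|B_2|/3}.
#' @export
shaker_reference_speed <- function(params) abs(params$B2) / 3

#' Second squirming mode from a force-dipole description
#'
#' Real microswimmers are often characterised by a force dipole of magnitude
#' `f` and extent `delta`; the stresslet \eqn{S \sim f\delta \sim \eta R^2
#' B_2} maps onto a squirming amplitude \eqn{|B_2| \sim S/(\eta\delta^2) =
#' f/(\eta\delta)}. For E. coli (`f` ~ 0.4 pN, `delta` ~ 2 um in water) this
#' gives roughly 200 um/s.
#'
#' @param f Dipole force magnitude, `>= 0`.
#' @param delta Dipole length, `> 0`.
#' @param eta Dynamic viscosity, `> 0`.
#' @return The estimated \eqn{|B_2| = f/(\eta\delta)}.
#' @examples
#' dipole_to_b2(f = 0.4e-12, delta = 2e-6, eta = 1e-3)  # 2e-4 m/s = 200 um/s
#' @export
dipole_to_b2 <- function(f, delta, eta) {
  stopifnot(is.numeric(f), f >= 0, is.numeric(delta), delta > 0,
            is.numeric(eta), eta > 0)
  f / (eta * delta)
}

#' Dimensionless groups governing squirmer sedimentation
#'
#' Computes the ratios that govern the competition between activity and
#' gravity:
#' \itemize{
#'   \item \eqn{\chi_1 = v_p / v_g}: propulsion/gravity ratio;
#'   \item \eqn{\chi_2 = \mathrm{sign}(B_2)\, v_{B2} / v_g}: signed
#'     activity/gravity ratio built on the shaker reference speed
#'     \eqn{v_{B2} = |B_2|/3} (negative for pushers, positive for pullers);
#'   \item \eqn{\beta = B_2/B_1} (signed infinity for shakers, `B1 = 0`);
#'   \item \eqn{\ell^* = v_p\tau/R}: run length in units of the radius;
#'   \item \eqn{t_c = R/v_p} and \eqn{t_\nu = R^2/\nu}: displacement and
#'     viscous times.
#' }
#'
#' All groups are invariant under a common rescaling of speeds.
#'
#' @param params A [swimmer_params()].
#' @param env A [fluid_environment()] with `Fg > 0` (the \eqn{\chi} ratios are
#'   undefined for `Fg = 0` and an error is signalled).
#' @return An object of class `dimensionless_groups` with fields `chi1`,
#'   `chi2`, `beta`, `ell_star`, `t_c`, `t_nu`, `v_p`, `v_g`, `v_B2`.
#' @examples
#' sw <- swimmer_params(B1 = 30, B2 = -200, R = 1, tau = 1)
#' env <- fluid_environment(eta = 1 / (6 * pi), Fg = 1)  # v_g = 1
#' dimensionless_groups(sw, env)
#' @export
dimensionless_groups <- function(params, env) {
  v_p <- swim_speed(params)
  v_B2 <- shaker_reference_speed(params)
  v_g <- settling_speed(env, params$R)
  if (v_g <= 0)
    stop("chi ratios are undefined for Fg = 0 (v_g = 0); set a positive gravity force")
  beta <- if (params$B1 > 0) params$B2 / params$B1 else sign(params$B2) * Inf
  structure(
    list(chi1 = v_p / v_g,
         chi2 = sign(params$B2) * v_B2 / v_g,
         beta = beta,
         ell_star = v_p * params$tau / params$R,
         t_c = if (v_p > 0) params$R / v_p else Inf,
         t_nu = params$R^2 / env$nu,
         v_p = v_p, v_g = v_g, v_B2 = v_B2),
    class = "dimensionless_groups"
  )
}

#' @export
print.dimensionless_groups <- function(x, ...) {
  cat("<dimensionless_groups>\n")
  cat(sprintf("  chi1 = %g, chi2 = %g, beta = %s\n", x$chi1, x$chi2, format(x$beta)))
  cat(sprintf("  ell* = %g, t_c = %g, t_nu = %g\n", x$ell_star, x$t_c, x$t_nu))
  invisible(x)
}

#' @export
tidy.dimensionless_groups <- function(x, ...) {
  tibble::tibble(
    group = c("chi1", "chi2", "beta", "ell_star", "t_c", "t_nu"),
    value = c(x$chi1, x$chi2, x$beta, x$ell_star, x$t_c, x$t_nu),
    description = c("propulsion/gravity ratio v_p/v_g",
                    "signed activity/gravity ratio v_B2/v_g",
                    "squirming-mode ratio B2/B1",
                    "run length v_p*tau in radii",
                    "self-displacement time R/v_p",
                    "viscous relaxation time R^2/nu")
  )
}

#' Theoretical sedimentation length of a run-and-tumble swimmer
#'
#' In the self-propulsion dominated regime (\eqn{\chi_1 \gg 1}) the steady
#' density profile is exponential, \eqn{\rho(z) \sim e^{-z/\lambda}}, with
#' \eqn{\lambda = \ell^* \chi_1 R / 3 = v_p^2\tau/(3 v_g)}: the run-and-tumble
#' diffusivity \eqn{D = v_p^2\tau/3} divided by the settling speed. Near
#' \eqn{\chi_1 = 1} the drift-diffusion picture breaks down and particles
#' pile up at the bottom wall; the formula is not meaningful there.
#'
#' @param groups A [dimensionless_groups()].
#' @param R Particle radius.
#' @return The sedimentation length \eqn{\lambda} (length units of `R`).
#' @export
sedimentation_length_theory <- function(groups, R) {
  groups$ell_star * R * groups$chi1 / 3
}

#' Single-particle effective temperature as an equivalent length
#'
#' The analogy with the passive (Perrin) barometric profile assigns an active
#' suspension an effective temperature via \eqn{k_B T^{(1p)}_{eff} =
#' D/\mu = v_p^2\tau/(3\mu)}; expressed as the equivalent length
#' \eqn{k_B T^{(1p)}_{eff}/F_g} it coincides with the theoretical
#' sedimentation length.
#'
#' @param params A [swimmer_params()].
#' @param env A [fluid_environment()].
#' @return \eqn{v_p^2\tau/(3\mu F_g)} (length); `Inf` with a warning when
#'   `Fg = 0`.
#' @export
effective_temperature_1p <- function(params, env) {
  v_p <- swim_speed(params)
  v_g <- settling_speed(env, params$R)
  if (env$Fg == 0) {
    warning("Fg = 0: single-particle effective temperature length is infinite")
    return(Inf)
  }
  v_p^2 * params$tau / (3 * v_g)
}

#' Close-packed sediment height
#'
#' If all particles of a suspension at volume fraction `phi` in a box of
#' height `H` collapsed into a close-packed layer at packing fraction
#' `packing`, the layer height would be \eqn{\phi H / \phi_{cp}}. Used as the
#' gravitational-collapse yardstick against which active sediment widths are
#' compared; the default packing fraction 0.70 sits between random close
#' packing (0.64) and FCC (0.74).
#'
#' @param phi Suspension volume fraction.
#' @param H Box height.
#' @param packing Packing fraction of the collapsed sediment.
#' @return The close-packed layer height (same units as `H`).
#' @examples
#' close_packed_height(phi = 0.07, H = 80)  # 8 (units of R if H is)
#' @export
close_packed_height <- function(phi, H, packing = 0.70) {
  stopifnot(phi > 0, H > 0, packing > 0, packing <= 1)
  phi * H / packing
}
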