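# shared fixtures: standard parameter sets used across the suite

# unit-speed potential swimmer: v_p = 1, R = 1, run length ell* = tau
unit_swimmer <- function(tau = 4.3, B2 = 0, ...) {
  swimmer_params(B1 = 1.5, B2 = B2, R = 1, tau = tau, ...)
}

# environment with mobility mu = 1 so that v_g = Fg
unit_env <- function(Fg = 0) fluid_environment(eta = 1 / (6 * pi), Fg = Fg)

# independent surface-quadrature oracle for the mean slip-speed magnitude:
# (1/4pi) \oint |(B1 + B2 cos th) sin th| dOmega
slip_surface_mean_oracle <- function(B1, B2) {
  integrate(function(th) abs((B1 + B2 * cos(th)) * sin(th)) * sin(th) / 2,
            0, pi, rel.tol = 1e-10)$value
}

# independent dense-quadrature oracle for the zero-flux steady profile:
# rho(z) = C exp(-int_0^z dz'/lambda(z')) via adaptive quadrature per z
steady_density_oracle <- function(lambda_fun, z, H = max(z)) {
  I <- vapply(z, function(zz)
    integrate(function(s) 1 / lambda_fun(s), 0, zz,
              rel.tol = 1e-10, subdivisions = 2000L)$value, numeric(1))
  rho <- exp(-I)
  Z <- integrate(function(s) {
    Is <- vapply(s, function(ss)
      integrate(function(u) 1 / lambda_fun(u), 0, ss,
                rel.tol = 1e-10, subdivisions = 2000L)$value, numeric(1))
    exp(-Is)
  }, 0, H, rel.tol = 1e-9)$value
  rho / Z
}

# mean-height oracle for a truncated exponential profile on [0, H]
exp_mean_height <- function(lambda, H) {
  lambda - H * exp(-H / lambda) / (1 - exp(-H / lambda))
}
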