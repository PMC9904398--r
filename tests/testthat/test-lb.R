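test_that("slip velocity matches the squirmer surface law", {
  sw <- swimmer_params(B1 = 2, B2 = 3, R = 2.3, tau = 1)
  e <- c(0, 0, 1)
  # poles: sin(theta) = 0 kills the slip
  expect_equal(slip_velocity(e, c(0, 0, 1), sw), c(0, 0, 0))
  expect_equal(slip_velocity(e, c(0, 0, -1), sw), c(0, 0, 0))
  # equator: magnitude B1, direction -e, independent of B2
  us <- slip_velocity(e, c(1, 0, 0), sw)
  expect_equal(us, c(0, 0, -2))
  # tangential everywhere; magnitude equals (B1 + B2 cos th) sin th
  set.seed(171)
  for (i in 1:20) {
    r <- tumble_orientation(1)[1, ]
    u <- slip_velocity(e, r, sw)
    expect_lt(abs(sum(u * r)), 1e-12)
    cth <- sum(e * r)
    expect_equal(sqrt(sum(u^2)), abs((2 + 3 * cth) * sqrt(1 - cth^2)),
                 tolerance = 1e-10)
  }
  # pure shaker: maximal slip B2/2 at theta = pi/4
  shk <- swimmer_params(B1 = 0, B2 = 1, R = 2.3, tau = 1)
  th <- seq(0, pi, by = 1e-4)
  mags <- abs((0 + 1 * cos(th)) * sin(th))
  expect_equal(max(mags), 0.5, tolerance = 1e-6)
  u45 <- slip_velocity(e, c(sin(pi / 4), 0, cos(pi / 4)), shk)
  expect_equal(sqrt(sum(u45^2)), 0.5, tolerance = 1e-12)
  expect_error(slip_velocity(c(0, 0, 2), c(1, 0, 0), sw), "unit")
})

test_that("uniform rest fluid is a fixed point of collide-and-stream", {
  sw <- swimmer_params(B1 = 0, B2 = 0, R = 2.3, tau = 1e9)
  cfg <- lb_config(8, 12, sw, walls = FALSE)
  st <- lb_initialize(cfg)
  st <- lb_advance(st, 50)
  fl <- lb_fields(st)
  expect_equal(fl$rho, rep(1, nrow(fl)), tolerance = 1e-14)
  expect_equal(max(abs(c(fl$ux, fl$uy, fl$uz))), 0, tolerance = 1e-14)
})

test_that("global momentum is conserved without boundaries", {
  set.seed(181)
  sw <- swimmer_params(B1 = 0, B2 = 0, R = 2.3, tau = 1e9)
  cfg <- lb_config(10, 10, sw, walls = FALSE)
  nn <- 10 * 10 * 10
  st <- lb_initialize(cfg, u0 = list(ux = runif(nn, -0.02, 0.02),
                                     uy = runif(nn, -0.02, 0.02),
                                     uz = runif(nn, -0.02, 0.02)))
  st <- lb_advance(st, 200)
  d <- st$diag
  expect_lt(max(abs(d$p_end - d$p_start)), 1e-10)
  expect_lt(abs(d$mass_end - d$mass_start) / d$mass_start, 1e-12)
})

test_that("shear-wave decay reproduces nu = cs^2 (tau_LB - 1/2) within 1%", {
  L <- 16
  nn <- L * L * L
  k <- (seq_len(nn) - 1) %/% (L * L)
  ux <- 0.01 * sin(2 * pi * (k + 0.5) / L)
  sw <- swimmer_params(B1 = 0, B2 = 0, R = 2.3, tau = 1e9)
  for (tau_lb in c(0.8, 1.0)) {
    cfg <- lb_config(L, L, sw, walls = FALSE, tau_lb = tau_lb)
    st <- lb_initialize(cfg, u0 = list(ux = ux))
    amp <- function(s) { fl <- lb_fields(s); 2 * mean(fl$ux * sin(2 * pi * fl$z / L)) }
    st <- lb_advance(st, 100)             # skip the start-up transient
    a0 <- amp(st)
    st <- lb_advance(st, 300)
    a1 <- amp(st)
    nu_meas <- -log(a1 / a0) / (300 * (2 * pi / L)^2)
    expect_equal(nu_meas, (tau_lb - 0.5) / 3, tolerance = 0.01)
  }
})

test_that("mass and momentum budgets close to bookkeeping precision with moving squirmers", {
  set.seed(191)
  sw <- swimmer_params(B1 = 0.05, B2 = -0.05, R = 2.3, tau = 400)
  cfg <- lb_config(12, 24, sw, Fg = 0.03, N = 3)
  st <- lb_initialize(cfg)
  m_body <- 4 / 3 * pi * 2.3^3
  for (chunk in 1:3) {
    U0 <- st$bodies[, 4:6, drop = FALSE]
    st <- lb_advance(st, 150)
    d <- st$diag
    # fluid-side mass identity: all changes are booked
    expect_lt(abs((d$mass_end - d$mass_start) -
                    (d$created_mass - d$deleted_mass - d$bb_mass)) / d$mass_start,
              1e-12)
    # fluid-side momentum identity
    lhs <- d$p_end - d$p_start
    rhs <- -d$to_bodies - d$to_walls + d$created_mom - d$deleted_mom +
      d$fluid_force_impulse
    expect_lt(max(abs(lhs - rhs)), 1e-9)
    # body-side: velocity change equals applied impulse / mass
    dP_body <- colSums((st$bodies[, 4:6, drop = FALSE] - U0) * m_body)
    expect_lt(max(abs(dP_body - d$body_impulse)), 1e-9)
    # confinement is absolute
    expect_true(all(st$bodies[, 3] > 2.3 & st$bodies[, 3] < 24 - 2.3))
  }
})

test_that("reconstructed solid volume fraction matches the configured phi", {
  set.seed(201)
  sw <- swimmer_params(B1 = 0, B2 = 0, R = 2.3, tau = 1e9)
  cfg <- lb_config(16, 32, sw, phi = 0.07)
  st <- lb_initialize(cfg)
  phi_mask <- mean(st$mask >= 0)
  # staircase discretisation of an R = 2.3 sphere: per-sphere node count is
  # within ~15% of the continuum volume
  expect_equal(phi_mask, cfg$box$phi, tolerance = 0.15)
})

test_that("fluid fluctuation profiles: zero at rest, zero for uniform flow, peaked at a shaker", {
  sw <- swimmer_params(B1 = 0, B2 = 0, R = 2.3, tau = 1e9)
  cfg <- lb_config(10, 20, sw, walls = FALSE)
  st <- lb_initialize(cfg)
  expect_true(all(lb_fluct_profile(st)$sigma2 == 0))
  stu <- lb_initialize(cfg, u0 = list(ux = 0.03))
  expect_lt(max(lb_fluct_profile(stu)$sigma2), 1e-28)
  # a steady mid-box shaker stirs its own slab the most, symmetrically
  shk <- swimmer_params(B1 = 0, B2 = 0.06, R = 2.3, tau = 1e9)
  cfg2 <- lb_config(16, 32, shk, walls = FALSE, N = 1)
  st2 <- lb_initialize(cfg2, X = matrix(c(8, 8, 16), 1, 3),
                       E = matrix(c(0, 0, 1), 1, 3), mobile = 0L)
  st2 <- lb_advance(st2, 800)
  fp <- lb_fluct_profile(st2)
  pk <- which.max(fp$sigma2)
  expect_lt(abs(fp$z[pk] - 16), 3.5)
  away <- mean(fp$sigma2[abs(fp$z - 16) > 10])
  expect_lt(away, 0.2 * max(fp$sigma2))
  lower <- fp$sigma2[fp$z >= 16 - 8 & fp$z < 16]
  upper <- rev(fp$sigma2[fp$z > 16 & fp$z <= 16 + 8])
  expect_equal(lower, upper, tolerance = 0.25)
})

test_that("run-and-tumble coupling: no tumbles at infinite tau, isotropy over many", {
  set.seed(211)
  sw <- swimmer_params(B1 = 0.05, B2 = 0, R = 2.3, tau = 1e9)
  cfg <- lb_config(10, 20, sw, N = 1, walls = FALSE)
  X <- matrix(c(5, 5, 10), 1, 3); E <- matrix(c(0, 0, 1), 1, 3)
  run <- simulate_lb(cfg, n_steps = 100, stride = 20, X = X, E = E)
  # orientation never tumbles; only staircase-torque noise at ~1e-7
  expect_true(all(abs(run$trajectory$ez - 1) < 1e-4))
  # frequent tumbling: recorded orientations isotropic on ensemble average
  sw2 <- swimmer_params(B1 = 0.05, B2 = 0, R = 2.3, tau = 40)
  cfg2 <- lb_config(10, 20, sw2, N = 1, walls = FALSE)
  run2 <- simulate_lb(cfg2, n_steps = 4000, stride = 20, X = X, E = E)
  expect_lt(abs(mean(run2$trajectory$ez)), 0.35)
})
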