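test_that("density profiles are normalised, located and relabelling-invariant", {
  # single occupied bin
  p1 <- density_profile(rep(40, 100), H = 80, bin_width = 0.5)
  expect_equal(sum(p1$rho * 0.5), 1)
  expect_equal(p1$z[p1$count > 0], 40.25)
  expect_equal(mean_height(p1), 40)
  # uniform sample: flat at 1/H by chi-squared
  set.seed(101)
  z <- runif(20000, 0, 80)
  p2 <- density_profile(z, H = 80, bin_width = 4)
  expect_gt(chisq.test(p2$count)$p.value, 0.01)
  expect_equal(mean(p2$rho), 1 / 80, tolerance = 1e-12)
  # relabelling (permutation) invariance
  p3 <- density_profile(sample(z), H = 80, bin_width = 4)
  expect_equal(p3$rho, p2$rho)
  expect_error(density_profile(numeric(0), H = 80), "empty")
})

test_that("exponential samples round-trip through the sedimentation-length fit", {
  set.seed(111)
  H <- 80; lam_true <- 10
  zg <- seq(0, H, by = 0.1)
  rho <- exp(-zg / lam_true); rho <- rho / pracma::trapz(zg, rho)
  z <- sample_from_profile(tibble::tibble(z = zg, rho = rho), 5e4)
  prof <- density_profile(z, H = H, bin_width = 0.5)
  fit <- fit_sedimentation_length(prof, R = 1)
  expect_equal(fit$lambda, lam_true, tolerance = 3 * fit$se / lam_true + 0.02)
  expect_true(fit$ok)
})

test_that("sedimentation-length fit is exact on noiseless data and scale-equivariant", {
  z <- seq(0.25, 80, by = 0.5)
  prof <- tibble::tibble(z = z, rho = exp(-z / 10) / 10)
  fit <- fit_sedimentation_length(prof, fit_range = c(4, 60))
  expect_equal(fit$lambda, 10, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # rescale z by c = 2.5: lambda scales by exactly c
  z2 <- 2.5 * z
  prof2 <- tibble::tibble(z = z2, rho = exp(-z2 / 25) / 25)
  fit2 <- fit_sedimentation_length(prof2, fit_range = c(10, 150))
  expect_equal(fit2$lambda, 25, tolerance = 1e-10)
  # two-slope profile is flagged as non-exponential
  rho_piece <- ifelse(z < 40, exp(-z / 5), exp(-40 / 5) * exp(-(z - 40) / 40))
  fitp <- fit_sedimentation_length(tibble::tibble(z = z, rho = rho_piece),
                                   fit_range = c(4, 75))
  expect_false(fitp$ok)
  # broom-style accessors
  expect_named(tidy(fit), c("term", "estimate", "std.error"))
  expect_true(glance(fit)$exponential.ok)
})

test_that("steady-state detector finds changepoints and rejects drifting series", {
  tt <- seq_len(3000)
  expect_true(detect_steady_state(tibble::tibble(t = tt, h = rep(5, 3000)),
                                  window = 100)$converged)
  expect_equal(detect_steady_state(tibble::tibble(t = tt, h = rep(5, 3000)),
                                   window = 100)$start, 1)
  # monotone decay to a plateau at t = 1000
  set.seed(121)
  h <- ifelse(tt < 1000, 20 * exp(-(tt) / 250) + 10, 10) * (1 + rnorm(3000, 0, 0.005))
  ss <- detect_steady_state(tibble::tibble(t = tt, h = h), window = 200, tol = 0.05)
  expect_true(ss$converged)
  expect_gt(ss$start, 500); expect_lt(ss$start, 1200)
  # 10% oscillation never satisfies a 5% criterion
  h_osc <- 10 * (1 + 0.1 * sin(tt / 20))
  expect_false(detect_steady_state(tibble::tibble(t = tt, h = h_osc),
                                   window = 200, tol = 0.05)$converged)
})

test_that("layering detector measures the 2R comb and ignores pure exponentials", {
  z <- seq(0.05, 40, by = 0.1)
  comb <- exp(-z / 12) * (1 + 4 * (exp(-(z - 2)^2 / 0.18) + exp(-(z - 4)^2 / 0.18) +
                                     exp(-(z - 6)^2 / 0.18)))
  lay <- detect_layering(tibble::tibble(z = z, rho = comb / pracma::trapz(z, comb)),
                         R = 1)
  expect_equal(length(lay$peaks), 3)
  expect_equal(lay$mean_spacing, 2, tolerance = 0.05)
  lay0 <- detect_layering(tibble::tibble(z = z, rho = exp(-z / 12) / 12), R = 1)
  expect_lte(length(lay0$peaks), 1)
  expect_true(is.na(lay0$mean_spacing) || length(lay0$spacing) == 0)
})

test_that("supernatant metrics: exponential gives zero, shelf is measured, uniform spans", {
  H <- 80
  z <- seq(0.25, H, by = 0.5)
  # pure exponential: no supernatant
  sn0 <- supernatant_metrics(tibble::tibble(z = z, rho = exp(-z / 10) / 10))
  expect_equal(sn0$X_sn, 0)
  # exponential + constant shelf on [30, 50], zero above
  shelf <- 0.9 * exp(-z / 5) / (5 * (1 - exp(-30 / 5))) * (z < 30) +
    0.1 / 20 * (z >= 30 & z <= 50)
  sn1 <- supernatant_metrics(tibble::tibble(z = z, rho = shelf))
  expect_equal(sn1$X_sn, 0.1, tolerance = 0.03)
  expect_equal(sn1$plateau[1], 30, tolerance = 1)
  expect_equal(sn1$plateau[2], 50, tolerance = 1)
  expect_equal(sn1$zeta0, 50, tolerance = 1)
  # uniform profile: plateau spans the box
  snu <- supernatant_metrics(tibble::tibble(z = z, rho = rep(1 / H, length(z))))
  expect_equal(snu$X_sn, 1, tolerance = 0.02)
  expect_equal(snu$zeta0, H, tolerance = 0.5)
})

test_that("supernatant of a constant-lambda Smoluchowski profile is zero", {
  for (lam in c(3, 10, 40)) {
    z <- seq(0, 80, by = 0.25)
    rho <- steady_density(tibble::tibble(z = z, lambda_eff = rep(lam, length(z))))
    expect_equal(supernatant_metrics(rho)$X_sn, 0)
  }
})

test_that("orientation statistics normalise, factorise and expose conditionals", {
  set.seed(131)
  n <- 5e4
  z <- rexp(n, 1 / 10); z <- z[z < 80]
  E <- tumble_orientation(length(z))
  d <- tibble::tibble(z = z, ez = E[, 3])
  os <- orientation_statistics(d, H = 80, bin_width = 2, e_bins = 10,
                               z_stars = c(2, 30))
  dz <- 2; de <- 2 / 10
  expect_equal(sum(os$joint$p) * dz * de, 1, tolerance = 1e-8)
  # conditionals integrate to one over ez
  for (zs in c(2, 30)) {
    pc <- os$conditionals$p[os$conditionals$z_star == zs]
    expect_equal(sum(pc) * de, 1, tolerance = 1e-8)
  }
  # isotropic orientations: conditional flat in ez
  pc <- os$conditionals$p[os$conditionals$z_star == 2]
  n2 <- round(pc * de * sum(d$z >= 2 & d$z < 4))
  expect_gt(chisq.test(n2)$p.value, 0.01)
  # marginal over ez equals the density profile bin-for-bin
  prof <- density_profile(d, H = 80, bin_width = 2)
  expect_equal(os$marginal_z$rho, prof$rho, tolerance = 1e-12)
  # fully aligned orientations concentrate in the top ez bin
  os_up <- orientation_statistics(tibble::tibble(z = z, ez = rep(1, length(z))),
                                  H = 80, bin_width = 2, e_bins = 10)
  top <- os_up$joint[os_up$joint$ez > 0.8, ]
  expect_equal(sum(top$p) * dz * de, 1, tolerance = 1e-8)
  # empty z* bin flagged missing
  os_m <- orientation_statistics(d[d$z < 40, ], H = 80, bin_width = 2,
                                 z_stars = 70)
  expect_true(all(os_m$conditionals$missing))
})

test_that("sedimenting run-and-tumble suspensions develop height-dependent polar order", {
  # long run length: downward-oriented near the wall, upward in the bulk
  set.seed(141)
  sw <- unit_swimmer(tau = 30)       # ell* = 30
  env <- unit_env(Fg = 0.25)         # chi1 = 4, lambda_theory = 10
  box <- box_geometry(L = 40, H = 100, R = 1, N = 800)
  burn <- simulate_rtp(sw, env, box, dt = 0.25, n_steps = 3000, record_stride = 1e6)
  run <- simulate_rtp(sw, env, box, dt = 0.25, n_steps = 5000, record_stride = 50,
                      init = burn$state)
  os <- orientation_statistics(run$trajectory, H = 100, bin_width = 2,
                               z_stars = c(2, 30))
  m <- os$polar_order
  near_wall <- m$m[m$z <= 4 & m$count > 100]
  bulk <- m$m[m$z >= 20 & m$z <= 40 & m$count > 100]
  expect_lt(mean(near_wall), 0)
  expect_gt(mean(bulk), 0)
})

test_that("short-run-length steady state approximately factorises P(z, ez)", {
  set.seed(151)
  sw <- unit_swimmer(tau = 1)        # ell* = 1, fast tumbling
  env <- unit_env(Fg = 0.1)
  box <- box_geometry(L = 30, H = 60, R = 1, N = 600)
  burn <- simulate_rtp(sw, env, box, dt = 0.05, n_steps = 4000, record_stride = 1e6)
  run <- simulate_rtp(sw, env, box, dt = 0.05, n_steps = 4000, record_stride = 40,
                      init = burn$state)
  os <- orientation_statistics(run$trajectory, H = 60, bin_width = 3, e_bins = 5)
  # compare joint to product of marginals where occupied: correlation-free
  dz <- 3; de <- 2 / 5
  marg_e <- tapply(os$joint$p * dz, os$joint$ez, sum)
  joint_wide <- matrix(os$joint$p, nrow = length(unique(os$joint$z)))
  pred <- outer(os$marginal_z$rho, as.vector(marg_e))
  sel <- os$marginal_z$rho > 0.005
  rel <- abs(joint_wide[sel, ] - pred[sel, ]) / max(pred)
  expect_lt(max(rel), 0.15)
})
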