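test_that("constant lambda reproduces the closed-form truncated exponential", {
  z <- seq(0, 80, by = 0.25)
  lam <- lambda_eff_profile(fluctuation_profile(z, rep(0, length(z))),
                            mode = "swimmer", v_ref = 1, lambda_1p = 10)
  expect_equal(lam$lambda_eff, rep(10, length(z)))   # sigma2 = 0 collapses to 1p
  rho <- steady_density(lam)
  rho_exact <- exp(-z / 10) / (10 * (1 - exp(-80 / 10)))
  # trapezoid normalisation carries O(dz^2); the shape itself is exact
  expect_equal(rho$rho, rho_exact, tolerance = 1e-4)
  expect_equal(pracma::trapz(rho$z, rho$rho), 1, tolerance = 1e-8)
  expect_equal(attr(rho, "h"), exp_mean_height(10, 80), tolerance = 5e-4)
})

test_that("variable lambda matches the adaptive-quadrature oracle", {
  H <- 60
  z <- seq(0, H, by = 0.1)
  lam_fun <- function(s) 8 * (1 + s / H)
  lam <- tibble::tibble(z = z, lambda_eff = lam_fun(z))
  rho <- steady_density(lam)
  expect_equal(rho$rho, steady_density_oracle(lam_fun, z, H), tolerance = 1e-4)
})

test_that("solver matches the oracle on random smooth profiles", {
  set.seed(61)
  H <- 40
  z <- seq(0, H, by = 0.05)
  for (rep in 1:20) {
    a <- runif(1, 3, 15); b <- runif(1, -0.5, 2); cfreq <- runif(1, 0.5, 2)
    amp <- runif(1, 0, 0.3)
    lam_fun <- function(s) a * (1 + pmax(b, 0) * s / H + amp * sin(cfreq * 2 * pi * s / H)^2)
    rho <- steady_density(tibble::tibble(z = z, lambda_eff = lam_fun(z)))
    expect_lt(max(abs(rho$rho - steady_density_oracle(lam_fun, z, H)) / max(rho$rho)),
              1e-4)
  }
})

test_that("swimmer-mode lambda_eff follows lambda_1p (1 + alpha sigma2 / v_p^2)", {
  z <- seq(0, 20, by = 0.5)
  s2 <- ifelse(abs(z - 10) < 0.25, 4, 0)   # sigma2 = v_p^2 at one height
  lam <- lambda_eff_profile(fluctuation_profile(z, s2), mode = "swimmer",
                            alpha = 1, v_ref = 2, lambda_1p = 5)
  expect_equal(lam$lambda_eff[z == 10], 10)      # doubled where sigma2 = v_p^2
  expect_equal(lam$lambda_eff[z == 0], 5)
})

test_that("shaker mode has no single-particle contribution and flags collapse", {
  z <- seq(0, 20, by = 0.5)
  lam <- lambda_eff_profile(fluctuation_profile(z, 0.09 * exp(-z / 5)),
                            mode = "shaker", alpha = 4.4, v_ref = 0.3, ell_T = 1)
  expect_equal(lam$lambda_eff, 4.4 * 1 * 0.09 * exp(-z / 5) / 0.09, tolerance = 1e-12)
  expect_warning(
    lam0 <- lambda_eff_profile(fluctuation_profile(z, rep(0, length(z))),
                               mode = "shaker", alpha = 4.4, v_ref = 0.3),
    "collapse")
  expect_true(attr(lam0, "degenerate"))
  # floored solver still returns a finite, normalised (delta-like) profile
  rho0 <- steady_density(lam0)
  expect_true(all(is.finite(rho0$rho)))
  expect_true(attr(rho0, "degenerate"))
})

test_that("supernatant-like distal flattening follows d ln rho / dz = -1/lambda", {
  H <- 50
  z <- seq(0, H, by = 0.1)
  lam_eff <- ifelse(z < 30, 5, 400)
  rho <- steady_density(tibble::tibble(z = z, lambda_eff = lam_eff))
  lr <- log(rho$rho)
  slope_distal <- abs(diff(lr[z > 35]) / 0.1)
  expect_true(all(slope_distal < 1 / 300))
})

test_that("density is monotone non-increasing and mean height orders with sigma2", {
  set.seed(71)
  H <- 40
  z <- seq(0, H, by = 0.2)
  for (rep in 1:10) {
    s2a <- runif(1, 0, 2) * exp(-z / runif(1, 5, 20))
    s2b <- s2a + runif(1, 0.1, 1)   # pointwise larger fluctuations
    ra <- steady_density(lambda_eff_profile(fluctuation_profile(z, s2a),
                                            "swimmer", alpha = 1, v_ref = 1, lambda_1p = 6))
    rb <- steady_density(lambda_eff_profile(fluctuation_profile(z, s2b),
                                            "swimmer", alpha = 1, v_ref = 1, lambda_1p = 6))
    expect_true(all(diff(ra$rho) <= 1e-12))
    expect_gt(attr(rb, "h"), attr(ra, "h"))
  }
})

test_that("alpha recovery: round trip through steady_density is exact to 1%", {
  z <- seq(0, 80, by = 0.5)
  fl <- generate_synthetic_sigma2("exponential_decay", z, sigma0_sq = 0.5,
                                  ell_sigma = 20)
  for (mode in c("swimmer", "shaker")) for (a_true in c(1, 4.4)) {
    lam <- lambda_eff_profile(fl, mode, alpha = a_true, v_ref = 1,
                              lambda_1p = if (mode == "swimmer") 15 else NULL,
                              ell_T = 1)
    obs <- steady_density(lam)
    fit <- fit_alpha(obs, fl, mode = mode, v_ref = 1,
                     lambda_1p = if (mode == "swimmer") 15 else NULL, ell_T = 1)
    expect_equal(fit$alpha, a_true, tolerance = 0.01)
  }
})

test_that("alpha recovery is unbiased under multiplicative profile noise", {
  set.seed(81)
  z <- seq(0, 80, by = 1)
  fl <- generate_synthetic_sigma2("exponential_decay", z, sigma0_sq = 1, ell_sigma = 25)
  lam <- lambda_eff_profile(fl, "swimmer", alpha = 2, v_ref = 1, lambda_1p = 12)
  clean <- steady_density(lam)
  alphas <- vapply(1:100, function(i) {
    noisy <- tibble::tibble(z = clean$z, rho = clean$rho * exp(rnorm(length(z), 0, 0.05)))
    fit_alpha(noisy, fl, mode = "swimmer", v_ref = 1, lambda_1p = 12)$alpha
  }, numeric(1))
  se <- sd(alphas) / sqrt(100)
  expect_lt(abs(mean(alphas) - 2), 3 * se + 1e-3)
})

test_that("swimmer model with sigma2 -> 0 closes the loop with the dry engine", {
  set.seed(91)
  sw <- unit_swimmer(tau = 3)
  env <- unit_env(Fg = 0.125)                  # chi1 = 8
  lam_1p <- effective_temperature_1p(sw, env)  # = 8 by Eq.-form v_p^2 tau/(3 vg)
  H <- 60
  box <- box_geometry(L = 30, H = H, R = 1, N = 800)
  burn <- simulate_rtp(sw, env, box, dt = 0.15, n_steps = 6000, record_stride = 1e6)
  run <- simulate_rtp(sw, env, box, dt = 0.15, n_steps = 4000, record_stride = 40,
                      init = burn$state)
  prof <- density_profile(run$trajectory, H = H, bin_width = 0.5)
  fit <- fit_sedimentation_length(prof, fit_range = c(10, 45))
  z <- seq(0, H, by = 0.25)
  model <- steady_density(lambda_eff_profile(
    fluctuation_profile(z, rep(0, length(z))), "swimmer",
    v_ref = 1, lambda_1p = lam_1p))
  model_fit <- fit_sedimentation_length(model, fit_range = c(10, 45))
  expect_equal(fit$lambda, model_fit$lambda, tolerance = 0.08)
})

test_that("fit_alpha rejects starved inputs", {
  z <- seq(0, 10, by = 2.5)
  fl <- generate_synthetic_sigma2("constant", z, sigma0_sq = 1)
  obs <- tibble::tibble(z = z, rho = exp(-z / 3))
  expect_error(fit_alpha(obs[1:3, ], fl, mode = "swimmer", v_ref = 1, lambda_1p = 3),
               "fewer than 5")
})
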