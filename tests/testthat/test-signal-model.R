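test_that("Beer-Lambert transform honours its contract", {
  expect_equal(beer_lambert(1), 0)
  expect_equal(beer_lambert(exp(-1)), 68)
  # monotone decreasing in intensity
  I <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(beer_lambert(I)) < 0))
  expect_error(beer_lambert(0), "positive")
  expect_error(beer_lambert(-0.2), "positive")
  expect_error(beer_lambert(1.5), "normalize")
})

test_that("noiseless harmonic series is recovered exactly", {
  t <- (0:74) / 25
  des <- harmonic_design(t, 1.0)
  omega <- 2 * pi
  y <- 5 + 2 * sin(omega * t) + 1 * cos(omega * t)
  fit <- fit_pixel(y, des)
  expect_equal(unname(fit$coef[1:5]), c(5, 2, 1, 0, 0), tolerance = 1e-9)
  expect_equal(fit$rho, 0, tolerance = 1e-9)
  expect_lt(max(fit$se), 1e-6)
  expect_true(fit$converged)
  expect_equal(fit$phase, atan2(1, 2), tolerance = 1e-9)
  # broken-stick slopes are recovered too
  drift <- 0.5 * pmin(t, 1) - 0.3 * pmin(pmax(t - 1, 0), 1) +
    0.2 * pmax(t - 2, 0)
  fit2 <- fit_pixel(y + drift, des)
  slopes <- cumsum(fit2$coef[c("trend1", "trend2", "trend3")])
  expect_equal(unname(slopes), c(0.5, -0.3, 0.2), tolerance = 1e-8)
})

test_that("GLS with rho fixed at zero equals the OLS oracle", {
  t <- (0:74) / 25
  des <- harmonic_design(t, 1.0)
  set.seed(20)
  for (k in 1:20) {
    y <- rnorm(1, 10, 3) + as.numeric(des$X[, -1] %*% rnorm(7)) + rnorm(75)
    fit <- fit_pixel(y, des, rho = 0)
    oracle <- coef(lm(y ~ des$X - 1))
    expect_equal(unname(fit$coef), unname(oracle), tolerance = 1e-8)
  }
})

test_that("AR(1) coefficient is estimated with acceptable small-sample bias", {
  t <- (0:74) / 25
  des <- harmonic_design(t, 1.0)
  omega <- 2 * pi
  signal <- 30 + 4 * sin(omega * t) + 2 * cos(omega * t)
  set.seed(21)
  rho_hat <- replicate(500, {
    fit_pixel(signal + ar1_noise(75, 0.6, 1), des)$rho
  })
  expect_lt(abs(mean(rho_hat) - 0.6), 0.15)
})

test_that("feasible GLS agrees with the nlme maximum-likelihood oracle", {
  skip_if_not_installed("nlme")
  t <- (0:74) / 25
  des <- harmonic_design(t, 1.0)
  omega <- 2 * pi
  set.seed(22)
  y <- 30 + 4 * sin(omega * t) + 2 * cos(omega * t) + ar1_noise(75, 0.5, 0.8)
  fit <- fit_pixel(y, des)
  df <- data.frame(y = y, des$X[, -1])
  gfit <- nlme::gls(y ~ sin1 + cos1 + sin2 + cos2 + trend1 + trend2 + trend3,
                    data = df, correlation = nlme::corAR1())
  # different rho estimators (lag-1 FGLS vs ML), so coefficients agree
  # loosely and the phase closely
  expect_equal(unname(fit$coef), unname(coef(gfit)), tolerance = 0.05)
  expect_equal(fit$phase, atan2(coef(gfit)["cos1"], coef(gfit)["sin1"]),
               tolerance = 0.02, ignore_attr = TRUE)
})

test_that("phase is equivariant under time shifts", {
  t <- (0:74) / 25
  des <- harmonic_design(t, 1.0)
  omega <- 2 * pi
  base <- fit_pixel(30 + 3 * sin(omega * t), des)
  wrap <- function(a) atan2(sin(a), cos(a))
  for (delta in c(0.1, 0.25, 0.4)) {
    sh <- fit_pixel(30 + 3 * sin(omega * (t - delta)), des)
    expect_equal(wrap(sh$phase - base$phase), wrap(-omega * delta),
                 tolerance = 1e-8)
  }
})

test_that("pulse amplitude matches closed forms and a fine-grid oracle", {
  mk <- function(a1, b1, a2, b2) {
    structure(list(coef = c(intercept = 0, sin1 = a1, cos1 = b1,
                            sin2 = a2, cos2 = b2)),
              class = "harmonic_fit")
  }
  expect_equal(pulse_amplitude(mk(2, 0, 0, 0)), 4, tolerance = 1e-8)
  expect_equal(pulse_amplitude(mk(0, 0, 0, 3)), 6, tolerance = 1e-8)
  th <- seq(0, 2 * pi, length.out = 1e6)
  v <- sin(th) + cos(th) + 0.5 * sin(2 * th)
  expect_equal(pulse_amplitude(mk(1, 1, 0.5, 0)), max(v) - min(v),
               tolerance = 1e-4)
  # invariant under phase rotation of (a1, b1) at fixed R
  amps <- sapply(seq(0, 2 * pi, length.out = 9), function(ph) {
    pulse_amplitude(mk(3 * cos(ph), 3 * sin(ph), 0, 0))
  })
  expect_equal(amps, rep(6, 9), tolerance = 1e-8)
})

test_that("phase CI collapses for zero SE and stays on the estimate's branch", {
  t <- (0:74) / 25
  des <- harmonic_design(t, 1.0)
  omega <- 2 * pi
  fit <- fit_pixel(30 + 2 * sin(omega * t) + 1 * cos(omega * t), des)
  ci <- phase_ci(fit, seed = 1)
  expect_equal(ci$width, 0, tolerance = 1e-9)
  expect_equal(ci$lo, fit$phase, tolerance = 1e-9)
  # estimate near +pi: CI must not wrap to -pi
  fitp <- fit_pixel(30 + 3 * sin(omega * t + pi - 0.01) +
                      ar1_noise(75, 0, 0.2), des)
  expect_gt(abs(fitp$phase), 3)
  cip <- phase_ci(fitp, seed = 2)
  expect_true(cip$lo <= fitp$phase && fitp$phase <= cip$hi)
  expect_lt(cip$width, 1)
  # degenerate zero-amplitude fit is flagged
  fit0 <- fit
  fit0$coef[c("sin1", "cos1")] <- 0
  expect_true(phase_ci(fit0)$degenerate)
})

test_that("CI width shrinks with signal-to-noise ratio", {
  t <- (0:74) / 25
  des <- harmonic_design(t, 1.0)
  omega <- 2 * pi
  set.seed(30)
  widths <- sapply(c(0.5, 2, 8), function(A) {
    median(replicate(20, {
      fit <- fit_pixel(30 + A * sin(omega * t) + ar1_noise(75, 0.3, 0.6), des)
      phase_ci(fit, n_mc = 400)$width
    }))
  })
  expect_true(all(diff(widths) < 0))
})

test_that("cardiac period can be estimated from the path-averaged signal", {
  truth <- wave_ground_truth(seed = 12, noise_sd = 0.3)
  s <- generate_series(truth)
  expect_equal(estimate_cardiac_period(s), 1.0, tolerance = 0.05)
})

test_that("rank-deficient and short designs are rejected", {
  expect_error(harmonic_design((0:5) / 25, 1.0), "9 frames")
  t <- (0:74) / 25
  des <- harmonic_design(t, 1.0)
  expect_error(fit_pixel(rnorm(10), des), "match")
})
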