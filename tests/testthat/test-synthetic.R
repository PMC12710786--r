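test_that("analytic phase profile has the advertised slopes and continuity", {
  truth <- noiseless_truth()
  x <- seq(0, 0.59, by = 0.01)
  psi <- phase_profile_truth(truth, x)
  expect_equal(psi[1], 0)
  # slope = 2*pi/(T*v) on each branch
  expect_equal(diff(psi[x <= 0.40]) / 0.01,
               rep(2 * pi / (1 * -30), sum(x <= 0.40) - 1), tolerance = 1e-9)
  # v = -20 mm/s, T = 1 s gives -0.3142 rad/mm
  t20 <- wave_ground_truth(speed_retro = -20, noise_sd = 0)
  p20 <- phase_profile_truth(t20, x)
  expect_equal((p20[2] - p20[1]) / 0.01, -pi / 10, tolerance = 1e-12)
  # continuity at the knot: both branches give the same value at x_turn
  expect_equal(phase_profile_truth(truth, c(0, 0.40))[2],
               psi[which(x == 0.40)])
})

test_that("OLS refit on each branch recovers the analytic slopes", {
  truth <- wave_ground_truth(speed_retro = -30, speed_antero = 20,
                             x_turn = 0.4, noise_sd = 0)
  x <- seq(0, 0.8, by = 0.005)
  psi <- phase_profile_truth(truth, x)
  down <- x <= 0.4; up <- x >= 0.4
  s_down <- coef(lm(psi[down] ~ x[down]))[2]
  s_up <- coef(lm(psi[up] ~ x[up]))[2]
  expect_equal(unname(s_down), 2 * pi / -30, tolerance = 1e-12)
  expect_equal(unname(s_up), 2 * pi / 20, tolerance = 1e-12)
})

test_that("phase profile rejects a turning point outside the path", {
  truth <- noiseless_truth()
  expect_error(phase_profile_truth(truth, seq(0.45, 0.59, 0.01)),
               "outside")
  expect_error(wave_ground_truth(x_turn = 2), "outside")
})

test_that("noiseless series is a pure scaled sinusoid per pixel", {
  truth <- noiseless_truth(h2_ratio = 0)
  s <- generate_series(truth)
  A <- truth$amp_peak *
    exp(-(s$distance_mm - truth$amp_mu)^2 / (2 * truth$amp_sigma^2))
  ptp <- apply(s$series, 1, function(v) max(v) - min(v))
  # 75 samples per 3 cycles: grid misses the crest by at most half a step
  expect_equal(ptp, 2 * A, tolerance = 1e-2)
  expect_equal(rowMeans(s$series), rep(truth$baseline, truth$n_pixels),
               tolerance = 1e-10)
})

test_that("AR(1) noise matches its closed forms", {
  set.seed(7)
  e0 <- ar1_noise(3000, rho = 0, sd = 1)
  r1 <- cor(e0[-1], e0[-3000])
  expect_lt(abs(r1), 0.1)
  set.seed(8)
  e5 <- ar1_noise(10000, rho = 0.5, sd = 1)
  expect_equal(var(e5), 1 / (1 - 0.25), tolerance = 0.05)
  expect_equal(cor(e5[-1], e5[-10000]), 0.5, tolerance = 0.05)
})

test_that("generation is fully deterministic under a fixed seed", {
  t1 <- wave_ground_truth(seed = 99)
  expect_identical(generate_series(t1)$series, generate_series(t1)$series)
  t2 <- wave_ground_truth(seed = 100)
  expect_false(identical(generate_series(t1)$series,
                         generate_series(t2)$series))
})

test_that("series CSV + JSON sidecar round-trips", {
  truth <- wave_ground_truth(seed = 3)
  s <- generate_series(truth)
  path <- file.path(tempdir(), "series.csv")
  write_series_csv(s, path)
  s2 <- read_series_csv(path)
  expect_equal(s2$series, s$series, tolerance = 1e-12)
  expect_equal(s2$distance_mm, s$distance_mm)
  expect_equal(s2$truth$speed_retro, truth$speed_retro)
  expect_equal(s2$cardiac_period, truth$cardiac_period)
  unlink(c(path, sub("csv$", "json", path)))
})

test_that("rendering with zero jitter and constant series gives identical frames", {
  truth <- noiseless_truth(amp_peak = 0, drift_slopes = c(0, 0, 0))
  scene <- render_test_scene(truth)
  f <- scene$stack$frames
  for (k in seq_along(f)[-1]) expect_identical(f[[k]], f[[1]])
})

test_that("Beer-Lambert transform inverts the rendering on centerline pixels", {
  scene <- render_test_scene()
  stack <- scene$stack
  max_val <- 2^stack$bit_depth - 1
  cl <- scene$centerline
  rec <- vapply(stack$frames, function(fr) fr[cl], numeric(nrow(cl)))
  rec <- beer_lambert(rec / max_val)
  # quantization to 1 gray level propagates through -68*log(I)
  I <- exp(-scene$series$series / 68)
  max_err <- 68 * (0.5 / max_val) / min(I)
  expect_lt(max(abs(rec - scene$series$series)), 2 * max_err)
})

test_that("vessel curves leaving the frame are rejected", {
  expect_error(vessel_geometry(frame_dim = c(40, 50), start = c(20, 10),
                               n_pixels = 60), "bounds")
  expect_error(vessel_geometry(amplitude_px = 10, period_px = 20), "steep")
})

test_that("ground-truth configs round-trip through YAML and JSON", {
  skip_if_not_installed("yaml")
  cfg <- list(speed_retro = -25, speed_antero = 18, x_turn = 0.35, seed = 9)
  yml <- file.path(tempdir(), "truth.yaml")
  yaml::write_yaml(cfg, yml)
  tr <- read_truth_config(yml)
  expect_equal(tr$speed_retro, -25)
  expect_equal(tr$x_turn, 0.35)
  expect_equal(tr$fps, 25)  # defaults fill in
  jsn <- file.path(tempdir(), "truth.json")
  jsonlite::write_json(cfg, jsn, auto_unbox = TRUE)
  expect_equal(read_truth_config(jsn)$speed_antero, 18)
  bad <- file.path(tempdir(), "bad.json")
  jsonlite::write_json(list(nonsense = 1), bad, auto_unbox = TRUE)
  expect_error(read_truth_config(bad), "unknown config fields")
  unlink(c(yml, jsn, bad))
})

test_that("frames and masks round-trip through TIFF and PNG", {
  skip_if_not_installed("tiff")
  skip_if_not_installed("png")
  scene <- render_test_scene()
  tif <- file.path(tempdir(), "frames.tif")
  write_frames_tiff(scene$stack, tif)
  back <- read_frame_stack(tif, fps = scene$stack$fps)
  expect_equal(length(back$frames), length(scene$stack$frames))
  expect_equal(back$frames[[3]], scene$stack$frames[[3]], tolerance = 0.51)
  msk <- file.path(tempdir(), "vein.png")
  write_mask_png(scene$vein_mask, msk)
  expect_equal(png::readPNG(msk) != 0, scene$vein_mask,
               ignore_attr = TRUE)
  unlink(c(tif, msk))
})
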