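# shared fixtures: all synthetic, built in code at test time

# clean two-wave truth used by the exactness tests
noiseless_truth <- function(...) {
  args <- utils::modifyList(list(noise_sd = 0, rho = 0,
                                 drift_slopes = c(0, 0, 0), seed = 1),
                            list(...))
  do.call(wave_ground_truth, args)
}

# separable Gaussian blur with replicate padding (for sharpness fixtures)
gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- ceiling(3 * sigma)
  k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
  pad_conv <- function(v) {
    vp <- c(rep(v[1], r), v, rep(v[length(v)], r))
    as.numeric(stats::filter(vp, k, sides = 2))[(r + 1):(r + length(v))]
  }
  out <- apply(img, 2, pad_conv)
  t(apply(out, 1, pad_conv))
}

# directed Hausdorff distance between two point sets (n x 2 matrices)
hausdorff <- function(a, b) {
  one_way <- function(p, q) {
    max(vapply(seq_len(nrow(p)), function(i) {
      sqrt(min((q[, 1] - p[i, 1])^2 + (q[, 2] - p[i, 2])^2))
    }, numeric(1)))
  }
  max(one_way(a, b), one_way(b, a))
}

# small rendered scene shared by the preprocessing tests
render_test_scene <- function(truth = noiseless_truth(),
                              jitter_translate_px = 0, jitter_rotate_deg = 0,
                              seed = 42, amplitude_px = 4) {
  series <- generate_series(truth)
  geom <- vessel_geometry(frame_dim = c(72, 90), start = c(36, 12),
                          n_pixels = truth$n_pixels,
                          amplitude_px = amplitude_px, period_px = 90,
                          width_px = 3, disc_center = c(36, 8),
                          disc_radius_px = 30)
  scene <- render_frames(series, geom,
                         jitter_translate_px = jitter_translate_px,
                         jitter_rotate_deg = jitter_rotate_deg, seed = seed)
  scene$series <- series
  scene
}
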