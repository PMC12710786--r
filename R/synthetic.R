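#' Ground truth for a synthetic two-wave scene
#'
#' Defines the generative model for per-centerline-pixel blood-column
#' intensity over exactly three cardiac cycles: two opposing pulse waves
#' whose first-harmonic phase varies linearly with distance at two signed
#' slopes meeting at a turning point, a Gaussian pulse-amplitude hump,
#' a continuous piecewise-linear (broken-stick) inter-cycle lighting drift,
#' and AR(1) noise.
#'
#' Sign semantics follow venous flow on the optic disc: blood flows from
#' the periphery toward the disc center, i.e. toward the start of the
#' centerline path. A wave travelling toward increasing centerline distance
#' is therefore retrograde to flow and carries a negative signed velocity;
#' a wave travelling with flow (toward the path start) is anterograde and
#' positive. Under the phase-lead convention used throughout the package
#' (first harmonic \code{a*sin(wt) + b*cos(wt) = R*sin(wt + psi)},
#' \code{psi = atan2(b, a)}), a wave with signed velocity \code{v} produces
#' a phase profile of slope \code{2*pi/(T*v)} radians/mm, so the retrograde
#' wave yields the initial down trend and the anterograde wave the
#' subsequent up trend with no sign patching.
#'
#' @param speed_retro Signed velocity of the retrograde wave (mm/s), must be
#'   negative (wave travels toward increasing centerline distance).
#' @param speed_antero Signed velocity of the anterograde wave (mm/s), must
#'   be positive.
#' @param x_turn Meeting point of the two waves (mm along the centerline).
#' @param amp_peak Peak of the Gaussian pulse-amplitude hump
#'   (blood-column units).
#' @param amp_mu,amp_sigma Center and standard deviation of the amplitude
#'   hump (mm); \code{amp_sigma > 0}.
#' @param baseline Constant baseline blood-column level added to every pixel.
#' @param cardiac_period Cardiac period T in seconds.
#' @param h2_ratio Second-to-first harmonic amplitude ratio.
#' @param drift_slopes Numeric vector of three per-cycle linear trend slopes
#'   (blood-column units per second); the drift is continuous at the cycle
#'   boundaries t = T and t = 2T.
#' @param rho AR(1) coefficient of the noise, in [0, 1).
#' @param noise_sd Innovation standard deviation of the AR(1) noise.
#' @param n_pixels Number of centerline pixels.
#' @param fps Frame rate (frames per second); \code{3 * cardiac_period * fps}
#'   must be a whole number of frames.
#' @param mm_per_px Centerline pixel spacing in mm.
#' @param seed Optional integer seed stored with the truth and used by
#'   [generate_series()].
#'
#' @return An object of class \code{wave_ground_truth}.
#' @seealso [generate_series()], [phase_profile_truth()], [render_frames()]
#' @export
wave_ground_truth <- function(speed_retro = -30, speed_antero = 20,
                              x_turn = 0.40,
                              amp_peak = 6, amp_mu = 0.30, amp_sigma = 0.20,
                              baseline = 30,
                              cardiac_period = 1.0, h2_ratio = 0.3,
                              drift_slopes = c(0.5, -0.3, 0.2),
                              rho = 0.3, noise_sd = 0.06,
                              n_pixels = 60, fps = 25, mm_per_px = 0.01,
                              seed = NULL) {
  stopifnot(is.numeric(speed_retro), is.numeric(speed_antero))
  if (speed_retro >= 0)
    stop("speed_retro must be negative (retrograde wave travels toward increasing distance)")
  if (speed_antero <= 0)
    stop("speed_antero must be positive (anterograde wave travels with flow)")
  if (cardiac_period <= 0) stop("cardiac_period must be positive")
  if (fps <= 0) stop("fps must be positive")
  if (amp_sigma <= 0) stop("amp_sigma must be positive")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (length(drift_slopes) != 3) stop("drift_slopes must have one slope per cycle (3)")
  if (n_pixels < 2) stop("need at least 2 centerline pixels")
  if (mm_per_px <= 0) stop("mm_per_px must be positive")
  n_frames <- 3 * cardiac_period * fps
  if (abs(n_frames - round(n_frames)) > 1e-9)
    stop("3 * cardiac_period * fps must be a whole number of frames")
  n_frames <- as.integer(round(n_frames))
  x_max <- (n_pixels - 1) * mm_per_px
  if (x_turn < 0 || x_turn > x_max)
    stop("x_turn lies outside the centerline path [0, ", format(x_max), "] mm; ",
         "configuration unusable")
  structure(list(
    speed_retro = speed_retro, speed_antero = speed_antero, x_turn = x_turn,
    amp_peak = amp_peak, amp_mu = amp_mu, amp_sigma = amp_sigma,
    baseline = baseline, cardiac_period = cardiac_period,
    h2_ratio = h2_ratio, drift_slopes = drift_slopes,
    rho = rho, noise_sd = noise_sd,
    n_pixels = as.integer(n_pixels), n_frames = n_frames,
    fps = fps, mm_per_px = mm_per_px, seed = seed
  ), class = "wave_ground_truth")
}

#' @export
print.wave_ground_truth <- function(x, ...) {
  cat("Two-wave ground truth\n")
  cat(sprintf("  speeds: retro %.2f / antero %.2f mm/s, meeting at %.3f mm\n",
              x$speed_retro, x$speed_antero, x$x_turn))
  cat(sprintf("  amplitude hump: peak %.2f at %.3f mm (sigma %.3f mm), baseline %.2f\n",
              x$amp_peak, x$amp_mu, x$amp_sigma, x$baseline))
  cat(sprintf("  %d pixels x %d frames, fps %.1f, T %.2f s, %.4f mm/px\n",
              x$n_pixels, x$n_frames, x$fps, x$cardiac_period, x$mm_per_px))
  cat(sprintf("  AR(1): rho %.2f, innovation sd %.3f; h2 ratio %.2f\n",
              x$rho, x$noise_sd, x$h2_ratio))
  invisible(x)
}

#' Analytic phase profile of the two-wave ground truth
#'
#' Piecewise-linear first-harmonic phase along the centerline: slope
#' \code{2*pi/(T*v)} on each side of the meeting point, continuous there,
#' and anchored so the first pixel has phase zero.
#'
#' @param truth A [wave_ground_truth()] object.
#' @param x Strictly increasing distances (mm) at which to evaluate.
#' @return Phase in radians, same length as \code{x}.
#' @export
phase_profile_truth <- function(truth, x) {
  stopifnot(inherits(truth, "wave_ground_truth"), is.numeric(x), length(x) >= 1)
  if (any(diff(x) <= 0)) stop("x must be strictly increasing")
  if (truth$x_turn < min(x) || truth$x_turn > max(x))
    stop("x_turn lies outside the evaluation range; configuration unusable")
  T <- truth$cardiac_period
  s_down <- 2 * pi / (T * truth$speed_retro)   # < 0
  s_up   <- 2 * pi / (T * truth$speed_antero)  # > 0
  x0 <- x[1]
  psi_turn <- s_down * (truth$x_turn - x0)
  ifelse(x <= truth$x_turn,
         s_down * (x - x0),
         psi_turn + s_up * (x - truth$x_turn))
}

#' AR(1) noise series
#'
#' Stationary first-order autoregressive noise: \code{e[t] = rho*e[t-1] +
#' innovation}, innovations iid Normal(0, sd), initialized from the
#' stationary distribution (variance \code{sd^2/(1-rho^2)}).
#'
#' @param n Length of the series.
#' @param rho AR(1) coefficient in [0, 1).
#' @param sd Innovation standard deviation.
#' @return Numeric vector of length \code{n}.
#' @export
ar1_noise <- function(n, rho = 0, sd = 1) {
  stopifnot(n >= 1, rho >= 0, rho < 1, sd >= 0)
  innov <- stats::rnorm(n, 0, sd)
  if (rho == 0) return(innov)
  e0 <- stats::rnorm(1, 0, sd / sqrt(1 - rho^2))
  as.numeric(stats::filter(innov, rho, method = "recursive", init = e0))
}

# continuous piecewise-linear drift with knots at cycle boundaries
broken_stick_drift <- function(t, period, slopes) {
  slopes[1] * pmin(t, period) +
    slopes[2] * pmin(pmax(t - period, 0), period) +
    slopes[3] * pmax(t - 2 * period, 0)
}

#' Generate a synthetic centerline intensity series
#'
#' Realizes the generative model of [wave_ground_truth()]: pixel i at time t
#' carries
#' \code{baseline + A(x_i)*(sin(w*t + psi_i) + h2_ratio*sin(2*w*t + 2*psi_i))
#' + drift(t) + AR(1) noise}, with
#' \code{A(x) = amp_peak * exp(-(x - amp_mu)^2 / (2*amp_sigma^2))} and
#' \code{psi} from [phase_profile_truth()]. Noise is drawn independently per
#' pixel. Fully reproducible when \code{truth$seed} is set.
#'
#' @param truth A [wave_ground_truth()] object.
#' @return An object of class \code{intensity_series}: a list with
#'   \code{series} (n_pixels x n_frames matrix), \code{distance_mm},
#'   \code{time_s}, \code{fps}, \code{cardiac_period} and the stored
#'   \code{truth}.
#' @export
generate_series <- function(truth) {
  stopifnot(inherits(truth, "wave_ground_truth"))
  if (!is.null(truth$seed)) set.seed(truth$seed)
  x <- (seq_len(truth$n_pixels) - 1) * truth$mm_per_px
  t <- (seq_len(truth$n_frames) - 1) / truth$fps
  omega <- 2 * pi / truth$cardiac_period
  psi <- phase_profile_truth(truth, x)
  A <- truth$amp_peak * exp(-(x - truth$amp_mu)^2 / (2 * truth$amp_sigma^2))
  drift <- broken_stick_drift(t, truth$cardiac_period, truth$drift_slopes)
  series <- matrix(0, truth$n_pixels, truth$n_frames)
  for (i in seq_len(truth$n_pixels)) {
    periodic <- A[i] * (sin(omega * t + psi[i]) +
                          truth$h2_ratio * sin(2 * omega * t + 2 * psi[i]))
    noise <- if (truth$noise_sd > 0)
      ar1_noise(truth$n_frames, truth$rho, truth$noise_sd) else 0
    series[i, ] <- truth$baseline + periodic + drift + noise
  }
  structure(list(series = series, distance_mm = x, time_s = t,
                 fps = truth$fps, cardiac_period = truth$cardiac_period,
                 truth = truth),
            class = "intensity_series")
}

#' @export
print.intensity_series <- function(x, ...) {
  cat(sprintf("Centerline intensity series: %d pixels x %d frames (%.1f fps, T = %.2f s)\n",
              nrow(x$series), ncol(x$series), x$fps, x$cardiac_period))
  invisible(x)
}

#' Vessel scene geometry for frame rendering
#'
#' Describes a non-branching vessel curve inside a frame, the vessel width,
#' and the optic-disc mask used downstream for distance anchoring and scale
#' calibration. The centerline is one pixel per column, so consecutive
#' centerline pixels are 8-adjacent whenever the curve is gentle
#' (\code{amplitude_px * 2*pi / period_px <= 1}).
#'
#' @param frame_dim Frame size c(rows, cols).
#' @param start c(row, col) of the first centerline pixel (path start,
#'   nearest the disc center).
#' @param n_pixels Number of centerline pixels (one per column).
#' @param amplitude_px,period_px Vertical sine modulation of the centerline
#'   (pixels); \code{amplitude_px = 0} gives a straight horizontal vessel.
#' @param width_px Half-width of the vessel band in pixels (the band is a
#'   Chebyshev dilation of the centerline by this radius).
#' @param disc_center c(row, col) of the optic disc center.
#' @param disc_radius_px Radius of the circular disc mask in pixels.
#' @return An object of class \code{vessel_geometry} with the centerline
#'   pixel chain in \code{$centerline}.
#' @export
vessel_geometry <- function(frame_dim = c(72, 90), start = c(36, 12),
                            n_pixels = 60, amplitude_px = 4, period_px = 80,
                            width_px = 2,
                            disc_center = c(36, 8), disc_radius_px = 30) {
  stopifnot(length(frame_dim) == 2, length(start) == 2, n_pixels >= 2)
  if (amplitude_px > 0 && amplitude_px * 2 * pi / period_px > 1)
    stop("curve too steep: consecutive centerline pixels would not be 8-adjacent")
  i <- seq_len(n_pixels) - 1
  col <- start[2] + i
  row <- start[1] + round(amplitude_px * sin(2 * pi * i / period_px))
  margin <- width_px + 1
  if (any(col < 1 + margin | col > frame_dim[2] - margin |
            row < 1 + margin | row > frame_dim[1] - margin))
    stop("vessel curve leaves frame bounds")
  structure(list(frame_dim = as.integer(frame_dim),
                 centerline = cbind(row = row, col = col),
                 width_px = width_px,
                 disc_center = disc_center,
                 disc_radius_px = disc_radius_px),
            class = "vessel_geometry")
}

# binary dilation by a 3x3 (Chebyshev) structuring element, r times
dilate_cheb <- function(mask, r) {
  m <- mask
  if (r < 1) return(m)
  nr <- nrow(m); nc <- ncol(m)
  for (k in seq_len(r)) {
    p <- matrix(FALSE, nr + 2, nc + 2)
    p[2:(nr + 1), 2:(nc + 1)] <- m
    out <- matrix(FALSE, nr, nc)
    for (dr in -1:1) for (dc in -1:1)
      out <- out | p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
    m <- out
  }
  m
}

#' Render a synthetic frame stack from an intensity series
#'
#' Draws the vessel into each frame by inverting the Beer-Lambert transform
#' (vessel pixels carry \code{exp(-s/factor)} of the blood-column series of
#' their nearest centerline pixel, quantized to the stated bit depth),
#' composites it over a constant background, and perturbs each frame by a
#' small known random affine transform (rotation about the frame center plus
#' translation). Also emits the true vein mask, circular disc mask, per-frame
#' transforms, and the true centerline chain, providing an end-to-end oracle
#' for the preprocessing stage.
#'
#' @param series An [generate_series()] result (blood-column units, >= 0).
#' @param geometry A [vessel_geometry()]; its centerline must have
#'   \code{nrow(series$series)} pixels.
#' @param jitter_translate_px SD of the per-frame random translation (pixels).
#' @param jitter_rotate_deg SD of the per-frame random rotation (degrees).
#' @param bit_depth Bit depth of the rendered frames (default 8).
#' @param background Mean background intensity as a fraction of full scale.
#' @param texture_sd SD of a static, smooth random background texture
#'   (fraction of full scale; 0 gives a perfectly flat background). Real
#'   fundus frames carry static texture, and intensity-based registration
#'   relies on it: with a flat background the only structure is the
#'   pulsating vessel itself, whose brightness changes frame to frame.
#' @param factor Beer-Lambert absorption factor (default 68).
#' @param seed Optional seed for the jitter draws.
#' @return A list with \code{stack} (a [frame_stack()] of quantized frames),
#'   \code{vein_mask}, \code{disc_mask}, \code{transforms} (list of
#'   \code{list(A, b)} mapping aligned coordinates to jittered-frame
#'   coordinates), \code{centerline}, and \code{geometry}.
#' @export
render_frames <- function(series, geometry,
                          jitter_translate_px = 0, jitter_rotate_deg = 0,
                          bit_depth = 8, background = 0.85,
                          texture_sd = 0.05, factor = 68, seed = NULL) {
  stopifnot(inherits(series, "intensity_series"),
            inherits(geometry, "vessel_geometry"))
  s <- series$series
  if (nrow(s) != nrow(geometry$centerline))
    stop("geometry centerline length must match the number of series pixels")
  if (any(s < 0)) stop("series must be non-negative blood-column values")
  if (!is.null(seed)) set.seed(seed)
  nr <- geometry$frame_dim[1]; nc <- geometry$frame_dim[2]
  # vein mask: Chebyshev dilation of the centerline chain
  cl <- geometry$centerline
  base <- matrix(FALSE, nr, nc)
  base[cbind(cl[, 1], cl[, 2])] <- TRUE
  vein_mask <- dilate_cheb(base, geometry$width_px)
  # each vessel pixel takes the series of its nearest centerline pixel
  vp <- which(vein_mask, arr.ind = TRUE)
  nearest <- vapply(seq_len(nrow(vp)), function(k) {
    which.min((cl[, 1] - vp[k, 1])^2 + (cl[, 2] - vp[k, 2])^2)
  }, integer(1))
  # disc mask
  rr <- row(base); cc <- col(base)
  disc_mask <- (rr - geometry$disc_center[1])^2 +
    (cc - geometry$disc_center[2])^2 <= geometry$disc_radius_px^2
  max_val <- 2^bit_depth - 1
  n_frames <- ncol(s)
  transforms <- vector("list", n_frames)
  frames <- vector("list", n_frames)
  ctr <- c((nr + 1) / 2, (nc + 1) / 2)
  bg <- matrix(background, nr, nc)
  if (texture_sd > 0) {
    field <- smooth_gauss(matrix(stats::rnorm(nr * nc), nr, nc), 1.5)
    bg <- bg + texture_sd * field / stats::sd(field)
    bg <- pmin(pmax(bg, 0), 1)
  }
  for (f in seq_len(n_frames)) {
    img <- bg
    img[cbind(vp[, 1], vp[, 2])] <- exp(-s[nearest, f] / factor)
    theta <- if (jitter_rotate_deg > 0)
      stats::rnorm(1, 0, jitter_rotate_deg) * pi / 180 else 0
    shift <- if (jitter_translate_px > 0)
      stats::rnorm(2, 0, jitter_translate_px) else c(0, 0)
    A <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    b <- ctr - A %*% ctr + shift
    transforms[[f]] <- list(A = A, b = as.numeric(b))
    # jittered frame: sample the ideal image at inverse-transformed coords
    Ainv <- solve(A)
    warped <- warp_affine(img, Ainv, as.numeric(-Ainv %*% b), fill = background)
    frames[[f]] <- matrix(as.integer(round(warped * max_val)), nr, nc)
  }
  stack <- frame_stack(frames, fps = series$fps, bit_depth = bit_depth)
  list(stack = stack, vein_mask = vein_mask, disc_mask = disc_mask,
       transforms = transforms, centerline = cl, geometry = geometry)
}

#' Write / read a centerline series as CSV with a JSON ground-truth sidecar
#'
#' The CSV holds one row per centerline pixel: a \code{distance_mm} column
#' followed by one column per frame. The sidecar (written next to the CSV
#' with extension \code{.json}) stores the generating parameters so a series
#' can be round-tripped.
#'
#' @param series An \code{intensity_series}.
#' @param path Output CSV path.
#' @return \code{write_series_csv} returns \code{path} invisibly;
#'   \code{read_series_csv} returns an \code{intensity_series} (with
#'   \code{truth} restored when a sidecar is present).
#' @export
write_series_csv <- function(series, path) {
  stopifnot(inherits(series, "intensity_series"))
  df <- data.frame(distance_mm = series$distance_mm, series$series,
                   check.names = FALSE)
  names(df)[-1] <- sprintf("f%04d", seq_len(ncol(series$series)))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(fps = series$fps, cardiac_period = series$cardiac_period)
  if (!is.null(series$truth)) meta$truth <- unclass(series$truth)
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a ground-truth configuration from YAML or JSON
#'
#' The file holds fields of [wave_ground_truth()] (any subset; the rest
#' take their defaults).
#'
#' @param path A .yaml/.yml (requires the \pkg{yaml} package) or .json file.
#' @return A \code{wave_ground_truth}.
#' @export
read_truth_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = , yml = {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("package 'yaml' is required to read YAML configs")
      yaml::read_yaml(path)
    },
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format: ", ext))
  known <- names(formals(wave_ground_truth))
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0) stop("unknown config fields: ", paste(bad, collapse = ", "))
  do.call(wave_ground_truth, cfg)
}

#' Write rendered frames and masks to standard image formats
#'
#' \code{write_frames_tiff} stores a frame stack as a multi-page TIFF
#' (intensities rescaled to [0, 1] by the bit-depth maximum; requires
#' \pkg{tiff}); \code{write_mask_png} stores a binary mask as PNG
#' (requires \pkg{png}).
#'
#' @param stack A [frame_stack()].
#' @param mask A binary matrix.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_frames_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("package 'tiff' is required to write TIFF stacks")
  max_val <- 2^stack$bit_depth - 1
  tiff::writeTIFF(lapply(stack$frames, function(f) f / max_val), path,
                  bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_frames_tiff
#' @export
write_mask_png <- function(mask, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("package 'png' is required to write PNG masks")
  png::writePNG((mask != 0) * 1, path)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  sidecar <- sub("\\.csv$", ".json", path)
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE)
  else stop("missing JSON sidecar: ", sidecar)
  truth <- NULL
  if (!is.null(meta$truth)) {
    tr <- meta$truth
    truth <- wave_ground_truth(
      speed_retro = tr$speed_retro, speed_antero = tr$speed_antero,
      x_turn = tr$x_turn, amp_peak = tr$amp_peak, amp_mu = tr$amp_mu,
      amp_sigma = tr$amp_sigma, baseline = tr$baseline,
      cardiac_period = tr$cardiac_period, h2_ratio = tr$h2_ratio,
      drift_slopes = tr$drift_slopes, rho = tr$rho, noise_sd = tr$noise_sd,
      n_pixels = tr$n_pixels, fps = tr$fps, mm_per_px = tr$mm_per_px,
      seed = tr$seed)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- NULL
  structure(list(series = m, distance_mm = df$distance_mm,
                 time_s = (seq_len(ncol(m)) - 1) / meta$fps,
                 fps = meta$fps, cardiac_period = meta$cardiac_period,
                 truth = truth),
            class = "intensity_series")
}
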