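#' Distance-phase profile of one video
#'
#' Bundles the per-pixel fit results into the object the wave-geometry stage
#' segments: strictly increasing centerline distance, normalized (first
#' pixel = 0) unwrapped phase, phase CI widths, per-pixel pulse amplitude,
#' and the Euclidean offset from the optic disc center to the path start.
#'
#' @param fits Per-pixel data.frame from [fit_series()] (columns
#'   \code{distance_mm}, \code{phase_rad}, \code{ci_width},
#'   \code{amplitude}; a \code{converged} column, when present, drops
#'   non-converged pixels).
#' @param start_offset_mm Euclidean distance from the disc center to the
#'   path start (mm); 0 for purely synthetic profiles.
#' @param smooth Apply a defensive moving-median (window 3) to the
#'   normalized phase before extremum detection (default FALSE; the raw
#'   profile is used).
#' @return An object of class \code{phase_profile}.
#' @export
phase_profile <- function(fits, start_offset_mm = 0, smooth = FALSE) {
  stopifnot(is.data.frame(fits),
            all(c("distance_mm", "phase_rad", "amplitude") %in% names(fits)))
  if (!is.null(fits$converged)) fits <- fits[fits$converged %in% c(TRUE, NA), ]
  if (nrow(fits) < 2) stop("profile needs at least 2 usable pixels")
  if (any(diff(fits$distance_mm) <= 0))
    stop("distances must be strictly increasing")
  psi <- normalize_phase(fits$phase_rad)
  psi_used <- if (smooth) stats::runmed(psi, 3, endrule = "keep") else psi
  structure(list(x = fits$distance_mm, psi = psi, psi_used = psi_used,
                 ci_width = if (!is.null(fits$ci_width)) fits$ci_width else
                   rep(NA_real_, nrow(fits)),
                 amplitude = fits$amplitude,
                 start_offset_mm = start_offset_mm, smooth = smooth),
            class = "phase_profile")
}

#' Normalize and unwrap a phase array
#'
#' Subtracts the first value so the first pixel has phase zero, then repairs
#' any successive jump larger than pi in magnitude by the nearest multiple
#' of 2*pi (defensive: the study observed no phase wrapping).
#'
#' @param phase Numeric vector of phases (radians).
#' @return Normalized, unwrapped phase; first element exactly 0.
#' @export
normalize_phase <- function(phase) {
  stopifnot(length(phase) >= 1)
  p <- phase - phase[1]
  if (length(p) == 1) return(0)
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(0, cumsum(d))
}

# strict interior local extrema of a numeric vector
local_maxima <- function(v) which(diff(sign(diff(v))) < 0) + 1
local_minima <- function(v) which(diff(sign(diff(v))) > 0) + 1

# topographic prominence of a local maximum of v at index i: height above
# the key col, where the col on each side is the lowest point between the
# peak and the nearest strictly higher ground (the side minimum when no
# higher ground exists; -Inf for an empty side)
topo_prominence <- function(v, i) {
  h <- v[i]
  side_base <- function(idx) {
    if (length(idx) == 0) return(-Inf)
    cm <- Inf
    for (j in idx) {
      if (v[j] > h) return(cm)
      cm <- min(cm, v[j])
    }
    cm
  }
  bl <- side_base(rev(seq_len(i - 1)))
  br <- side_base(seq(i + 1, length(v))[seq_len(max(length(v) - i, 0))])
  h - max(bl, br)
}

default_prominence <- function(profile) {
  w <- stats::median(profile$ci_width, na.rm = TRUE)
  if (is.finite(w)) 3 * w else 0
}

#' Locate the phase turning point
#'
#' Finds the first local maximum closest to the origin of the normalized
#' distance-phase profile (index 1 qualifies when the profile starts on a
#' down trend) and the first subsequent local minimum whose prominence
#' reaches \code{min_prominence}; that minimum is the phase turning point,
#' interpreted as the meeting point of the two opposing waves.
#'
#' @param profile A [phase_profile()].
#' @param min_prominence Minimum prominence (radians) for the turning
#'   point. Default: three times the median phase CI width of the profile,
#'   tying significance to the estimated phase uncertainty (0 when no CI
#'   widths are available).
#' @return List with \code{i_max0}, \code{i_turn}, \code{x_turn} (mm), and
#'   the \code{min_prominence} used.
#' @export
find_turning_point <- function(profile, min_prominence = NULL) {
  stopifnot(inherits(profile, "phase_profile"))
  psi <- profile$psi_used
  n <- length(psi)
  if (n < 5) stop("need at least 5 profile points")
  if (is.null(min_prominence)) min_prominence <- default_prominence(profile)
  mx <- local_maxima(psi)
  i_max0 <- if (psi[2] < psi[1]) 1L
  else if (length(mx) > 0) mx[1]
  else stop("no turning point: profile is monotone increasing",
            call. = FALSE)
  mins <- local_minima(psi)
  mins <- mins[mins > i_max0 & mins < n]
  for (i in mins) {
    if (topo_prominence(-psi, i) >= min_prominence)
      return(list(i_max0 = i_max0, i_turn = i, x_turn = profile$x[i],
                  min_prominence = min_prominence))
  }
  stop("no turning point: no local minimum after the first maximum reaches ",
       "the required prominence (", format(min_prominence, digits = 3),
       " rad); video should be excluded", call. = FALSE)
}

#' First significant local maximum past the turning point
#'
#' Scans the profile beyond the turning point for the first local maximum
#' whose prominence reaches \code{min_prominence}; this marks the end of
#' the linear up trend. When no maximum qualifies (e.g. a strictly
#' increasing tail), the global maximum of the post-turn segment is
#' returned with a weak flag (for a strictly increasing tail this is the
#' last index).
#'
#' @param profile A [phase_profile()].
#' @param i_turn Turning point index from [find_turning_point()].
#' @param min_prominence Minimum prominence (radians); same default as
#'   [find_turning_point()].
#' @return List with \code{i_max1} and logical \code{weak}.
#' @export
find_next_max <- function(profile, i_turn, min_prominence = NULL) {
  stopifnot(inherits(profile, "phase_profile"))
  psi <- profile$psi_used
  n <- length(psi)
  if (i_turn >= n) stop("turning point is the last profile index")
  if (is.null(min_prominence)) min_prominence <- default_prominence(profile)
  mx <- local_maxima(psi)
  mx <- mx[mx > i_turn]
  for (i in mx) {
    if (topo_prominence(psi, i) >= min_prominence)
      return(list(i_max1 = i, weak = FALSE))
  }
  seg <- psi[i_turn:n]
  list(i_max1 = i_turn - 1L + which.max(seg), weak = TRUE)
}

#' Least-squares trend line and pulse wave velocity over an interval
#'
#' Fits an ordinary least-squares line to the distance-phase points in the
#' closed index interval and converts its slope (radians/mm) to a signed
#' pulse wave velocity: the phase slope in seconds per mm is
#' \code{slope * T / (2*pi)}, and its inverse \code{2*pi/(T*slope)} is the
#' PWV in mm/s. The sign is preserved: a down trend gives a negative
#' (retrograde) PWV, an up trend a positive (anterograde) one.
#'
#' @param profile A [phase_profile()].
#' @param interval Integer index range \code{c(from, to)} (closed).
#' @param period Cardiac period T in seconds.
#' @return List with \code{slope} (rad/mm), \code{pwv} (mm/s; \code{NaN}
#'   with \code{degenerate = TRUE} for a zero slope), \code{intercept}, and
#'   \code{n}.
#' @export
fit_trend_pwv <- function(profile, interval, period) {
  stopifnot(inherits(profile, "phase_profile"), period > 0,
            length(interval) == 2)
  idx <- interval[1]:interval[2]
  if (length(idx) < 3) stop("interval must contain at least 3 points")
  x <- profile$x[idx]; y <- profile$psi[idx]
  cf <- unname(stats::coef(stats::lm.fit(cbind(1, x), y)))
  slope <- cf[2]
  if (slope == 0)
    return(list(slope = 0, pwv = NaN, intercept = cf[1], n = length(idx),
                degenerate = TRUE))
  list(slope = slope, pwv = 2 * pi / (period * slope), intercept = cf[1],
       n = length(idx), degenerate = FALSE)
}

#' Gaussian fit to the pulse-amplitude hump
#'
#' Nonlinear least squares of \code{A * exp(-(x - mu)^2 / (2*sigma^2)) + c}
#' to the distance-pulse amplitude curve. The full profile is fitted first;
#' if that does not converge, the fit is retried on the window between the
#' half-maximum crossings around the amplitude peak. The hump width is twice
#' the fitted standard deviation.
#'
#' @param x Distances (mm).
#' @param amplitude Per-pixel pulse amplitudes.
#' @return List with \code{mu}, \code{sigma}, \code{hw} (= 2*sigma),
#'   \code{peak} (fitted A), \code{baseline} (fitted c), and \code{window}
#'   ("full" or "halfmax").
#' @export
fit_hump <- function(x, amplitude) {
  stopifnot(length(x) == length(amplitude), length(x) >= 5)
  imax <- which.max(amplitude)
  if (imax == 1 || imax == length(x))
    stop("amplitude has no interior maximum; cannot fit a hump")
  run_fit <- function(xi, ai) {
    a0 <- max(ai) - min(ai)
    half <- min(ai) + a0 / 2
    above <- ai >= half
    sigma0 <- diff(range(xi[above])) / 2.355  # FWHM -> sigma
    if (!is.finite(sigma0) || sigma0 <= 0) sigma0 <- diff(range(xi)) / 6
    df <- data.frame(xi = xi, ai = ai)
    minpack.lm::nlsLM(
      ai ~ A * exp(-(xi - mu)^2 / (2 * sigma^2)) + c0, data = df,
      start = list(A = a0, mu = xi[which.max(ai)], sigma = sigma0,
                   c0 = min(ai)),
      lower = c(A = 0, mu = min(xi), sigma = 1e-8, c0 = -Inf),
      upper = c(A = Inf, mu = max(xi), sigma = Inf, c0 = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  fit <- tryCatch(run_fit(x, amplitude), error = function(e) NULL)
  window <- "full"
  if (is.null(fit)) {
    half <- min(amplitude) + (max(amplitude) - min(amplitude)) / 2
    lo <- imax; while (lo > 1 && amplitude[lo - 1] >= half) lo <- lo - 1
    hi <- imax; while (hi < length(x) && amplitude[hi + 1] >= half) hi <- hi + 1
    if (hi - lo + 1 >= 4)
      fit <- tryCatch(run_fit(x[lo:hi], amplitude[lo:hi]),
                      error = function(e) NULL)
    window <- "halfmax"
  }
  if (is.null(fit))
    stop("Gaussian hump fit did not converge on either window; ",
         "video excluded from hump-width units", call. = FALSE)
  cf <- stats::coef(fit)
  list(mu = unname(cf["mu"]), sigma = unname(cf["sigma"]),
       hw = 2 * unname(cf["sigma"]), peak = unname(cf["A"]),
       baseline = unname(cf["c0"]), window = window)
}

#' Turning-point distance metrics D1-D5
#'
#' Distances relating the turning point, the point of maximum pulse
#' amplitude, and the optic disc center, measured along the centerline path
#' (distances from the disc center additionally include the Euclidean
#' offset from the disc center to the path start):
#' D1 = |x_turn - x_maxamp| (mm); D2 = x_turn + start offset (mm);
#' D3 = D1 in hump widths; D4 = D2 in hump widths;
#' D5 = x_maxamp + start offset (mm).
#'
#' @param x_turn Turning point distance along the path (mm).
#' @param x_maxamp Distance of the maximum pulse amplitude (mm).
#' @param hw Hump width (mm); \code{NA} yields missing D3/D4.
#' @param start_offset_mm Euclidean disc center to path start distance (mm).
#' @return Named list D1..D5.
#' @export
compute_distances <- function(x_turn, x_maxamp, hw, start_offset_mm) {
  D1 <- abs(x_turn - x_maxamp)
  D2 <- x_turn + start_offset_mm
  D5 <- x_maxamp + start_offset_mm
  if (is.na(hw)) {
    D3 <- NA_real_; D4 <- NA_real_
  } else {
    D3 <- D1 / hw; D4 <- D2 / hw
  }
  list(D1 = D1, D2 = D2, D3 = D3, D4 = D4, D5 = D5)
}

#' Segment a phase profile into the two-wave geometry of one video
#'
#' Runs the full wave-geometry analysis: turning-point detection, ordinary
#' least-squares trend lines on the down- and up-trend intervals with their
#' signed pulse wave velocities, Gaussian hump width, and the distance
#' metrics D1-D5.
#'
#' @param profile A [phase_profile()].
#' @param period Cardiac period T (s).
#' @param min_prominence Prominence threshold for extremum detection; see
#'   [find_turning_point()].
#' @return An object of class \code{wave_result}: list with \code{i_max0},
#'   \code{i_turn}, \code{x_turn}, \code{i_max1}, \code{weak_max1},
#'   \code{s1}, \code{s2} (signed PWVs, mm/s), \code{slope_down},
#'   \code{slope_up}, \code{x_maxamp}, \code{hump} (or NULL), \code{hw},
#'   \code{D1}..\code{D5}, \code{period}, \code{profile}.
#' @export
analyze_profile <- function(profile, period, min_prominence = NULL) {
  stopifnot(inherits(profile, "phase_profile"))
  tp <- find_turning_point(profile, min_prominence)
  nm <- find_next_max(profile, tp$i_turn, min_prominence)
  down <- fit_trend_pwv(profile, c(tp$i_max0, tp$i_turn), period)
  up <- fit_trend_pwv(profile, c(tp$i_turn, nm$i_max1), period)
  x_maxamp <- profile$x[which.max(profile$amplitude)]
  hump <- tryCatch(fit_hump(profile$x, profile$amplitude),
                   error = function(e) NULL)
  hw <- if (is.null(hump)) NA_real_ else hump$hw
  d <- compute_distances(tp$x_turn, x_maxamp, hw, profile$start_offset_mm)
  structure(c(list(i_max0 = tp$i_max0, i_turn = tp$i_turn,
                   x_turn = tp$x_turn,
                   i_max1 = nm$i_max1, weak_max1 = nm$weak,
                   slope_down = down$slope, s1 = down$pwv,
                   slope_up = up$slope, s2 = up$pwv,
                   x_maxamp = x_maxamp, hump = hump, hw = hw),
              d,
              list(period = period, profile = profile)),
            class = "wave_result")
}

#' @export
print.wave_result <- function(x, ...) {
  cat("Two-wave geometry result\n")
  cat(sprintf("  turning point: %.4f mm (index %d); max amplitude at %.4f mm\n",
              x$x_turn, x$i_turn, x$x_maxamp))
  cat(sprintf("  PWV down-trend S1 = %.2f mm/s, up-trend S2 = %.2f mm/s%s\n",
              x$s1, x$s2, if (x$weak_max1) " (weak up-trend end)" else ""))
  cat(sprintf("  hump width = %s mm; D1 = %.3f, D2 = %.3f, D3 = %s, D4 = %s, D5 = %.3f\n",
              if (is.na(x$hw)) "NA" else sprintf("%.4f", x$hw),
              x$D1, x$D2,
              if (is.na(x$D3)) "NA" else sprintf("%.3f", x$D3),
              if (is.na(x$D4)) "NA" else sprintf("%.3f", x$D4), x$D5))
  invisible(x)
}

#' One-row data.frame of a wave result
#'
#' @param x A [analyze_profile()] result.
#' @param row.names,optional,... Passed through for compatibility.
#' @return A one-row data.frame with the headline quantities of the video.
#' @export
as.data.frame.wave_result <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  data.frame(x_turn = x$x_turn, x_maxamp = x$x_maxamp,
             s1 = x$s1, s2 = x$s2, hw = x$hw,
             D1 = x$D1, D2 = x$D2, D3 = x$D3, D4 = x$D4, D5 = x$D5,
             weak_max1 = x$weak_max1, row.names = row.names)
}

#' Plot a segmented distance-phase profile
#'
#' Two-panel base-graphics plot: normalized phase and pulse amplitude
#' against centerline distance with the down-/up-trend regression lines,
#' and the phase CI widths underneath.
#'
#' @param x A \code{wave_result}.
#' @param ... Further arguments passed to \code{plot}.
#' @export
plot.wave_result <- function(x, ...) {
  p <- x$profile
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 4))
  on.exit(graphics::par(op))
  graphics::plot(p$x, p$psi, type = "b", pch = 16, cex = 0.6,
                 xlab = "distance along centerline (mm)",
                 ylab = "normalized phase (rad)", ...)
  idx_d <- x$i_max0:x$i_turn
  idx_u <- x$i_turn:x$i_max1
  graphics::lines(p$x[idx_d],
                  x$slope_down * p$x[idx_d] +
                    (p$psi[x$i_turn] - x$slope_down * p$x[x$i_turn]),
                  col = "blue", lwd = 2)
  graphics::lines(p$x[idx_u],
                  x$slope_up * p$x[idx_u] +
                    (p$psi[x$i_turn] - x$slope_up * p$x[x$i_turn]),
                  col = "red", lwd = 2)
  graphics::abline(v = x$x_turn, lty = 3)
  op2 <- graphics::par(new = TRUE)
  graphics::plot(p$x, p$amplitude, type = "l", col = "darkgreen", axes = FALSE,
                 xlab = "", ylab = "")
  graphics::axis(4, col.axis = "darkgreen")
  graphics::mtext("pulse amplitude", side = 4, line = 2.5, col = "darkgreen")
  graphics::plot(p$x, p$ci_width, type = "h",
                 xlab = "distance along centerline (mm)",
                 ylab = "phase CI width (rad)")
  invisible(x)
}
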