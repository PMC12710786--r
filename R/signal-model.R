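#' Beer-Lambert blood-column transform
#'
#' Converts normalized pixel intensity to a value proportional to blood
#' column thickness: \code{s = -log(I) * factor}. Intensities must first be
#' normalized to (0, 1] by dividing by the bit-depth maximum, which makes
#' the transformed signal non-negative and the absorption-factor scale
#' reproducible.
#'
#' @param intensity Numeric vector/matrix of normalized intensities in
#'   (0, 1].
#' @param factor Hemoglobin absorption factor (arbitrary units), default 68.
#' @return Blood-column signal, same shape as \code{intensity}.
#' @export
beer_lambert <- function(intensity, factor = 68) {
  if (factor <= 0) stop("factor must be positive")
  if (any(intensity <= 0))
    stop("intensity must be positive: saturated-black pixel or missing ",
         "normalization")
  if (any(intensity > 1))
    stop("intensity exceeds 1: normalize by the bit-depth maximum first")
  -log(intensity) * factor
}

#' Harmonic regression design for one cardiac recording
#'
#' Second-order Fourier series in sine-cosine form at the cardiac frequency
#' plus a continuous piecewise-linear (broken-stick) trend with knots at the
#' cycle boundaries t = T and t = 2T: columns are the intercept,
#' \code{sin(wt)}, \code{cos(wt)}, \code{sin(2wt)}, \code{cos(2wt)}, \code{t},
#' \code{(t-T)+}, \code{(t-2T)+}. The hinge parameterization means the
#' fitted per-cycle trend slopes are the cumulative sums of the last three
#' coefficients.
#'
#' @param t Frame times in seconds (strictly increasing).
#' @param period Cardiac period T in seconds.
#' @return An object of class \code{harmonic_design}: list with the design
#'   matrix \code{X}, \code{t}, \code{period}, \code{omega}.
#' @export
harmonic_design <- function(t, period) {
  if (period <= 0) stop("period must be positive")
  if (length(t) < 9 || any(diff(t) <= 0))
    stop("t must be strictly increasing with at least 9 frames")
  omega <- 2 * pi / period
  X <- cbind(intercept = 1,
             sin1 = sin(omega * t), cos1 = cos(omega * t),
             sin2 = sin(2 * omega * t), cos2 = cos(2 * omega * t),
             trend1 = t,
             trend2 = pmax(t - period, 0),
             trend3 = pmax(t - 2 * period, 0))
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient; need >= 3 complete cycles ",
         "sampled at >= 8 frames per cycle")
  structure(list(X = X, t = t, period = period, omega = omega),
            class = "harmonic_design")
}

# Small-sample bias calibration for the residual lag-1 autocorrelation.
# Residuals r = M e (M the annihilator of the design) of AR(1) noise have
# E[sum r_t r_(t-1)] / E[sum r_t^2] = g(rho) != rho: the fitted trend and
# harmonic columns absorb part of the autocorrelation, biasing the naive
# statistic downward (about -0.11 at rho = 0 for 75 frames, 8 columns).
# g is computed exactly from traces of M Sigma(rho) M on a rho grid and the
# returned closure inverts it by interpolation.
ar1_moment_calibration <- function(X, grid = seq(-0.5, 0.95, by = 0.025)) {
  n <- nrow(X)
  M <- diag(n) - X %*% solve(crossprod(X), t(X))
  g <- vapply(grid, function(r) {
    A <- M %*% stats::toeplitz(r^(0:(n - 1))) %*% M
    sum(A[cbind(2:n, 1:(n - 1))]) / sum(diag(A))
  }, numeric(1))
  function(s) min(stats::approx(g, grid, xout = s, rule = 2)$y, 0.99)
}

# Prais-Winsten whitening of a vector or column-wise of a matrix
whiten_ar1 <- function(z, rho) {
  z <- as.matrix(z)
  w <- z
  w[1, ] <- sqrt(1 - rho^2) * z[1, ]
  if (nrow(z) > 1)
    w[-1, ] <- z[-1, , drop = FALSE] - rho * z[-nrow(z), , drop = FALSE]
  w
}

#' Per-pixel harmonic regression with AR(1) errors
#'
#' Fits the harmonic regression model to one pixel's blood-column time
#' series by feasible generalized least squares: iterate (whitened) OLS,
#' re-estimate the AR(1) coefficient from the lag-1 autocorrelation of the
#' raw-scale residuals, and whiten (Prais-Winsten) until the AR(1)
#' coefficient changes by less than \code{tol} (maximum \code{max_iter}
#' iterations). Coefficient standard errors come from the whitened normal
#' equations. Non-convergence is flagged, not raised, so downstream code can
#' exclude the pixel.
#'
#' @param y Numeric series, same length as the design times.
#' @param design A [harmonic_design()].
#' @param rho Fix the AR(1) coefficient at this value instead of estimating
#'   it (use \code{rho = 0} to get ordinary least squares).
#' @param tol Convergence tolerance on the AR(1) coefficient.
#' @param max_iter Maximum number of FGLS iterations.
#' @param rho_correction Apply a moment-matching small-sample bias
#'   correction to the estimated AR(1) coefficient (default TRUE). The
#'   naive residual lag-1 autocorrelation is biased toward zero because the
#'   fitted design absorbs part of the noise autocorrelation; the
#'   correction inverts the exact expectation of the statistic under the
#'   design. Without it the coefficient standard errors, and hence the
#'   phase CIs, are too narrow.
#' @param rho_cal Optional pre-computed calibration closure (internal reuse
#'   across pixels sharing a design).
#' @return An object of class \code{harmonic_fit}: coefficients \code{coef}
#'   (intercept, sin1, cos1, sin2, cos2, trend1..3), standard errors
#'   \code{se}, \code{rho}, innovation variance \code{sigma2},
#'   peak-to-trough \code{amplitude} of the periodic component, first
#'   harmonic \code{phase} (radians, \code{atan2(cos1, sin1)}),
#'   \code{converged}, and the \code{design}.
#' @export
fit_pixel <- function(y, design, rho = NULL, tol = 1e-4, max_iter = 50,
                      rho_correction = TRUE, rho_cal = NULL) {
  stopifnot(inherits(design, "harmonic_design"))
  X <- design$X
  if (length(y) != nrow(X)) stop("length(y) must match the design")
  n <- nrow(X); p <- ncol(X)
  estimate_rho <- is.null(rho)
  r_cur <- if (estimate_rho) 0 else rho
  converged <- !estimate_rho
  scale_y <- stats::var(y)
  beta <- NULL
  exact_fit <- FALSE
  for (it in seq_len(max_iter)) {
    Xw <- whiten_ar1(X, r_cur); yw <- whiten_ar1(y, r_cur)
    qrw <- qr(Xw)
    if (qrw$rank < p) stop("rank-deficient whitened design")
    beta <- qr.coef(qrw, yw)[, 1]
    if (!estimate_rho) break
    res <- y - as.numeric(X %*% beta)
    denom <- sum(res^2)
    if (denom <= 1e-20 || (scale_y > 0 && denom / n < 1e-16 * scale_y)) {
      # numerically exact fit: no information about rho
      exact_fit <- TRUE
      r_new <- 0
    } else {
      r_new <- sum(res[-1] * res[-n]) / denom
      r_new <- max(min(r_new, 0.99), -0.99)
    }
    if (abs(r_new - r_cur) < tol) {
      r_cur <- r_new
      converged <- TRUE
      break
    }
    r_cur <- r_new
  }
  if (estimate_rho && rho_correction && !exact_fit) {
    if (is.null(rho_cal)) rho_cal <- ar1_moment_calibration(X)
    r_cur <- rho_cal(r_cur)
  }
  Xw <- whiten_ar1(X, r_cur); yw <- whiten_ar1(y, r_cur)
  qrw <- qr(Xw)
  beta <- qr.coef(qrw, yw)[, 1]
  rss <- sum((yw - Xw %*% beta)^2)
  sigma2 <- rss / (n - p)
  XtXi <- chol2inv(qr.R(qrw))
  se <- sqrt(pmax(sigma2 * diag(XtXi), 0))
  names(se) <- names(beta)
  fit <- structure(list(coef = beta, se = se, rho = r_cur, sigma2 = sigma2,
                        converged = converged, design = design,
                        phase = atan2(beta[["cos1"]], beta[["sin1"]]),
                        amplitude = NA_real_),
                   class = "harmonic_fit")
  fit$amplitude <- pulse_amplitude(fit)
  fit
}

#' @export
print.harmonic_fit <- function(x, ...) {
  cat("Harmonic regression fit (AR(1) FGLS)\n")
  print(round(rbind(estimate = x$coef, se = x$se), 5))
  cat(sprintf("rho = %.4f, amplitude = %.4f, phase = %.4f rad, converged: %s\n",
              x$rho, x$amplitude, x$phase, x$converged))
  invisible(x)
}

# periodic component of a fit on a phase grid theta = omega * t
periodic_component <- function(coefs, theta) {
  coefs[["sin1"]] * sin(theta) + coefs[["cos1"]] * cos(theta) +
    coefs[["sin2"]] * sin(2 * theta) + coefs[["cos2"]] * cos(2 * theta)
}

#' Pulsation amplitude of a fitted periodic component
#'
#' The difference between the maximum and minimum of the fitted periodic
#' component over one cycle, evaluated on an \code{n_grid}-point grid and
#' refined to the exact extrema by local univariate optimization around the
#' grid argmax/argmin.
#'
#' @param fit A [fit_pixel()] result (or any list with a \code{coef} vector
#'   containing sin1, cos1, sin2, cos2).
#' @param n_grid Number of grid points over one period (default 1000).
#' @return Peak-to-trough amplitude (same units as the series).
#' @export
pulse_amplitude <- function(fit, n_grid = 1000) {
  co <- fit$coef
  th <- seq(0, 2 * pi, length.out = n_grid + 1)[-(n_grid + 1)]
  v <- periodic_component(co, th)
  step <- 2 * pi / n_grid
  refine <- function(i, maximize) {
    stats::optimize(function(z) periodic_component(co, z),
                    interval = c(th[i] - step, th[i] + step),
                    maximum = maximize, tol = 1e-12)
  }
  vmax <- refine(which.max(v), TRUE)$objective
  vmin <- refine(which.min(v), FALSE)$objective
  vmax - vmin
}

#' Monte-Carlo confidence interval for the first-harmonic phase
#'
#' Draws \code{n_mc} independent samples of the first-harmonic sine and
#' cosine coefficients from the normal distributions defined by their
#' estimates and standard errors, computes the phase of each sample pair,
#' re-centers each sampled phase to the 2*pi branch nearest the estimated
#' phase, and returns percentile bounds.
#'
#' @param fit A [fit_pixel()] result.
#' @param n_mc Number of Monte-Carlo samples (default 1000).
#' @param seed Optional seed for reproducibility.
#' @param level Confidence level (default 0.95).
#' @param use_covariance Sample (sin1, cos1) jointly from their estimated
#'   covariance instead of independently (sensitivity analysis; default
#'   FALSE, matching the independent-normal procedure).
#' @return List with \code{lo}, \code{hi} (radians), \code{width}, and
#'   \code{degenerate} (TRUE when the phase is undefined because both
#'   coefficients are zero).
#' @export
phase_ci <- function(fit, n_mc = 1000, seed = NULL, level = 0.95,
                     use_covariance = FALSE) {
  stopifnot(inherits(fit, "harmonic_fit"))
  a <- fit$coef[["sin1"]]; b <- fit$coef[["cos1"]]
  if (a == 0 && b == 0)
    return(list(lo = NA_real_, hi = NA_real_, width = NA_real_,
                degenerate = TRUE))
  if (!all(is.finite(fit$se[c("sin1", "cos1")])))
    stop("non-finite coefficient standard errors")
  if (!is.null(seed)) set.seed(seed)
  if (use_covariance) {
    Xw <- whiten_ar1(fit$design$X, fit$rho)
    V <- fit$sigma2 * chol2inv(qr.R(qr(Xw)))
    idx <- match(c("sin1", "cos1"), colnames(fit$design$X))
    S <- V[idx, idx]
    z <- matrix(stats::rnorm(2 * n_mc), n_mc, 2) %*% chol(S + diag(1e-30, 2))
    as_ <- a + z[, 1]; bs <- b + z[, 2]
  } else {
    as_ <- stats::rnorm(n_mc, a, fit$se[["sin1"]])
    bs <- stats::rnorm(n_mc, b, fit$se[["cos1"]])
  }
  ps <- atan2(bs, as_)
  ps <- ps + 2 * pi * round((fit$phase - ps) / (2 * pi))
  alpha <- (1 - level) / 2
  q <- stats::quantile(ps, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(lo = q[1], hi = q[2], width = q[2] - q[1], degenerate = FALSE)
}

#' Fit the harmonic model to every centerline pixel
#'
#' Runs [fit_pixel()] and [phase_ci()] across all pixels of a centerline
#' intensity series and assembles the per-pixel results the wave-geometry
#' stage consumes.
#'
#' @param series An \code{intensity_series} (from [generate_series()],
#'   [sample_series()] + [beer_lambert()], or [read_series_csv()]).
#' @param period Cardiac period in seconds; defaults to the one stored with
#'   the series, with [estimate_cardiac_period()] as a fallback.
#' @param rho Optional fixed AR(1) coefficient (NULL = estimate per pixel).
#' @param n_mc Monte-Carlo samples for the phase CIs.
#' @param seed Optional seed (used once before the per-pixel CI loop).
#' @return A data.frame with one row per pixel: \code{distance_mm},
#'   \code{amplitude}, \code{phase_rad}, \code{ci_lo}, \code{ci_hi},
#'   \code{ci_width}, \code{rho}, \code{converged}.
#' @export
fit_series <- function(series, period = NULL, rho = NULL, n_mc = 1000,
                       seed = NULL) {
  stopifnot(inherits(series, "intensity_series"))
  if (is.null(period)) period <- series$cardiac_period
  if (is.null(period)) period <- estimate_cardiac_period(series)
  des <- harmonic_design(series$time_s, period)
  rho_cal <- if (is.null(rho)) ar1_moment_calibration(des$X) else NULL
  if (!is.null(seed)) set.seed(seed)
  n_pix <- nrow(series$series)
  out <- data.frame(distance_mm = series$distance_mm,
                    amplitude = NA_real_, phase_rad = NA_real_,
                    ci_lo = NA_real_, ci_hi = NA_real_, ci_width = NA_real_,
                    rho = NA_real_, converged = NA)
  for (i in seq_len(n_pix)) {
    fit <- fit_pixel(series$series[i, ], des, rho = rho, rho_cal = rho_cal)
    ci <- phase_ci(fit, n_mc = n_mc)
    out$amplitude[i] <- fit$amplitude
    out$phase_rad[i] <- fit$phase
    out$ci_lo[i] <- ci$lo; out$ci_hi[i] <- ci$hi; out$ci_width[i] <- ci$width
    out$rho[i] <- fit$rho
    out$converged[i] <- fit$converged
  }
  out
}

#' Estimate the cardiac period from the path-averaged signal
#'
#' Fallback when no per-video cardiac period is recorded: the period of the
#' dominant non-DC peak of the periodogram of the path-averaged intensity
#' series (linearly detrended first so slow lighting drift does not masquerade
#' as a low frequency).
#'
#' @param series An \code{intensity_series}.
#' @return Estimated period in seconds.
#' @export
estimate_cardiac_period <- function(series) {
  stopifnot(inherits(series, "intensity_series"))
  y <- colMeans(series$series)
  t <- series$time_s
  y <- stats::resid(stats::lm(y ~ t))
  sp <- stats::spec.pgram(stats::ts(y, frequency = series$fps), plot = FALSE,
                          taper = 0, detrend = FALSE)
  1 / sp$freq[which.max(sp$spec)]
}
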