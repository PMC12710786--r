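#' Frame stack container
#'
#' Registered or raw single-channel frames with a common time base. Frames
#' are stored as a list of equally sized numeric matrices (row, col), with
#' intensities on their native integer scale (0 .. 2^bit_depth - 1).
#'
#' @param frames List of numeric matrices, all the same dimension,
#'   intensities >= 0.
#' @param fps Frame rate (frames per second).
#' @param bit_depth Bit depth of the intensity scale (default 8).
#' @param mm_per_px Optional mm-per-pixel scale (set after calibration).
#' @param time_s Optional per-frame times; default \code{(0:(n-1))/fps}.
#' @return An object of class \code{frame_stack}.
#' @export
frame_stack <- function(frames, fps, bit_depth = 8, mm_per_px = NULL,
                        time_s = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1, fps > 0)
  d <- dim(frames[[1]])
  for (f in frames) {
    if (!is.matrix(f) || !identical(dim(f), d))
      stop("all frames must be matrices of identical dimension")
    if (any(f < 0)) stop("frame intensities must be non-negative")
  }
  if (is.null(time_s)) time_s <- (seq_along(frames) - 1) / fps
  if (any(diff(time_s) <= 0)) stop("frame times must be strictly increasing")
  structure(list(frames = frames, fps = fps, bit_depth = bit_depth,
                 mm_per_px = mm_per_px, time_s = time_s, dim = d),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("Frame stack: %d frames of %d x %d px, %.1f fps, %d-bit%s\n",
              length(x$frames), x$dim[1], x$dim[2], x$fps, x$bit_depth,
              if (is.null(x$mm_per_px)) "" else
                sprintf(", %.4f mm/px", x$mm_per_px)))
  invisible(x)
}

#' Read an image stack from disk
#'
#' Reads a multi-page TIFF or a directory/vector of per-frame PNG or TIFF
#' images into a [frame_stack()], extracting one color channel (green by
#' default) from RGB input. Requires the \pkg{tiff} and/or \pkg{png}
#' packages. Intensities are rescaled from the [0, 1] convention of those
#' readers to the integer scale implied by \code{bit_depth}.
#'
#' @param path A multi-page TIFF file, a directory of frames, or a character
#'   vector of image files (sorted lexicographically).
#' @param fps Frame rate of the acquisition.
#' @param channel Color channel to extract from RGB frames ("green", "red",
#'   "blue"), ignored for grayscale input.
#' @param bit_depth Bit depth of the source images.
#' @return A [frame_stack()].
#' @export
read_frame_stack <- function(path, fps, channel = "green", bit_depth = 8) {
  ch <- match.arg(channel, c("red", "green", "blue"))
  ci <- match(ch, c("red", "green", "blue"))
  files <- if (length(path) == 1 && dir.exists(path))
    sort(list.files(path, full.names = TRUE)) else path
  arrs <- list()
  for (f in files) {
    ext <- tolower(tools::file_ext(f))
    a <- switch(ext,
      tif = , tiff = {
        if (!requireNamespace("tiff", quietly = TRUE))
          stop("package 'tiff' is required to read TIFF stacks")
        tiff::readTIFF(f, all = TRUE)
      },
      png = {
        if (!requireNamespace("png", quietly = TRUE))
          stop("package 'png' is required to read PNG frames")
        list(png::readPNG(f))
      },
      stop("unsupported image format: ", ext))
    arrs <- c(arrs, if (is.list(a)) a else list(a))
  }
  max_val <- 2^bit_depth - 1
  frames <- lapply(arrs, function(a) {
    m <- if (length(dim(a)) == 3) a[, , min(ci, dim(a)[3])] else a
    round(m * max_val)
  })
  frame_stack(frames, fps = fps, bit_depth = bit_depth)
}

# 3x3 Laplacian response on the interior of an image
laplacian3 <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- 2:(nr - 1); ci <- 2:(nc - 1)
  4 * img[ri, ci] - img[ri - 1, ci] - img[ri + 1, ci] -
    img[ri, ci - 1] - img[ri, ci + 1]
}

#' Select the sharpest frame of a stack
#'
#' Sharpness is scored as the variance of the 3x3 Laplacian response over
#' the frame; Gaussian blur strictly lowers this high-frequency energy.
#' Ties break to the lowest index.
#'
#' @param stack A [frame_stack()].
#' @return Integer index of the sharpest frame.
#' @export
select_sharpest <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  if (length(stack$frames) == 0) stop("empty frame stack")
  if (stack$dim[1] < 3 || stack$dim[2] < 3)
    stop("frames too small for a 3x3 sharpness score")
  scores <- vapply(stack$frames, function(f) stats::var(as.numeric(laplacian3(f))),
                   numeric(1))
  which.max(scores)  # which.max returns the first (lowest-index) maximum
}

#' Bilinear affine warp of an image (inverse mapping)
#'
#' Samples \code{img} at the affinely transformed coordinates of the output
#' grid: the output pixel at (r, c) takes the bilinearly interpolated value
#' of \code{img} at \code{A \%*\% c(r, c) + b}. Coordinates are 1-based
#' pixel centers.
#'
#' @param img Numeric matrix.
#' @param A 2x2 linear part of the transform.
#' @param b Length-2 offset.
#' @param fill Value for samples falling outside \code{img}.
#' @return A matrix of the same dimension as \code{img}.
#' @export
warp_affine <- function(img, A = diag(2), b = c(0, 0), fill = NA_real_) {
  nr <- nrow(img); nc <- ncol(img)
  rr <- rep(seq_len(nr), times = nc)
  cc <- rep(seq_len(nc), each = nr)
  sr <- A[1, 1] * rr + A[1, 2] * cc + b[1]
  sc <- A[2, 1] * rr + A[2, 2] * cc + b[2]
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  ok <- r0 >= 1 & r0 <= nr - 1 & c0 >= 1 & c0 <= nc - 1
  # clamp indices so subscripting is safe; invalid samples overwritten below
  r0c <- pmin(pmax(r0, 1), nr - 1); c0c <- pmin(pmax(c0, 1), nc - 1)
  i00 <- r0c + (c0c - 1) * nr
  v <- (1 - fr) * (1 - fc) * img[i00] +
    fr * (1 - fc) * img[i00 + 1] +
    (1 - fr) * fc * img[i00 + nr] +
    fr * fc * img[i00 + nr + 1]
  v[!ok] <- fill
  matrix(v, nr, nc)
}

# separable Gaussian smoothing with replicated edges
smooth_gauss <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- ceiling(3 * sigma)
  k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
  conv1 <- function(v) {
    vp <- c(rep(v[1], r), v, rep(v[length(v)], r))
    as.numeric(stats::filter(vp, k, sides = 2))[(r + 1):(r + length(v))]
  }
  t(apply(apply(img, 2, conv1), 1, conv1))
}

# central-difference gradient images with replicated edges
grad_images <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  gr <- (img[c(2:nr, nr), ] - img[c(1, 1:(nr - 1)), ]) / 2
  gc <- (img[, c(2:nc, nc)] - img[, c(1, 1:(nc - 1))]) / 2
  list(gr = gr, gc = gc)
}

# MSE objective and its analytic gradient for the 6-parameter affine warp
# par = (A11, A21, A12, A22, b1, b2); the gradient warps the moving image's
# spatial derivatives to the same grid and applies the chain rule
make_register_fns <- function(moving, ref, interior) {
  g <- grad_images(moving)
  nr <- nrow(ref); nc <- ncol(ref)
  rr <- matrix(rep(seq_len(nr), times = nc), nr, nc)
  cc <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  fn <- function(par) {
    A <- matrix(par[1:4], 2, 2)
    w <- warp_affine(moving, A, par[5:6])
    d <- (w - ref)[interior]
    d <- d[!is.na(d)]
    if (length(d) < 0.25 * sum(interior)) return(mean(ref^2))
    mean(d^2)
  }
  gr <- function(par) {
    A <- matrix(par[1:4], 2, 2)
    w <- warp_affine(moving, A, par[5:6])
    Gr <- warp_affine(g$gr, A, par[5:6])
    Gc <- warp_affine(g$gc, A, par[5:6])
    d <- w - ref
    ok <- interior & !is.na(d) & !is.na(Gr) & !is.na(Gc)
    n <- sum(ok)
    if (n == 0) return(rep(0, 6))
    dv <- d[ok]; grv <- Gr[ok]; gcv <- Gc[ok]
    2 / n * c(sum(dv * grv * rr[ok]), sum(dv * gcv * rr[ok]),
              sum(dv * grv * cc[ok]), sum(dv * gcv * cc[ok]),
              sum(dv * grv), sum(dv * gcv))
  }
  list(fn = fn, gr = gr)
}

#' Affine co-registration of a frame stack
#'
#' Intensity-based registration of every frame to a reference frame: a
#' coarse integer-translation search followed by quasi-Newton (BFGS)
#' refinement of the full 6-parameter affine transform with analytic
#' gradients (bilinear interpolation, mean squared error objective on the
#' frame interior). The reference frame is left untouched.
#'
#' @param stack A [frame_stack()].
#' @param ref_index Index of the reference frame (e.g. from
#'   [select_sharpest()]).
#' @param max_shift Radius of the coarse integer translation search (px).
#' @param margin Border width (px) excluded from the objective.
#' @param smooth_sigma Gaussian pre-smoothing (px) applied to both images
#'   for transform estimation only; reduces interpolation-induced bias in
#'   the MSE optimum. The returned frames are resampled from the originals.
#' @param maxit BFGS iteration budget per frame.
#' @param max_fail_frac Error if more than this fraction of frames fail to
#'   converge.
#' @return A list with \code{stack} (aligned [frame_stack()]),
#'   \code{transforms} (per frame \code{list(A, b)} mapping reference
#'   coordinates to source-frame coordinates), and logical \code{converged}
#'   per frame.
#' @export
register_affine <- function(stack, ref_index = select_sharpest(stack),
                            max_shift = 4, margin = 3, smooth_sigma = 1,
                            maxit = 200, max_fail_frac = 0.2) {
  stopifnot(inherits(stack, "frame_stack"))
  n <- length(stack$frames)
  if (ref_index < 1 || ref_index > n) stop("invalid ref_index")
  ref <- stack$frames[[ref_index]]
  ref_s <- smooth_gauss(ref, smooth_sigma)
  nr <- nrow(ref); nc <- ncol(ref)
  interior <- matrix(FALSE, nr, nc)
  interior[(margin + 1):(nr - margin), (margin + 1):(nc - margin)] <- TRUE
  aligned <- vector("list", n)
  transforms <- vector("list", n)
  converged <- logical(n)
  for (f in seq_len(n)) {
    if (f == ref_index) {
      aligned[[f]] <- ref
      transforms[[f]] <- list(A = diag(2), b = c(0, 0))
      converged[f] <- TRUE
      next
    }
    moving <- stack$frames[[f]]
    fns <- make_register_fns(smooth_gauss(moving, smooth_sigma), ref_s,
                             interior)
    # coarse translation init
    shifts <- expand.grid(dr = -max_shift:max_shift, dc = -max_shift:max_shift)
    sc <- vapply(seq_len(nrow(shifts)), function(k) {
      fns$fn(c(1, 0, 0, 1, shifts$dr[k], shifts$dc[k]))
    }, numeric(1))
    p0 <- c(1, 0, 0, 1, shifts$dr[which.min(sc)], shifts$dc[which.min(sc)])
    opt <- stats::optim(p0, fns$fn, fns$gr, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-12,
                                       parscale = c(0.02, 0.02, 0.02, 0.02, 1, 1)))
    A <- matrix(opt$par[1:4], 2, 2)
    b <- opt$par[5:6]
    aligned[[f]] <- {
      w <- warp_affine(moving, A, b)
      w[is.na(w)] <- mean(moving)
      w
    }
    transforms[[f]] <- list(A = A, b = b)
    converged[f] <- opt$convergence == 0
  }
  if (mean(!converged) > max_fail_frac)
    stop("affine registration failed on more than ",
         round(100 * max_fail_frac), "% of frames")
  out <- frame_stack(aligned, fps = stack$fps, bit_depth = stack$bit_depth,
                     mm_per_px = stack$mm_per_px, time_s = stack$time_s)
  list(stack = out, transforms = transforms, converged = converged)
}

# 8-neighbour circular sequence used by the thinning and ordering routines
neigh8 <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                c(1, 0), c(1, -1), c(0, -1), c(-1, -1))

# Zhang-Suen binary thinning to a single-pixel skeleton
zhang_suen <- function(mask) {
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  shift <- function(p, dr, dc) p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      pad_m <- pad[2:(nr + 1), 2:(nc + 1)]
      P <- lapply(seq_len(8), function(k) shift(pad, neigh8[k, 1], neigh8[k, 2]))
      # P2..P9 in the Zhang-Suen ordering: N, NE, E, SE, S, SW, W, NW
      B <- Reduce(`+`, P)
      Acount <- Reduce(`+`, lapply(seq_len(8), function(k) {
        (!P[[k]]) & P[[if (k == 8) 1 else k + 1]]
      }))
      if (step == 1) {
        c1 <- !(P[[1]] & P[[3]] & P[[5]])
        c2 <- !(P[[3]] & P[[5]] & P[[7]])
      } else {
        c1 <- !(P[[1]] & P[[3]] & P[[7]])
        c2 <- !(P[[1]] & P[[5]] & P[[7]])
      }
      del <- pad_m & B >= 2 & B <= 6 & Acount == 1 & c1 & c2
      if (any(del)) {
        changed <- TRUE
        pad_m[del] <- FALSE
        pad[2:(nr + 1), 2:(nc + 1)] <- pad_m
      }
    }
    if (!changed) break
  }
  pad[2:(nr + 1), 2:(nc + 1)]
}

# connected-component count under 8-connectivity (simple BFS)
count_components8 <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0)
  nr <- nrow(mask)
  lab <- matrix(0L, nr, ncol(mask))
  comp <- 0L
  for (k in seq_len(nrow(idx))) {
    r <- idx[k, 1]; c <- idx[k, 2]
    if (lab[r, c] > 0) next
    comp <- comp + 1L
    queue <- list(c(r, c)); lab[r, c] <- comp
    while (length(queue) > 0) {
      p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      for (j in seq_len(8)) {
        rr <- p[1] + neigh8[j, 1]; cc <- p[2] + neigh8[j, 2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= ncol(mask) &&
              mask[rr, cc] && lab[rr, cc] == 0) {
          lab[rr, cc] <- comp
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  comp
}

skeleton_neighbors <- function(skel, r, c) {
  out <- NULL
  for (j in seq_len(8)) {
    rr <- r + neigh8[j, 1]; cc <- c + neigh8[j, 2]
    if (rr >= 1 && rr <= nrow(skel) && cc >= 1 && cc <= ncol(skel) &&
          skel[rr, cc])
      out <- rbind(out, c(rr, cc))
  }
  out
}

# walk the skeleton from a start pixel in the direction of `first`,
# never revisiting
walk_arm <- function(skel, start, first) {
  visited <- matrix(FALSE, nrow(skel), ncol(skel))
  visited[start[1], start[2]] <- TRUE
  path <- rbind(start, first)
  visited[first[1], first[2]] <- TRUE
  cur <- first
  repeat {
    nb <- skeleton_neighbors(skel, cur[1], cur[2])
    nb <- nb[!visited[cbind(nb[, 1], nb[, 2])], , drop = FALSE]
    if (nrow(nb) == 0) break
    # prefer rook-adjacent continuation when both a rook and a diagonal
    # neighbour are unvisited (they then describe the same corner)
    if (nrow(nb) > 1) {
      d <- abs(nb[, 1] - cur[1]) + abs(nb[, 2] - cur[2])
      nb <- nb[order(d), , drop = FALSE]
    }
    cur <- nb[1, ]
    visited[cur[1], cur[2]] <- TRUE
    path <- rbind(path, cur)
  }
  path
}

#' Extract an ordered single-pixel vessel centerline
#'
#' Thins a binary vein mask to its topological skeleton (Zhang-Suen), checks
#' that the skeleton is a simple non-branching path, and orders the pixels
#' into a path starting at the skeleton pixel closest to the optic disc
#' center. When that pixel is interior to the skeleton, the longer of its
#' two arms is walked (study paths start near the disc center and run
#' outward).
#'
#' @param vein_mask Binary matrix (logical or 0/1), one connected component.
#' @param disc_center c(row, col) of the optic disc center.
#' @return An object of class \code{vessel_path}: list with \code{coords}
#'   (n x 2 matrix, row/col), \code{disc_center}, and
#'   \code{start_offset_px} (Euclidean distance from the disc center to the
#'   path start).
#' @export
extract_centerline <- function(vein_mask, disc_center) {
  m <- vein_mask != 0
  if (!any(m)) stop("empty vein mask")
  if (count_components8(m) != 1)
    stop("vein mask must be a single connected component")
  skel <- zhang_suen(m)
  pix <- which(skel, arr.ind = TRUE)
  ndeg <- vapply(seq_len(nrow(pix)), function(k) {
    nb <- skeleton_neighbors(skel, pix[k, 1], pix[k, 2])
    if (is.null(nb)) 0L else nrow(nb)
  }, integer(1))
  if (any(ndeg > 2))
    stop("skeleton has a branch point; clean the vein mask so the vessel ",
         "is a single non-branching segment")
  if (all(ndeg == 2) && nrow(pix) > 2)
    stop("skeleton forms a closed loop; clean the vein mask")
  d2 <- (pix[, 1] - disc_center[1])^2 + (pix[, 2] - disc_center[2])^2
  start <- pix[which.min(d2), ]
  nb <- skeleton_neighbors(skel, start[1], start[2])
  if (is.null(nb)) {
    coords <- matrix(start, 1, 2)
  } else if (nrow(pix) == 2) {
    coords <- rbind(start, nb[1, ])
  } else {
    arms <- lapply(seq_len(nrow(nb)), function(k) walk_arm(skel, start, nb[k, ]))
    # drop arms that are prefixes of another (diagonal + rook to same corner)
    lens <- vapply(arms, nrow, integer(1))
    coords <- arms[[which.max(lens)]]
  }
  dimnames(coords) <- NULL
  structure(list(coords = coords, disc_center = disc_center,
                 start_offset_px = sqrt(min(d2))),
            class = "vessel_path")
}

#' @export
print.vessel_path <- function(x, ...) {
  cat(sprintf("Vessel centerline path: %d pixels, start %.2f px from disc center\n",
              nrow(x$coords), x$start_offset_px))
  invisible(x)
}

#' Cumulative centerline distance
#'
#' Polyline length from the path start to each pixel: \code{mm_per_px} per
#' rook step, \code{mm_per_px * sqrt(2)} per diagonal step.
#'
#' @param path A [extract_centerline()] result.
#' @param mm_per_px Scale from [calibrate_scale()].
#' @return The \code{vessel_path} with \code{distance_mm} (first element 0)
#'   and \code{start_offset_mm} added.
#' @export
path_distances <- function(path, mm_per_px) {
  stopifnot(inherits(path, "vessel_path"), mm_per_px > 0)
  co <- path$coords
  if (nrow(co) > 1) {
    dr <- diff(co[, 1]); dc <- diff(co[, 2])
    if (any(abs(dr) > 1 | abs(dc) > 1 | (dr == 0 & dc == 0)))
      stop("consecutive path pixels must be distinct and 8-adjacent")
    steps <- sqrt(dr^2 + dc^2) * mm_per_px
    path$distance_mm <- c(0, cumsum(steps))
  } else {
    path$distance_mm <- 0
  }
  path$mm_per_px <- mm_per_px
  path$start_offset_mm <- path$start_offset_px * mm_per_px
  path
}

#' Millimeter-per-pixel scale from the optic disc height
#'
#' @param disc_height_px Disc height in pixels (from the disc mask).
#' @param disc_height_mm Known disc height in millimeters (from calibrated
#'   imaging).
#' @return mm per pixel.
#' @export
calibrate_scale <- function(disc_height_px, disc_height_mm) {
  if (disc_height_px <= 0 || disc_height_mm <= 0)
    stop("disc heights must be positive")
  disc_height_mm / disc_height_px
}

#' Disc center and height from a binary disc mask
#'
#' @param disc_mask Binary matrix.
#' @return List with \code{center} (row, col centroid) and
#'   \code{height_px} (vertical extent).
#' @export
disc_geometry <- function(disc_mask) {
  idx <- which(disc_mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty disc mask")
  list(center = c(mean(idx[, 1]), mean(idx[, 2])),
       height_px = diff(range(idx[, 1])) + 1)
}

#' Sample per-centerline-pixel intensity time series from a stack
#'
#' @param stack A registered [frame_stack()].
#' @param path A [vessel_path] with distances (see [path_distances()]).
#' @return An \code{intensity_series} whose \code{series} matrix holds the
#'   raw (integer-scale) intensities; apply [beer_lambert()] after
#'   normalizing by the bit-depth maximum to obtain blood-column values.
#' @export
sample_series <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"), inherits(path, "vessel_path"))
  co <- path$coords
  if (any(co[, 1] < 1 | co[, 1] > stack$dim[1] |
            co[, 2] < 1 | co[, 2] > stack$dim[2]))
    stop("path pixel outside frame bounds")
  m <- vapply(stack$frames, function(f) f[co], numeric(nrow(co)))
  m <- matrix(m, nrow = nrow(co))
  if (anyNA(m)) stop("path pixel sampled outside the registered image support")
  structure(list(series = m,
                 distance_mm = if (!is.null(path$distance_mm)) path$distance_mm
                 else (seq_len(nrow(co)) - 1) *
                   (if (!is.null(stack$mm_per_px)) stack$mm_per_px else 1),
                 time_s = stack$time_s, fps = stack$fps,
                 cardiac_period = NULL, truth = NULL),
            class = "intensity_series")
}
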