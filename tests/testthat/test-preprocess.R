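test_that("sharpest-frame selection prefers unblurred frames, ties to lowest index", {
  base <- matrix(runif(60 * 70), 60, 70)
  same <- frame_stack(list(base, base, base), fps = 25)
  expect_identical(select_sharpest(same), 1L)
  blurred <- frame_stack(list(gauss_blur(base, 1), base, gauss_blur(base, 2)),
                         fps = 25)
  expect_identical(select_sharpest(blurred), 2L)
  graded <- frame_stack(list(gauss_blur(base, 2), gauss_blur(base, 1), base),
                        fps = 25)
  expect_identical(select_sharpest(graded), 3L)
  expect_error(select_sharpest(frame_stack(list(matrix(0, 2, 2)), fps = 1)),
               "small")
})

test_that("affine registration recovers identity, translation, and rotation", {
  set.seed(11)
  ref <- gauss_blur(matrix(runif(64 * 64), 64, 64), 1.2) * 200
  # identity
  st <- frame_stack(list(ref, ref), fps = 10)
  reg <- register_affine(st, ref_index = 1)
  expect_lt(sqrt(sum(reg$transforms[[2]]$b^2)), 0.05)
  expect_lt(max(abs(reg$transforms[[2]]$A - diag(2))), 0.01)
  # pure translation (2, -1) px: moving(r) = ref(r + (2, -1))
  mv <- warp_affine(ref, diag(2), c(2, -1), fill = mean(ref))
  st <- frame_stack(list(ref, mv), fps = 10)
  reg <- register_affine(st, ref_index = 1)
  # estimated map (ref -> moving) composed with truth should be identity:
  # moving coords of ref pixel p are A p + b; truth moving(q) = ref(q + d)
  est <- reg$transforms[[2]]
  expect_lt(max(abs(est$b + c(2, -1))), 0.25)
  expect_lt(max(abs(est$A - diag(2))), 0.02)
  # pure rotation of 1 degree about the frame center
  th <- 1 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  ctr <- c(65, 65) / 2
  mv <- warp_affine(ref, R, as.numeric(ctr - R %*% ctr), fill = mean(ref))
  st <- frame_stack(list(ref, mv), fps = 10)
  reg <- register_affine(st, ref_index = 1)
  # estimated map is the inverse rotation; compare magnitudes
  ang <- atan2(reg$transforms[[2]]$A[2, 1], reg$transforms[[2]]$A[1, 1])
  expect_equal(abs(ang) * 180 / pi, 1, tolerance = 0.1)
})

test_that("centerline extraction thins a band to an ordered single-pixel path", {
  mask <- matrix(FALSE, 20, 60)
  mask[9:11, 5:54] <- TRUE
  path <- extract_centerline(mask, disc_center = c(10, 2))
  expect_s3_class(path, "vessel_path")
  expect_equal(nrow(path$coords), length(unique(path$coords[, 2])))
  expect_true(all(abs(diff(path$coords[, 2])) <= 1))
  expect_gte(nrow(path$coords), 45)
  # starts at the pixel closest to the disc center and runs outward
  expect_lt(path$coords[1, 2], path$coords[nrow(path$coords), 2])
})

test_that("branched masks are rejected with a cleanup hint", {
  y <- matrix(FALSE, 30, 30)
  y[15, 5:25] <- TRUE   # horizontal bar
  y[5:15, 15] <- TRUE   # vertical stem -> Y/T junction
  expect_error(extract_centerline(y, c(15, 5)), "branch")
  expect_error(extract_centerline(matrix(FALSE, 5, 5), c(1, 1)), "empty")
  two <- matrix(FALSE, 10, 10)
  two[2, 2] <- TRUE; two[8, 8] <- TRUE
  expect_error(extract_centerline(two, c(1, 1)), "connected")
})

test_that("extracted centerline of a rendered curved vessel matches the truth", {
  scene <- render_test_scene()
  path <- extract_centerline(scene$vein_mask,
                             disc_center = scene$geometry$disc_center)
  expect_lte(hausdorff(path$coords, scene$centerline), 1.5)
  # skeleton stays inside the mask
  expect_true(all(scene$vein_mask[path$coords]))
})

test_that("path distances follow rook and diagonal step lengths", {
  mk_path <- function(coords) {
    structure(list(coords = coords, disc_center = c(0, 0),
                   start_offset_px = 0), class = "vessel_path")
  }
  horiz <- mk_path(cbind(rep(5, 10), 1:10))
  expect_equal(path_distances(horiz, 0.01)$distance_mm[10], 0.09)
  diag_p <- mk_path(cbind(1:10, 1:10))
  expect_equal(path_distances(diag_p, 0.01)$distance_mm[10], 0.09 * sqrt(2))
  # mixed path equals the brute-force sum of Euclidean pixel distances
  set.seed(4)
  steps <- matrix(c(0, 1, 1, 1, 1, 0, 1, -1), 4, 2, byrow = TRUE)
  co <- apply(rbind(c(3, 3), steps[sample(1:4, 15, TRUE), ]), 2, cumsum)
  p <- mk_path(co)
  d <- path_distances(p, 0.02)$distance_mm
  brute <- c(0, cumsum(sqrt(rowSums(diff(co)^2)) * 0.02))
  expect_equal(d, brute, tolerance = 1e-12)
  # reversal re-anchors the same lengths
  rev_d <- path_distances(mk_path(co[nrow(co):1, ]), 0.02)$distance_mm
  expect_equal(rev_d, max(d) - rev(d), tolerance = 1e-12)
  bad <- mk_path(rbind(c(1, 1), c(1, 3)))
  expect_error(path_distances(bad, 0.01), "adjacent")
})

test_that("scale calibration is a guarded division", {
  expect_equal(calibrate_scale(300, 1.8), 0.006)
  expect_equal(calibrate_scale(1, 1), 1.0)
  expect_equal(300 * calibrate_scale(300, 1.8), 1.8)
  expect_error(calibrate_scale(0, 1.8), "positive")
  expect_error(calibrate_scale(300, -1), "positive")
})

test_that("series sampling returns the frame values along the path", {
  const <- frame_stack(replicate(4, matrix(100, 12, 12), simplify = FALSE),
                       fps = 10)
  p <- structure(list(coords = cbind(3:8, 4), disc_center = c(1, 1),
                      start_offset_px = 0), class = "vessel_path")
  p <- path_distances(p, 0.01)
  s <- sample_series(const, p)
  expect_true(all(s$series == 100))
  expect_equal(dim(s$series), c(6, 4))
  one <- frame_stack(list(matrix(7, 12, 12)), fps = 10)
  expect_equal(dim(sample_series(one, p)$series), c(6, 1))
  out_p <- structure(list(coords = cbind(3:14, 4), disc_center = c(1, 1),
                          start_offset_px = 0), class = "vessel_path")
  expect_error(sample_series(one, out_p), "bounds")
})

test_that("registration round-trip on a jittered stack recovers the series", {
  scene <- render_test_scene(jitter_translate_px = 1, jitter_rotate_deg = 0.3,
                             seed = 5)
  reg <- register_affine(scene$stack)
  expect_true(all(reg$converged))
  # gray-level RMSE at the true centerline pixels after alignment
  rec <- vapply(reg$stack$frames, function(f) f[scene$centerline],
                numeric(nrow(scene$centerline)))
  truth_gray <- 255 * exp(-scene$series$series / 68)
  expect_lt(sqrt(mean((rec - truth_gray)^2)), 2)
  # disc-height calibration recovers the rendering scale
  pre <- preprocess_video(scene$stack, scene$vein_mask,
                          disc_mask = scene$disc_mask,
                          disc_height_mm = 61 * 0.01)
  expect_equal(pre$mm_per_px, 0.01, tolerance = 1e-6)
})
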