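# Spatial descriptors: active area, binary Shannon entropy, box-counting
# dimension, centroid, and trajectory dynamics.

test_that("active area counts white pixels exactly", {
  expect_equal(active_area(matrix(0L, 6, 6)), 0)
  f <- matrix(0L, 10, 10)
  set.seed(1)
  f[sample(100, 37)] <- 255L
  expect_equal(active_area(f), 37)
  expect_equal(active_area(matrix(255L, 8, 8)), 64)
})

test_that("spatial entropy matches the binary closed form", {
  expect_equal(spatial_entropy(matrix(0L, 5, 5)), 0)
  expect_equal(spatial_entropy(matrix(255L, 5, 5)), 0)
  half <- matrix(c(0L, 255L), 10, 10)
  expect_equal(spatial_entropy(half), 1.0)
  q <- matrix(0L, 4, 4)
  q[1:4] <- 255L # p_white = 0.25
  expect_equal(spatial_entropy(q), 0.8113, tolerance = 1e-4)
})

test_that("entropy is the binary-entropy function of the white fraction", {
  set.seed(21)
  for (i in 1:10) {
    f <- random_binary_frame(16, 16, p = runif(1))
    expect_equal(spatial_entropy(f), h2(mean(f == 255)), tolerance = 1e-12)
  }
})

test_that("box counts match a brute-force grid scan", {
  set.seed(31)
  f <- random_binary_frame(32, 32, p = 0.3)
  fgidx <- which(f != 0, arr.ind = TRUE)
  for (e in c(2, 4, 8, 16)) {
    ci <- (fgidx[, 1] - 1) %/% e
    cj <- (fgidx[, 2] - 1) %/% e
    expect_equal(length(unique(ci + cj * (1 + max(ci)))),
                 oracle_box_count(f, e))
  }
})

test_that("fractal dimension recovers known dimensions", {
  # single pixel: N(eps) = 1 at every scale, slope 0
  pt <- matrix(0L, 64, 64); pt[20, 20] <- 255L
  expect_lte(fractal_dimension(pt), 0.05)

  # straight line across the frame: D = 1
  ln <- matrix(0L, 256, 256); ln[128, ] <- 255L
  expect_equal(fractal_dimension(ln), 1, tolerance = 0.15)

  # filled square: D = 2
  sq <- matrix(255L, 256, 256)
  expect_equal(fractal_dimension(sq), 2, tolerance = 0.05)

  # Sierpinski triangle (bitwise-AND construction), D = log3/log2
  n <- 256
  rc <- expand.grid(r = 0:(n - 1), c = 0:(n - 1))
  sp <- matrix(ifelse(bitwAnd(rc$r, rc$c) == 0, 255L, 0L), n, n)
  expect_equal(fractal_dimension(sp), log(3) / log(2), tolerance = 0.10)

  expect_true(is.na(fractal_dimension(matrix(0L, 32, 32))))
  expect_error(fractal_dimension(sq, box_sizes = 4), "2 box sizes")
})

test_that("dimension estimates bracket the space-filling and point limits", {
  set.seed(41)
  for (i in 1:20) {
    noise <- random_binary_frame(64, 64, p = 0.5)
    d <- fractal_dimension(noise)
    expect_gte(d, 1.6); expect_lte(d, 2.0)
    pt <- matrix(0L, 64, 64)
    pt[sample(64, 1), sample(64, 1)] <- 255L
    expect_lte(fractal_dimension(pt), 0.05)
  }
})

test_that("centroid is the mean white-pixel coordinate, 0-based (x, y)", {
  f <- matrix(0L, 20, 20); f[7, 13] <- 255L
  expect_equal(centroid(f), c(x = 12, y = 6))

  s <- matrix(0L, 21, 21); s[10:12, 10:12] <- 255L
  expect_equal(centroid(s), c(x = 10, y = 10))

  h <- matrix(0L, 10, 10)
  h[cbind(c(1, 2, 5, 10), c(1, 4, 6, 9))] <- 255L
  expect_equal(centroid(h), c(x = mean(c(0, 3, 5, 8)), y = mean(c(0, 1, 4, 9))))

  expect_true(all(is.na(centroid(matrix(0L, 5, 5)))))
})

test_that("centroid lies within the bounding box of the white pixels", {
  set.seed(51)
  for (i in 1:15) {
    f <- random_binary_frame(24, 24, p = 0.1)
    if (!any(f == 255)) next
    cen <- centroid(f)
    idx <- which(f == 255, arr.ind = TRUE)
    expect_gte(cen[["x"]], min(idx[, 2]) - 1)
    expect_lte(cen[["x"]], max(idx[, 2]) - 1)
    expect_gte(cen[["y"]], min(idx[, 1]) - 1)
    expect_lte(cen[["y"]], max(idx[, 1]) - 1)
  }
})

test_that("descriptors respond to background padding as documented", {
  set.seed(61)
  f <- matrix(0L, 16, 16)
  f[5:9, 6:11] <- 255L
  # padding on the bottom/right leaves area, dimension and centroid unchanged
  pad_br <- rbind(cbind(f, matrix(0L, 16, 16)), matrix(0L, 16, 32))
  expect_equal(active_area(pad_br), active_area(f))
  expect_equal(fractal_dimension(pad_br, c(8, 4, 2)),
               fractal_dimension(f, c(8, 4, 2)))
  expect_equal(centroid(pad_br), centroid(f))
  # padding on the top/left shifts the centroid by exactly the offset
  pad_tl <- rbind(matrix(0L, 3, 20), cbind(matrix(0L, 16, 4), f))
  expect_equal(centroid(pad_tl), centroid(f) + c(x = 4, y = 3))
  expect_equal(active_area(pad_tl), active_area(f))
})

test_that("trajectory metrics follow Euclidean geometry", {
  desc <- tibble::tibble(
    frame_index = 1:3, time_s = c(0, 0.1, 0.2),
    centroid_x = c(0, 3, 3), centroid_y = c(0, 4, 4),
    valid = TRUE
  )
  tm <- trajectory_metrics(desc)
  expect_equal(tm$step_displacements, c(5, 0))
  expect_equal(tm$cumulative_displacement, c(5, 5))

  const <- tibble::tibble(frame_index = 1:4, time_s = (0:3) / 10,
                          centroid_x = 2, centroid_y = 7, valid = TRUE)
  tmc <- trajectory_metrics(const)
  expect_true(all(tmc$step_displacements == 0))
  expect_true(all(tmc$cumulative_displacement == 0))

  # time reversal preserves the total accumulated displacement
  rev_desc <- desc[3:1, ]
  rev_desc$frame_index <- 1:3
  tmr <- trajectory_metrics(rev_desc)
  expect_equal(max(tmr$cumulative_displacement),
               max(tm$cumulative_displacement))
})

test_that("invalid frames are skipped and recorded; empty trajectories error", {
  desc <- tibble::tibble(
    frame_index = 1:4, time_s = (0:3) / 10,
    centroid_x = c(0, NA, 6, 6), centroid_y = c(0, NA, 8, 8),
    valid = c(TRUE, FALSE, TRUE, TRUE)
  )
  tm <- trajectory_metrics(desc)
  expect_equal(tm$skipped_frames, 2)
  expect_equal(nrow(tm$path), 3)
  expect_equal(tm$step_displacements, c(10, 0))
  expect_true(all(diff(tm$cumulative_displacement) >= 0))
  none <- desc; none$valid <- FALSE
  expect_error(trajectory_metrics(none), "empty trajectory")
})

test_that("the feature table carries the six features for valid frames", {
  au <- audio_waveform(sin(2 * pi * 11 * (0:7999) / 4000), fs_audio = 4000)
  traj <- simulate_spot_trajectory(au, membrane_spec(), optical_geometry())
  fr <- render_frames(traj, fps = 5, resolution = c(80, 60), noise_sigma = 2,
                      seed = 1)
  ms <- process_frames(fr, noise_sigma = 5, seed = 2)
  ft <- features_from_frames(ms, "Control", "toy")
  expect_true(all(feature_columns() %in% names(ft)))
  expect_true(all(ft$valid))
  expect_false(anyNA(ft[feature_columns()]))
  expect_equal(ft$step_disp[1], 0)
  expect_equal(ft$group_label[1], "Control")
  desc <- frame_descriptors(ms)
  expect_equal(nrow(desc), length(ms$frames))
  # entropy column is consistent with active area on every frame
  npix <- 80 * 60
  expect_equal(desc$entropy, vapply(desc$active_area / npix, h2, numeric(1)),
               tolerance = 1e-12)
})
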