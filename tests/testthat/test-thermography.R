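test_that("segmentation: uniform frame empty, small blob exact, ellipse area", {
  amb <- matrix(22, 40, 40)
  expect_false(any(segment_body(amb, ambient_estimate = 22)))

  blob <- amb
  blob[10, 10] <- 30; blob[10, 11] <- 30; blob[11, 10] <- 30
  m <- segment_body(blob, ambient_estimate = 22)
  expect_equal(sum(m), 3)
  expect_true(all(m[cbind(c(10, 10, 11), c(10, 11, 10))]))

  tb <- uniform_trace(35, unit = "degC")
  vid <- render_thermal_video(tb, t_body = 34, t_tail = 22, noise_sd = 0,
                              seed = 1)
  mask <- segment_body(vid$stack$frames[[1]])
  rr <- row(mask) - 30; cc <- col(mask) - 40
  ellipse_px <- sum((cc / 20)^2 + (rr / 7)^2 <= 1)  # oriented along cols
  expect_lt(abs(sum(mask) - ellipse_px) / ellipse_px, 0.05)
})

test_that("segmentation keeps only the largest connected component", {
  f <- matrix(22, 30, 30)
  f[5:6, 5:6] <- 30          # 4 px
  f[15:20, 15:20] <- 30      # 36 px
  m <- segment_body(f, ambient_estimate = 22)
  expect_equal(sum(m), 36)
  expect_false(m[5, 5])
})

test_that("pose of an axis-aligned rectangle: center, axis, length", {
  mask <- matrix(FALSE, 50, 50)
  mask[21:30, 11:40] <- TRUE   # 10 rows x 30 cols
  pose <- estimate_pose(mask, pixel_size_mm = 1, head_hint = c(25, 45))
  expect_equal(pose$centroid_px, c(25.5, 25.5))
  expect_lt(abs(abs(pose$anterior_unit[2]) - 1), 1e-9)  # axis along cols
  expect_equal(pose$body_length_mm, 30)
  expect_equal(sqrt(sum(pose$anterior_unit^2)), 1, tolerance = 1e-9)
  # hint toward larger col orients the anterior unit that way
  expect_gt(pose$anterior_unit[2], 0)
})

test_that("degenerate masks are rejected", {
  mask <- matrix(FALSE, 20, 20)
  expect_error(estimate_pose(mask, 1), "no body")
  mask[5, 5] <- TRUE
  expect_error(estimate_pose(mask, 1, open_px = 1), "degenerate")
})

test_that("pose recovers a rendered ellipse orientation within 2 degrees", {
  for (theta in c(0, 20, 65, -40)) {
    tb <- uniform_trace(35, unit = "degC")
    vid <- render_thermal_video(tb, t_body = 34, orientation_deg = theta,
                                frame_shape = c(80, 80),
                                body_center_px = c(40, 40),
                                noise_sd = 0, seed = 1)
    frame <- vid$stack$frames[[1]]
    pose <- estimate_pose(segment_body(frame), 1, frame)
    u_true <- c(-sin(theta * pi / 180), cos(theta * pi / 180))
    ang <- acos(min(1, abs(sum(pose$anterior_unit * u_true)))) * 180 / pi
    expect_lt(ang, 2)
    # warmer-end heuristic picks the head (anterior) direction
    expect_gt(sum(pose$anterior_unit * u_true), 0)
  }
})

test_that("BAT ROI placement follows the 25%-of-body-length rule", {
  pose <- structure(list(centroid_px = c(50, 50),
                         anterior_unit = c(-1, 0),
                         body_length_mm = 80,
                         mask = matrix(TRUE, 100, 100),
                         pixel_size_mm = 1), class = "body_pose")
  roi <- locate_bat_roi(pose)
  expect_equal(roi$center_px, c(30, 50))
  expect_equal(roi$radius_mm, 3)
  expect_false(roi$clipped)
  roi0 <- locate_bat_roi(pose, fraction = 0)
  expect_equal(roi0$center_px, c(50, 50))
  # center pushed out of frame is flagged
  pose$centroid_px <- c(10, 50)
  expect_true(locate_bat_roi(pose)$clipped)
})

test_that("roi_mean matches hand cases and the brute-force oracle", {
  f <- matrix(35, 20, 20)
  expect_equal(roi_mean(f, disk_roi(c(10, 10), 3), 1), 35)

  f2 <- matrix(100, 10, 10)
  f2[5:6, 5:6] <- c(30, 32, 34, 36)
  expect_equal(roi_mean(f2, disk_roi(c(5.5, 5.5), 1.1), 1), 33)

  set.seed(71)
  for (i in 1:20) {
    fr <- matrix(rnorm(30 * 25, 30, 3), 30, 25)
    ctr <- c(runif(1, 1, 30), runif(1, 1, 25))
    rad <- runif(1, 0.8, 6)
    got <- tryCatch(roi_mean(fr, disk_roi(ctr, rad), 1), error = function(e) NA)
    want <- brute_disk_mean(fr, ctr, rad, 1)
    if (is.na(want)) expect_true(is.na(got)) else expect_identical(got, want)
  }
  expect_error(roi_mean(f, disk_roi(c(-50, -50), 2), 1), "outside")
})

test_that("tail ROI mean matches painted temperatures and the oracle", {
  f <- matrix(22, 40, 40)
  f[19:21, 1:30] <- 28                      # tail strip along a row
  got <- tail_roi_mean(f, tail_base_px = c(20, 25), tail_dir = c(0, -1),
                       offset_mm = 10, diameter_mm = 2, pixel_size_mm = 1)
  expect_equal(got, 28)
  # disk fully in background reads ambient
  got_bg <- tail_roi_mean(f, c(5, 35), c(-1, 0), 2, 2, 1)
  expect_equal(got_bg, 22)
  # oracle equality on a random frame
  set.seed(5)
  fr <- matrix(rnorm(40 * 40, 25, 2), 40, 40)
  got <- tail_roi_mean(fr, c(20, 20), c(0, 1), 7, 4, 1)
  expect_identical(got, brute_disk_mean(fr, c(20, 27), 2, 1))
})

test_that("extract_trace composes per-frame calls and flags invalid ROIs", {
  frames <- lapply(c(30, 31, 32), function(v) matrix(v, 10, 10))
  st <- thermal_stack(frames, c(0, 1, 2), 1)
  tr <- extract_trace(st, disk_roi(c(5, 5), 2))
  expect_equal(tr$value, c(30, 31, 32))
  expect_equal(tr$time_s, c(0, 1, 2))

  tr2 <- extract_trace(st, function(frame, i) {
    if (i == 2) NULL else disk_roi(c(5, 5), 2)
  })
  expect_true(is.na(tr2$value[2]))
  expect_equal(tr2$value[c(1, 3)], c(30, 32))
  expect_error(thermal_stack(list(), numeric(0), 1), "non-empty")
})

test_that("pipeline recovers the programmed trace on noiseless video", {
  vid <- small_video(dip = 2, noise_sd = 0, seed = 2)
  tr <- extract_bat_trace(vid$stack)
  expect_lt(max(abs(tr$value - vid$truth$t_bat$value)), 0.05)
})

test_that("lowpass: DC exact, high frequency attenuated, mean preserved", {
  const <- uniform_trace(rep(37, 200), dt = 1, unit = "degC")
  out <- lowpass(const, cutoff_hz = 0.1)
  expect_lt(max(abs(out$value - 37)), 1e-9)

  t <- seq(0, 199, by = 1)
  sine <- new_trace(t, sin(2 * pi * 0.4 * t), "au")   # 0.4 Hz vs 0.05 cutoff
  f <- lowpass(sine, cutoff_hz = 0.05)
  mid <- 30:170
  expect_lt(max(abs(f$value[mid])), 0.1)   # >= 90% attenuation

  set.seed(2)
  noisy <- uniform_trace(5 + rnorm(300, 0, 0.5), dt = 1)
  lp <- lowpass(noisy, cutoff_hz = 0.05)
  expect_lt(abs(mean(lp$value) - mean(noisy$value)), 1e-6)

  expect_error(lowpass(const, cutoff_hz = 0.6), "Nyquist")
})
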