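test_that("segment_mask recovers the rendered silhouette and honours seeds", {
  out <- generate_elongation_series(
    growth_series_config(noise_sd = 0, length_noise_sd_px = 0,
                         angle_jitter_deg = 0, onset_min = 5, n_frames = 3))
  fr <- get_frame(out$series, 1, 1)
  m <- segment_mask(fr, threshold = 500)
  expect_identical(unclass(m)[seq_along(m)], (fr > 500)[seq_along(m)])
  m_auto <- segment_mask(fr, threshold = "auto")
  expect_identical(which(m_auto), which(m))

  two <- matrix(0, 30, 30)
  two[5:20, 5:10] <- 1     # larger blob
  two[25:27, 25:27] <- 1   # smaller blob
  small <- segment_mask(two, 0.5, selection_point = c(25, 25))
  expect_equal(sum(small), 9)
  large <- segment_mask(two, 0.5)
  expect_equal(sum(large), 16 * 6)
  expect_equal(attr(small, "policy"), "seeded")

  expect_error(segment_mask(matrix(1, 5, 5), "auto"), "non-uniform",
               class = "areakymo_validation_error")
  expect_error(segment_mask(matrix(1, 5, 5), 10), "no foreground",
               class = "areakymo_validation_error")
})

test_that("Feret diameter treats pixels as unit squares", {
  expect_equal(feret_diameter(matrix(TRUE, 1, 1)), sqrt(2))
  rect <- matrix(FALSE, 6, 7)
  rect[2:4, 2:5] <- TRUE  # 3 x 4 pixels -> 3-4-5 triangle
  expect_equal(feret_diameter(rect), 5)
  expect_error(feret_diameter(matrix(FALSE, 3, 3)), "empty",
               class = "areakymo_validation_error")
})

test_that("Feret equals the brute-force pairwise-corner oracle", {
  set.seed(31)
  for (k in 1:8) {
    m <- random_blob(size = 28, steps = 150)
    expect_equal(feret_diameter(m), brute_force_feret(m))
  }
})

test_that("Feret is rotation-robust and translation-invariant", {
  set.seed(5)
  m <- random_blob(size = 24, steps = 100)
  rot <- t(m)[rev(seq_len(ncol(m))), ]           # 90 degree rotation
  expect_equal(feret_diameter(rot), feret_diameter(m))
  shifted <- matrix(FALSE, 40, 40)
  shifted[7 + seq_len(nrow(m)), 9 + seq_len(ncol(m))] <- m
  expect_equal(feret_diameter(shifted), feret_diameter(m))
})

test_that("growth traces normalize to exactly 100 % at the first frame", {
  rod <- matrix(FALSE, 20, 60); rod[9:11, 6:55] <- TRUE
  masks <- list(rod, rod, rod)
  tr <- growth_trace(masks, time_step_min = 5)
  expect_identical(tr$length_pct, rep(100, 3))

  out <- generate_elongation_series(
    growth_series_config(noise_sd = 0, length_noise_sd_px = 0,
                         angle_jitter_deg = 0, n_frames = 10))
  masks <- lapply(seq_len(10), function(t)
    segment_mask(get_frame(out$series, t, 1), 500))
  tr2 <- growth_trace(masks, time_step_min = 5)
  expect_identical(tr2$length_pct[1], 100)
  expect_true(all(abs(tr2$length_px - out$truth$true_length$length_px) <= 1.5))

  # percentage is calibration-free, millimetres are not
  a <- growth_trace(masks, time_step_min = 5, px_per_mm = 100)
  b <- growth_trace(masks, time_step_min = 5, px_per_mm = 200)
  expect_equal(a$length_pct, b$length_pct)
  expect_equal(a$length_mm, 2 * b$length_mm)
})

test_that("line kymographs stack per-frame profiles as time columns", {
  # static series: every column identical
  fr <- matrix(runif(30 * 50), 30)
  s <- image_series(array(rep(fr, 4), c(30, 50, 1, 4)))
  lk <- line_kymograph(s, cbind(x = c(2, 47), y = c(15, 15)))
  expect_equal(lk[, 1], lk[, 4])

  # a tip advancing 2 px/frame traces an edge whose slope is the speed
  dat <- array(0, c(11, 60, 1, 8))
  for (t in 1:8) dat[4:8, 1:(20 + 2 * (t - 1)), 1, t] <- 100
  adv <- image_series(dat, time_step_min = 1)
  lk2 <- line_kymograph(adv, cbind(x = c(0, 59), y = c(5, 5)))
  edge <- apply(lk2, 2, function(col) max(which(col > 50)))
  fit <- stats::lm(edge ~ seq_len(8))
  expect_equal(unname(coef(fit)[2]), 2, tolerance = 1e-6)

  # uniform transverse profile: averaging width does not matter
  lk_w1 <- line_kymograph(adv, cbind(x = c(0, 59), y = c(5, 5)), width_px = 1)
  lk_w3 <- line_kymograph(adv, cbind(x = c(0, 59), y = c(5, 5)), width_px = 3)
  expect_equal(lk_w1, lk_w3)

  expect_error(line_kymograph(s, cbind(x = c(5, 5), y = c(9, 9))),
               "zero length", class = "areakymo_validation_error")
})

test_that("tip angle follows the 0-horizontal / 90-vertical convention", {
  vert <- generate_bending_series(start_angle_deg = 90, rate_deg_per_hr = 0,
                                  n_frames = 1)
  expect_equal(tip_angle(get_frame(vert$series, 1) > 0.5), 90)
  horiz <- generate_bending_series(start_angle_deg = 0, rate_deg_per_hr = 0,
                                   n_frames = 1)
  expect_equal(tip_angle(get_frame(horiz$series, 1) > 0.5), 0)
})

test_that("tip angle recovers generator angles within 2 degrees", {
  for (a in seq(-80, 80, by = 20)) {
    b <- generate_bending_series(start_angle_deg = a, rate_deg_per_hr = 0,
                                 n_frames = 1)
    est <- tip_angle(get_frame(b$series, 1) > 0.5,
                     basal_point = c(b$truth$angle$base_x[1],
                                     b$truth$angle$base_y[1]))
    expect_lte(abs(est - a), 2)
  }
  # whole-trace closed loop through the assay entry point
  bend <- generate_bending_series(start_angle_deg = 0, final_angle_deg = 90,
                                  rate_deg_per_hr = 45, n_frames = 9,
                                  time_step_min = 15)
  tr <- bend_angle_trace(bend$series)
  expect_true(all(abs(tr$angle_deg - bend$truth$angle$angle_deg) <= 2))
})

test_that("closed skeletons are rejected as having no free end", {
  ring <- matrix(FALSE, 30, 30)
  xy <- expand.grid(r = 1:30, c = 1:30)
  d <- sqrt((xy$r - 15.5)^2 + (xy$c - 15.5)^2)
  ring[cbind(xy$r, xy$c)] <- d > 8 & d < 12
  expect_error(tip_angle(ring), "closed curve|fewer than 2",
               class = "areakymo_validation_error")
})
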