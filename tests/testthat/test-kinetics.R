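test_that("ROI traces average the polygon interior per frame", {
  fr <- matrix(7, 12, 12)
  s <- image_series(array(rep(fr, 3), c(12, 12, 1, 3)), time_step_min = 2)
  tr <- extract_roi_trace(s, rect_roi(2, 2, 8, 8))
  expect_equal(tr$value, rep(7, 3))
  expect_equal(tr$time_min, c(0, 2, 4))

  vary <- image_series(array(runif(12 * 12 * 3), c(12, 12, 1, 3)))
  whole <- extract_roi_trace(vary, rect_roi(0, 0, 11, 11))
  expect_equal(whole$value,
               vapply(1:3, function(t) mean(vary$data[, , 1, t]), 0))

  # closed loop: a uniform stack carries the generated trace exactly
  lt <- generate_luminescence_trace(noise_sd = 0)
  stack <- uniform_stack(lt$trace$value)
  got <- extract_roi_trace(stack, rect_roi(3, 3, 12, 12))
  expect_equal(got$value, lt$trace$value)

  expect_error(extract_roi_trace(s, rect_roi(-10, -10, -2, -2)),
               "does not intersect", class = "areakymo_validation_error")
})

test_that("an exact two-piece line is recovered with zero SSE", {
  t <- seq(0, 100, by = 5)
  y <- ifelse(t <= 20, 50, 50 + 0.5 * (t - 20))
  est <- detect_onset(data.frame(time_min = t, value = y), "increase")
  expect_true(est$onset_detected)
  expect_equal(est$t_break_min, 20)
  expect_equal(est$sse, 0, tolerance = 1e-12)
  expect_equal(est$slope_pre, 0, tolerance = 1e-10)
  expect_equal(est$slope_post, 0.5, tolerance = 1e-10)
})

test_that("flat or wrong-direction traces yield a no-onset diagnostic", {
  t <- seq(0, 60, by = 5)
  flat <- detect_onset(data.frame(time_min = t, value = rep(3, 13)),
                       "increase")
  expect_false(flat$onset_detected)
  expect_match(flat$diagnostic, "flat|trends")
  expect_true(is.na(flat$t_break_min))

  falling <- detect_onset(data.frame(time_min = t, value = 100 - t),
                          "increase")
  expect_false(falling$onset_detected)
})

test_that("the changepoint matches the exhaustive grid-search oracle", {
  set.seed(23)
  for (k in 1:12) {
    n <- sample(10:30, 1)
    t <- seq(0, by = 5, length.out = n)
    onset <- sample(t[3:(n - 3)], 1)
    dir <- sample(c("increase", "decrease"), 1)
    sl <- runif(1, 0.2, 1) * if (dir == "increase") 1 else -1
    y <- ifelse(t <= onset, 10, 10 + sl * (t - onset)) + rnorm(n, 0, 0.4)
    est <- detect_onset(data.frame(time_min = t, value = y), dir)
    orc <- oracle_onset(t, y, dir)
    expect_equal(est$t_break_min, orc$t_break)
    if (est$onset_detected) expect_equal(est$sse, orc$sse, tolerance = 1e-8)
  }
})

test_that("negating a trace and flipping the direction keeps the breakpoint", {
  set.seed(41)
  t <- seq(0, 90, by = 5)
  y <- ifelse(t <= 35, 20, 20 + 0.8 * (t - 35)) + rnorm(length(t), 0, 0.5)
  up <- detect_onset(data.frame(time_min = t, value = y), "increase")
  dn <- detect_onset(data.frame(time_min = t, value = -y), "decrease")
  expect_equal(up$t_break_min, dn$t_break_min)
  expect_equal(up$sse, dn$sse, tolerance = 1e-9)
})

test_that("onset estimates expose tidy, glance and a bootstrap half-width", {
  t <- seq(0, 100, by = 5)
  set.seed(3)
  y <- ifelse(t <= 40, 10, 10 + 0.6 * (t - 40)) + rnorm(length(t), 0, 0.5)
  est <- detect_onset(data.frame(time_min = t, value = y), "increase",
                      bootstrap_ci = TRUE, n_boot = 50, seed = 2)
  td <- tidy(est)
  expect_equal(td$term, c("t_break_min", "slope_pre", "slope_post"))
  g <- glance(est)
  expect_true(g$onset_detected)
  expect_gte(g$ci_halfwidth_min, 0)
  expect_equal(g$t_break_min, 40)
})

test_that("trace validation rejects malformed input", {
  expect_error(detect_onset(data.frame(time_min = c(0, 5, 5, 10, 15),
                                       value = 1:5), "increase"),
               "strictly increasing", class = "areakymo_validation_error")
  expect_error(detect_onset(data.frame(time_min = 0:3, value = 1:4),
                            "increase"),
               "at least 5", class = "areakymo_validation_error")
  expect_error(detect_onset(data.frame(time_min = 0:5,
                                       value = c(1, NA, 3, 4, 5, 6)),
                            "increase"),
               "finite", class = "areakymo_validation_error")
})

test_that("transit time follows path length over velocity", {
  expect_equal(transit_time(1.2, 8, bilateral = TRUE), 4.5)
  expect_equal(transit_time(1.0, 60, bilateral = FALSE), 1.0)
  for (len in c(0.5, 1.2, 3)) {
    expect_equal(transit_time(len, 16), transit_time(len, 8) / 2)
  }
  expect_error(transit_time(0, 8), "segment_length_mm",
               class = "areakymo_validation_error")
  expect_error(transit_time(1.2, -1), "velocity_mm_per_hr",
               class = "areakymo_validation_error")
})
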