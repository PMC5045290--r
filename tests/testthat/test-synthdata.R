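test_that("the quench model is a protonation sigmoid with midpoint 0.5", {
  expect_equal(quench_fraction(6.0, pKa = 6.0), 0.5)
  # closed-form values of 1 / (1 + 10^(pKa - pH)) at the default pKa
  expect_equal(quench_fraction(6.4), 0.7152525, tolerance = 1e-6)
  expect_equal(quench_fraction(5.4), 0.2007600, tolerance = 1e-6)
  ph <- seq(3, 9, by = 0.05)
  expect_true(all(diff(quench_fraction(ph)) > 0))
})

test_that("noiseless pH series reproduce the quench model exactly", {
  cfg <- ph_series_config(noise_sd = 0, pKa = 6.0, ph_initial = 6.4,
                          ph_final = 5.4, onset_min = 20, tau_min = 5,
                          n_frames = 12, time_step_min = 5)
  out <- generate_ph_series(cfg)
  m <- wall_mask(out$series, threshold = 500)
  med <- frame_summary(pixel_ratios(out$series, m))$median
  expect_equal(med[1], 0.7152525, tolerance = 1e-6)      # B(6.4) before onset
  expect_equal(med[12], 0.2007600, tolerance = 5e-3)     # ~B(5.4) at 7 tau

  # constant pH schedule: the median ratio never moves
  flat <- generate_ph_series(ph_series_config(noise_sd = 0, ph_initial = 6.0,
                                              ph_final = 6.0, n_frames = 6))
  medf <- frame_summary(pixel_ratios(flat$series,
                                     wall_mask(flat$series, 500)))$median
  expect_equal(medf, rep(0.5, 6))
})

test_that("lower pH never yields a higher noiseless ratio", {
  cfg <- ph_series_config(noise_sd = 0, n_frames = 12)
  out <- generate_ph_series(cfg)
  med <- frame_summary(pixel_ratios(out$series,
                                    wall_mask(out$series, 500)))$median
  expect_true(all(diff(out$truth$ph$ph_upper) <= 0))
  expect_true(all(diff(med) <= 1e-12))
})

test_that("generators are bit-identical under the same seed", {
  a <- generate_ph_series(ph_series_config(seed = 7, onset_min = 5,
                                            n_frames = 4))
  b <- generate_ph_series(ph_series_config(seed = 7, onset_min = 5,
                                            n_frames = 4))
  expect_identical(a$series$data, b$series$data)
  c <- generate_ph_series(ph_series_config(seed = 8, onset_min = 5,
                                            n_frames = 4))
  expect_false(identical(a$series$data, c$series$data))

  e1 <- generate_elongation_series(growth_series_config(seed = 3,
                                                        n_frames = 4))
  e2 <- generate_elongation_series(growth_series_config(seed = 3,
                                                        n_frames = 4))
  expect_identical(e1$series$data, e2$series$data)
})

test_that("configuration validation names the offending field", {
  expect_error(ph_series_config(noise_sd = -1), "noise_sd",
               class = "areakymo_validation_error")
  expect_error(ph_series_config(onset_min = 80, n_frames = 12,
                                time_step_min = 5), "onset_min",
               class = "areakymo_validation_error")
  expect_error(ph_series_config(wall_width_px = 20, wall_spacing_px = 16),
               "wall_width_px", class = "areakymo_validation_error")
  expect_error(growth_series_config(initial_length_px = -5),
               "initial_length_px", class = "areakymo_validation_error")
  # a rod that would outgrow the frame is rejected up front
  expect_error(growth_series_config(initial_length_px = 300,
                                    growth_rate_pct_per_hr = 100,
                                    image_width_px = 320, n_frames = 24),
               "exceeds the frame", class = "areakymo_validation_error")
})

test_that("the elongation schedule is lag-then-linear with exact closed form", {
  cfg <- growth_series_config(initial_length_px = 200,
                              growth_rate_pct_per_hr = 30, onset_min = 20,
                              n_frames = 25, time_step_min = 5,
                              image_width_px = 360)
  out <- generate_elongation_series(cfg)
  tl <- out$truth$true_length
  expect_equal(tl$length_px[tl$time_min <= 20], rep(200, 5))
  # 120 min series: 200 * (1 + 0.30 * 100/60) = 300
  expect_equal(tl$length_px[tl$time_min == 120], 300)

  static <- generate_elongation_series(
    growth_series_config(growth_rate_pct_per_hr = 0, n_frames = 5))
  expect_equal(unique(static$truth$true_length$length_px), 200)
})

test_that("luminescence traces are flat, continuous at onset, and recoverable", {
  flat <- generate_luminescence_trace(amplitude = 0, noise_sd = 0)
  expect_equal(flat$trace$value, rep(100, 12))

  lt <- generate_luminescence_trace(onset_min = 20, noise_sd = 0)
  expect_equal(lt$trace$value[lt$trace$time_min == 20], 100)  # continuity

  est <- detect_onset(lt$trace, direction = "increase")
  expect_true(est$onset_detected)
  expect_lte(abs(est$t_break_min - 20), 5)  # within one time step
})

test_that("bending series follow a saturating linear angle schedule", {
  const <- generate_bending_series(start_angle_deg = 30, final_angle_deg = 90,
                                   rate_deg_per_hr = 0, n_frames = 4)
  expect_equal(const$truth$angle$angle_deg, rep(30, 4))

  b <- generate_bending_series(start_angle_deg = 0, final_angle_deg = 90,
                               rate_deg_per_hr = 90, n_frames = 9,
                               time_step_min = 15)
  tr <- b$truth$angle
  expect_equal(tr$angle_deg[tr$time_min == 30], 45)
  expect_equal(tr$angle_deg[tr$time_min == 120], 90)  # saturated
})

test_that("inject_drift rolls frames circularly and deterministically", {
  out <- generate_ph_series(ph_series_config(n_frames = 3, onset_min = 5))
  drift <- data.frame(dx_px = c(0, 4, -3), dy_px = c(0, -2, 5))
  d <- inject_drift(out$series, drift)
  expect_equal(sum(d$data), sum(out$series$data))  # nothing lost
  expect_identical(d$data[, , 1, 1], out$series$data[, , 1, 1])
  expect_false(identical(d$data[, , 1, 2], out$series$data[, , 1, 2]))
})
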