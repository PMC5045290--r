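two_channel <- function(ref, sense, ...) {
  stopifnot(all(dim(ref) == dim(sense)))
  image_series(array(c(ref, sense), c(dim(ref), 2, 1)), ...)
}

test_that("wall selection uses a strict threshold on the reference channel", {
  u <- matrix(100, 8, 8)
  s <- two_channel(u, u)
  expect_equal(wall_mask(s, 50)$n_pixels, 64L)
  expect_warning(m <- wall_mask(s, 100), "empty")
  expect_equal(m$n_pixels, 0L)

  out <- generate_ph_series(ph_series_config(noise_sd = 0, onset_min = 5,
                                             n_frames = 3))
  m <- wall_mask(out$series, 500)  # between background (50) and wall (1000)
  for (t in 1:3) expect_identical(m$masks[, , t], out$truth$wall)
})

test_that("raising the threshold never enlarges the mask", {
  out <- generate_ph_series(ph_series_config(n_frames = 2, onset_min = 5,
                                             seed = 5))
  thresholds <- c(100, 300, 500, 700, 900)
  sizes <- vapply(thresholds,
                  function(th) sum(wall_mask(out$series, th)$n_pixels), 0)
  expect_true(all(diff(sizes) <= 0))
  # subset relation, not just counts
  m1 <- wall_mask(out$series, 300)$masks
  m2 <- wall_mask(out$series, 700)$masks
  expect_true(all(m1[m2]))
})

test_that("pixel ratios are sense/ref with lower = more acidic", {
  u <- matrix(100, 6, 6)
  expect_equal(unique(pixel_ratios(two_channel(u, u),
                                   wall_mask(two_channel(u, u), 50))$ratio), 1)
  z <- two_channel(u, matrix(0, 6, 6))
  expect_equal(unique(pixel_ratios(z, wall_mask(z, 50))$ratio), 0)

  # at pH = pKa every noiseless wall pixel sits at the sigmoid midpoint
  out <- generate_ph_series(ph_series_config(noise_sd = 0, ph_initial = 6.0,
                                             ph_final = 6.0, onset_min = 5,
                                             n_frames = 2))
  rs <- pixel_ratios(out$series, wall_mask(out$series, 500))
  expect_equal(unique(rs$ratio), 0.5)
})

test_that("area kymograph blocks fill row-major with tail-drop overflow", {
  samples <- tibble::tibble(frame = 1L, time_min = 0,
                            ratio = seq(0.1, 1.0, by = 0.1))
  ak <- area_kymograph(samples, rect_width = 5, rows_per_block = 2)
  expect_equal(ak$provenance$placed, 10L)
  expect_equal(ak$provenance$dropped, 0L)
  expect_equal(ak$canvas[1, ], seq(0.1, 0.5, by = 0.1))  # row-major fill
  expect_equal(ak$canvas[2, ], seq(0.6, 1.0, by = 0.1))

  over <- tibble::tibble(frame = 1L, time_min = 0, ratio = seq_len(12) / 12)
  ak2 <- area_kymograph(over, rect_width = 5, rows_per_block = 2)
  expect_equal(ak2$provenance$dropped, 2L)
  expect_equal(max(ak2$canvas), 10 / 12)  # the tail was dropped

  const <- tibble::tibble(frame = 1L, time_min = 0, ratio = rep(0.7, 7))
  ak3 <- area_kymograph(const, rect_width = 4, rows_per_block = 3)
  expect_equal(sum(ak3$canvas == 0.7, na.rm = TRUE), 7L)
  expect_equal(sum(is.na(ak3$canvas)), 5L)
})

test_that("placed + dropped pixels are conserved across all blocks", {
  out <- generate_ph_series(ph_series_config(n_frames = 5, seed = 11))
  m <- wall_mask(out$series, 500)
  rs <- pixel_ratios(out$series, m)
  ak <- area_kymograph(rs, rect_width = 37, rows_per_block = 13)
  expect_equal(ak$provenance$placed + ak$provenance$dropped, m$n_pixels)
  expect_equal(sum(ak$provenance$placed) + sum(ak$provenance$dropped),
               sum(m$n_pixels))
})

test_that("frame summaries use interpolated quartiles and both mean variants", {
  samples <- tibble::tibble(frame = 1L, time_min = 0,
                            ref = rep(10, 4), sense = c(2, 4, 6, 8),
                            ratio = c(0.2, 0.4, 0.6, 0.8))
  fs <- frame_summary(samples)
  expect_equal(fs$q1, 0.3)
  expect_equal(fs$median, 0.5)
  expect_equal(fs$q3, 0.7)
  expect_equal(fs$mean_of_ratios, 0.5)
  expect_equal(fs$ratio_of_means, 0.5)  # uniform reference: exact identity

  const <- tibble::tibble(frame = 1L, time_min = 0, ref = rep(8, 5),
                          sense = rep(4, 5), ratio = rep(0.5, 5))
  fc <- frame_summary(const)
  expect_equal(unlist(fc[, c("min", "q1", "median", "q3", "max",
                             "mean_of_ratios", "ratio_of_means")]),
               setNames(rep(0.5, 7), c("min", "q1", "median", "q3", "max",
                                       "mean_of_ratios", "ratio_of_means")))
})

test_that("mean-of-ratios equals ratio-of-means whenever ref is uniform", {
  set.seed(21)
  for (k in 1:5) {
    n <- sample(5:40, 1)
    samples <- tibble::tibble(frame = 1L, time_min = 0,
                              ref = rep(runif(1, 50, 500), n),
                              sense = runif(n, 0, 400))
    samples$ratio <- samples$sense / samples$ref
    fs <- frame_summary(samples)
    expect_equal(fs$mean_of_ratios, fs$ratio_of_means)
  }
})

test_that("an empty frame is reported as no-data, not an error", {
  out <- generate_ph_series(ph_series_config(noise_sd = 0, onset_min = 5,
                                             n_frames = 2))
  suppressWarnings(m <- wall_mask(out$series, 5000))  # above everything
  rs <- pixel_ratios(out$series, m)
  fs <- frame_summary(rs)
  expect_equal(fs$n, c(0L, 0L))
  expect_true(all(is.na(fs$median)))
})

test_that("five-number summaries are ordered whenever n >= 1", {
  out <- generate_ph_series(ph_series_config(n_frames = 4, onset_min = 5,
                                             seed = 13))
  fs <- frame_summary(pixel_ratios(out$series, wall_mask(out$series, 500)))
  expect_true(all(fs$min <= fs$q1 & fs$q1 <= fs$median &
                    fs$median <= fs$q3 & fs$q3 <= fs$max))
})

test_that("sum projection adds z-slices per pixel and channel", {
  z1 <- image_series(array(runif(6 * 6 * 2), c(6, 6, 2, 1)))
  expect_equal(sum_project(z1)$data, z1$data)  # single slice: identity

  dat <- array(rep(z1$data, 2), c(6, 6, 2, 2))
  z2 <- image_series(dat)
  expect_equal(sum_project(z2)$data[, , , 1], 2 * z1$data[, , , 1])

  zz <- image_series(array(0, c(4, 4, 2, 3)))
  expect_true(all(sum_project(zz)$data == 0))
})

test_that("flank asymmetry matches the generator's pH offset", {
  upper <- rect_roi(0, 0, 95, 30)
  lower <- rect_roi(0, 60, 95, 95)

  sym <- generate_ph_series(ph_series_config(noise_sd = 0, onset_min = 5,
                                             n_frames = 3))
  fr <- flank_ratio(sym$series, upper, lower, threshold = 500)
  expect_equal(fr$mean_difference, 0)

  asym <- generate_ph_series(ph_series_config(noise_sd = 0,
                                              flank_delta_ph = -0.5,
                                              onset_min = 5, n_frames = 3))
  fr2 <- flank_ratio(asym$series, upper, lower, threshold = 500)
  expect_true(all(fr2$sections$difference < 0))  # lower flank more acidic

  expect_error(flank_ratio(sym$series, upper, upper, 500), "must differ",
               class = "areakymo_validation_error")
  expect_error(flank_ratio(sym$series, upper, rect_roi(0, 20, 95, 50), 500),
               "disjoint", class = "areakymo_validation_error")
})
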