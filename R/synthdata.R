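#' Protonation quench model for a pH-sensitive fluorophore
#'
#' Relative brightness of a GFP-derived, pH-sensitive fluorophore following a
#' single-site protonation sigmoid: `B(pH) = 1 / (1 + 10^(pKa - pH))`.
#' Brightness is strictly increasing in pH, so acidification quenches the
#' sense channel while a pH-insensitive reference channel is unaffected; the
#' sense/reference ratio of a dual reporter therefore drops as the apoplast
#' acidifies.
#'
#' @param ph pH value(s).
#' @param pKa Apparent pKa of the fluorophore (default 6.0, typical for
#'   GFP-derived sensors).
#' @return Relative brightness in (0, 1).
#' @examples
#' quench_fraction(6.0)        # 0.5 at the midpoint
#' quench_fraction(6.4) > quench_fraction(5.4)
#' @export
quench_fraction <- function(ph, pKa = 6.0) {
  1 / (1 + 10^(pKa - ph))
}

#' Step-onset pH time course
#'
#' pH is constant at `ph_initial` before `onset_min`, then relaxes
#' exponentially toward `ph_final` with time constant `tau_min`. The onset is
#' a sharp kink (slope discontinuity); `tau_min` controls how fast the new
#' plateau is approached.
#'
#' @param time_min Times in minutes.
#' @param ph_initial,ph_final pH before onset and asymptotic pH after onset.
#' @param onset_min Onset time in minutes.
#' @param tau_min Exponential approach time constant in minutes.
#' @return pH at each time.
#' @export
ph_schedule <- function(time_min, ph_initial, ph_final, onset_min, tau_min) {
  ifelse(time_min < onset_min, ph_initial,
         ph_final + (ph_initial - ph_final) * exp(-(time_min - onset_min) / tau_min))
}

#' Configuration for the synthetic ratiometric pH reporter series
#'
#' Describes a two-channel confocal-like time series of a cell-wall lattice
#' expressing a dual pH reporter: the reference channel is pH-independent,
#' the sense channel is quenched at low pH via [quench_fraction()], and the
#' wall pH follows the step-onset schedule of [ph_schedule()]. Defaults
#' emulate a 55-minute assay sampled every 5 minutes with acidification
#' starting 20 minutes after treatment.
#'
#' @param image_height_px,image_width_px Frame size in pixels.
#' @param wall_spacing_px Cell lattice period in pixels.
#' @param wall_width_px Thickness of the wall lines in pixels.
#' @param ref_wall_intensity Mean reference-channel brightness at wall pixels
#'   (arbitrary units, > 0).
#' @param background_intensity Off-wall brightness in both channels.
#' @param noise_sd Additive Gaussian noise standard deviation (>= 0), applied
#'   independently per pixel, channel and frame, then clipped at zero.
#' @param pKa Apparent pKa of the sense fluorophore.
#' @param ph_initial,ph_final Wall pH before onset and after full relaxation;
#'   `ph_final < ph_initial` for an acidification scenario.
#' @param onset_min True acidification onset in minutes; must fall inside the
#'   imaged interval.
#' @param tau_min Approach time constant of the pH drop in minutes. The
#'   default (50) keeps the decline in progress across the default window,
#'   as in real ratio traces where the new steady state is reached slowly.
#' @param flank_delta_ph pH offset added to the lower half of the frame
#'   (rows below the midline), for flank-asymmetry scenarios. Default 0.
#' @param n_frames Number of frames.
#' @param time_step_min Minutes between frames.
#' @param t_start_min Time of the first frame (minutes since treatment).
#' @param pixel_size_um Pixel size in micrometres.
#' @param seed Integer RNG seed; identical configurations generate
#'   bit-identical output.
#' @return A validated `ph_series_config` list.
#' @export
ph_series_config <- function(image_height_px = 96, image_width_px = 96,
                             wall_spacing_px = 16, wall_width_px = 2,
                             ref_wall_intensity = 1000,
                             background_intensity = 50,
                             noise_sd = 20, pKa = 6.0,
                             ph_initial = 6.4, ph_final = 5.4,
                             onset_min = 20, tau_min = 50,
                             flank_delta_ph = 0,
                             n_frames = 12, time_step_min = 5,
                             t_start_min = 0, pixel_size_um = 0.5,
                             seed = 1) {
  cfg <- list(
    image_height_px = image_height_px, image_width_px = image_width_px,
    wall_spacing_px = wall_spacing_px, wall_width_px = wall_width_px,
    ref_wall_intensity = ref_wall_intensity,
    background_intensity = background_intensity,
    noise_sd = noise_sd, pKa = pKa,
    ph_initial = ph_initial, ph_final = ph_final,
    onset_min = onset_min, tau_min = tau_min,
    flank_delta_ph = flank_delta_ph,
    n_frames = n_frames, time_step_min = time_step_min,
    t_start_min = t_start_min, pixel_size_um = pixel_size_um, seed = seed
  )
  check_number(cfg$image_height_px, "image_height_px", 4, integer = TRUE)
  check_number(cfg$image_width_px, "image_width_px", 4, integer = TRUE)
  check_number(cfg$wall_spacing_px, "wall_spacing_px", 2, integer = TRUE)
  check_number(cfg$wall_width_px, "wall_width_px", 1, integer = TRUE)
  if (cfg$wall_width_px >= cfg$wall_spacing_px) {
    abort("invalid value for field `wall_width_px`: must be smaller than `wall_spacing_px`",
          class = "areakymo_validation_error")
  }
  check_number(cfg$ref_wall_intensity, "ref_wall_intensity", 0, strict = TRUE)
  check_number(cfg$background_intensity, "background_intensity", 0)
  check_number(cfg$noise_sd, "noise_sd", 0)
  check_number(cfg$pKa, "pKa", 0, strict = TRUE)
  check_number(cfg$ph_initial, "ph_initial", 0, strict = TRUE)
  check_number(cfg$ph_final, "ph_final", 0, strict = TRUE)
  check_number(cfg$tau_min, "tau_min", 0, strict = TRUE)
  check_number(cfg$n_frames, "n_frames", 2, integer = TRUE)
  check_number(cfg$time_step_min, "time_step_min", 0, strict = TRUE)
  check_number(cfg$flank_delta_ph, "flank_delta_ph")
  check_number(cfg$seed, "seed", integer = TRUE)
  span <- cfg$n_frames * cfg$time_step_min
  if (!(cfg$onset_min >= 0 && cfg$onset_min < span)) {
    abort("invalid value for field `onset_min`: must lie in [0, n_frames * time_step_min)",
          class = "areakymo_validation_error")
  }
  structure(cfg, class = "ph_series_config")
}

# rectangular lattice of bright wall lines (logical H x W); cell sizes are
# jittered around `spacing` (real tissue is irregular, which also keeps the
# pattern aperiodic so that drift estimation is well-posed)
wall_lattice <- function(height, width, spacing, line_width,
                         jitter_frac = 0.3) {
  line_starts <- function(extent) {
    pos <- 0
    starts <- integer()
    while (pos < extent) {
      starts <- c(starts, round(pos))
      pos <- pos + spacing * (1 + stats::runif(1, -jitter_frac, jitter_frac))
    }
    starts
  }
  mark <- function(extent) {
    on <- rep(FALSE, extent)
    for (s in line_starts(extent)) {
      if (s + 1 > extent) next
      on[(s + 1):min(s + line_width, extent)] <- TRUE
    }
    on
  }
  outer(mark(height), mark(width), `|`)
}

#' Generate a synthetic ratiometric pH reporter series
#'
#' Renders a two-channel time series of a bright cell-wall lattice. At wall
#' pixels the reference channel has mean `ref_wall_intensity` (pH-independent)
#' and the sense channel has mean `ref_wall_intensity * quench_fraction(pH)`;
#' off-wall pixels sit at `background_intensity` in both channels. The wall pH
#' follows [ph_schedule()], optionally offset by `flank_delta_ph` in the lower
#' half of the frame. Gaussian noise is added independently per pixel, channel
#' and frame and clipped at zero.
#'
#' @param config A [ph_series_config()].
#' @return A list with elements `series` (a two-channel [image_series()],
#'   channels `ref` and `sense`) and `truth` (the generating ground truth:
#'   the wall lattice, per-frame wall pH and noiseless ratio for the two
#'   flanks, and the true onset). Analysis code must never read `truth`; it
#'   exists for closed-loop tests.
#' @examples
#' out <- generate_ph_series(ph_series_config(noise_sd = 0, onset_min = 5,
#'                                             n_frames = 4))
#' range(get_frame(out$series, 1, "ref"))
#' @export
generate_ph_series <- function(config) {
  stopifnot(inherits(config, "ph_series_config"))
  h <- config$image_height_px; w <- config$image_width_px
  wall <- withr::with_seed(
    config$seed,
    wall_lattice(h, w, config$wall_spacing_px, config$wall_width_px))
  times <- config$t_start_min + (seq_len(config$n_frames) - 1) * config$time_step_min
  ph_upper <- ph_schedule(times, config$ph_initial, config$ph_final,
                          config$onset_min, config$tau_min)
  ph_lower <- ph_upper + config$flank_delta_ph
  lower_rows <- seq_len(h) > h / 2

  data <- array(0, c(h, w, 2, config$n_frames))
  withr::with_seed(config$seed, {
    for (t in seq_len(config$n_frames)) {
      b <- matrix(quench_fraction(ph_upper[t], config$pKa), h, w)
      b[lower_rows, ] <- quench_fraction(ph_lower[t], config$pKa)
      ref <- matrix(config$background_intensity, h, w)
      ref[wall] <- config$ref_wall_intensity
      sen <- matrix(config$background_intensity, h, w)
      sen[wall] <- (config$ref_wall_intensity * b)[wall]
      if (config$noise_sd > 0) {
        ref <- ref + rnorm(h * w, 0, config$noise_sd)
        sen <- sen + rnorm(h * w, 0, config$noise_sd)
      }
      data[, , 1, t] <- pmax(ref, 0)
      data[, , 2, t] <- pmax(sen, 0)
    }
  })

  series <- image_series(data, channels = c("ref", "sense"),
                         pixel_size_um = config$pixel_size_um,
                         time_step_min = config$time_step_min,
                         t_start_min = config$t_start_min)
  truth <- list(
    wall = wall,
    ph = tibble(
      frame = seq_len(config$n_frames), time_min = times,
      ph_upper = ph_upper, ph_lower = ph_lower,
      ratio_upper = quench_fraction(ph_upper, config$pKa),
      ratio_lower = quench_fraction(ph_lower, config$pKa)
    ),
    true_onset_min = config$onset_min,
    config = config
  )
  list(series = series, truth = truth)
}

#' Configuration for the synthetic elongation (scanner) series
#'
#' Describes a single-channel time series of a bright segment silhouette on a
#' dark background, as produced by flatbed-scanner imaging of excised
#' hypocotyl segments. The true tip-to-tip length is constant at
#' `initial_length_px` through the lag phase, then grows linearly:
#' `L(t) = L0 * (1 + growth_rate_pct_per_hr/100 * (t - onset_min)/60)`.
#' Defaults emulate a 2-hour assay sampled every 5 minutes with growth
#' starting 20 minutes after treatment at 30 %/hr.
#'
#' @param initial_length_px True tip-to-tip segment length at t = 0 (pixels).
#' @param onset_min End of the lag phase in minutes.
#' @param growth_rate_pct_per_hr Post-onset slope of percent length per hour,
#'   applied to the initial length.
#' @param length_noise_sd_px Per-frame jitter of the rendered length
#'   (measurement noise; the recorded ground truth is the noiseless length).
#' @param angle_jitter_deg Per-frame pose wobble (degrees, sd of a Gaussian).
#' @param base_angle_deg Mean orientation of the segment (0 = horizontal).
#' @param rod_width_px Silhouette width in pixels.
#' @param image_height_px,image_width_px Frame size in pixels.
#' @param fg_intensity,bg_intensity Foreground/background intensity.
#' @param noise_sd Additive Gaussian intensity noise sd, clipped at zero.
#' @param px_per_mm Spatial calibration (pixels per millimetre).
#' @param n_frames,time_step_min,t_start_min,seed As in [ph_series_config()].
#' @return A validated `growth_series_config` list.
#' @export
growth_series_config <- function(initial_length_px = 200, onset_min = 20,
                                 growth_rate_pct_per_hr = 30,
                                 length_noise_sd_px = 1,
                                 angle_jitter_deg = 1,
                                 base_angle_deg = 0,
                                 rod_width_px = 9,
                                 image_height_px = 120, image_width_px = 340,
                                 fg_intensity = 1000, bg_intensity = 50,
                                 noise_sd = 20, px_per_mm = 100,
                                 n_frames = 24, time_step_min = 5,
                                 t_start_min = 0, seed = 1) {
  cfg <- list(
    initial_length_px = initial_length_px, onset_min = onset_min,
    growth_rate_pct_per_hr = growth_rate_pct_per_hr,
    length_noise_sd_px = length_noise_sd_px,
    angle_jitter_deg = angle_jitter_deg, base_angle_deg = base_angle_deg,
    rod_width_px = rod_width_px,
    image_height_px = image_height_px, image_width_px = image_width_px,
    fg_intensity = fg_intensity, bg_intensity = bg_intensity,
    noise_sd = noise_sd, px_per_mm = px_per_mm,
    n_frames = n_frames, time_step_min = time_step_min,
    t_start_min = t_start_min, seed = seed
  )
  check_number(cfg$initial_length_px, "initial_length_px", 0, strict = TRUE)
  check_number(cfg$onset_min, "onset_min", 0)
  check_number(cfg$growth_rate_pct_per_hr, "growth_rate_pct_per_hr", 0)
  check_number(cfg$length_noise_sd_px, "length_noise_sd_px", 0)
  check_number(cfg$angle_jitter_deg, "angle_jitter_deg", 0)
  check_number(cfg$base_angle_deg, "base_angle_deg", -180)
  check_number(cfg$rod_width_px, "rod_width_px", 2)
  check_number(cfg$image_height_px, "image_height_px", 8, integer = TRUE)
  check_number(cfg$image_width_px, "image_width_px", 8, integer = TRUE)
  check_number(cfg$fg_intensity, "fg_intensity", 0, strict = TRUE)
  check_number(cfg$bg_intensity, "bg_intensity", 0)
  check_number(cfg$noise_sd, "noise_sd", 0)
  check_number(cfg$px_per_mm, "px_per_mm", 0, strict = TRUE)
  check_number(cfg$n_frames, "n_frames", 2, integer = TRUE)
  check_number(cfg$time_step_min, "time_step_min", 0, strict = TRUE)
  check_number(cfg$seed, "seed", integer = TRUE)
  if (cfg$rod_width_px >= cfg$initial_length_px) {
    abort("invalid value for field `rod_width_px`: must be smaller than `initial_length_px`",
          class = "areakymo_validation_error")
  }
  # the rod must still fit at its final length (checked at the mean pose;
  # render_capsule() re-checks each realized pose)
  t_end <- cfg$t_start_min + (cfg$n_frames - 1) * cfg$time_step_min
  l_final <- true_length_px(t_end, cfg)
  a <- cfg$base_angle_deg * pi / 180
  ext_x <- abs(cos(a)) * l_final + abs(sin(a)) * cfg$rod_width_px
  ext_y <- abs(sin(a)) * l_final + abs(cos(a)) * cfg$rod_width_px
  if (ext_x > cfg$image_width_px - 2 || ext_y > cfg$image_height_px - 2) {
    abort("rod exceeds the frame bounds at its final length; enlarge the frame or shorten the series",
          class = "areakymo_validation_error")
  }
  structure(cfg, class = "growth_series_config")
}

true_length_px <- function(time_min, config) {
  ifelse(time_min <= config$onset_min, config$initial_length_px,
         config$initial_length_px *
           (1 + config$growth_rate_pct_per_hr / 100 *
              (time_min - config$onset_min) / 60))
}

# logical mask of a capsule (a segment dilated by half its width) with
# tip-to-tip length `length_px`, centred at (cx, cy) in 0-based pixel
# coordinates, at `angle_deg` (0 horizontal, +90 vertical-up, y down)
render_capsule <- function(height, width, cx, cy, length_px, angle_deg,
                           width_px) {
  rad <- width_px / 2
  half <- max(length_px / 2 - rad, 0)
  a <- angle_deg * pi / 180
  ux <- cos(a); uy <- -sin(a)
  p1 <- c(cx - half * ux, cy - half * uy)
  p2 <- c(cx + half * ux, cy + half * uy)
  if (min(p1[1], p2[1]) - rad < 0 || max(p1[1], p2[1]) + rad > width - 1 ||
      min(p1[2], p2[2]) - rad < 0 || max(p1[2], p2[2]) + rad > height - 1) {
    abort("rod exceeds the frame bounds", class = "areakymo_validation_error")
  }
  px <- rep(seq_len(width) - 1, each = height)
  py <- rep(seq_len(height) - 1, times = width)
  vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
  len2 <- vx^2 + vy^2
  tt <- if (len2 > 0) pmin(pmax(((px - p1[1]) * vx + (py - p1[2]) * vy) / len2, 0), 1) else 0
  d2 <- (px - (p1[1] + tt * vx))^2 + (py - (p1[2] + tt * vy))^2
  matrix(d2 <= rad^2, nrow = height, ncol = width)
}

#' Generate a synthetic elongation series
#'
#' Renders a bright rod (segment silhouette) on a dark background. The rod is
#' drawn as a capsule so that its true maximum-caliper length equals the
#' nominal tip-to-tip length exactly. Pose wobble and length jitter emulate
#' scanner repositioning and measurement noise; the recorded ground truth is
#' the noiseless length schedule.
#'
#' @param config A [growth_series_config()].
#' @return A list with `series` (single-channel [image_series()]) and `truth`
#'   (tibble `true_length` with `time_min`, `length_px`; `true_onset_min`;
#'   per-frame rendered angles).
#' @export
generate_elongation_series <- function(config) {
  stopifnot(inherits(config, "growth_series_config"))
  h <- config$image_height_px; w <- config$image_width_px
  times <- config$t_start_min + (seq_len(config$n_frames) - 1) * config$time_step_min
  l_true <- true_length_px(times, config)
  cx <- (w - 1) / 2; cy <- (h - 1) / 2

  data <- array(0, c(h, w, 1, config$n_frames))
  angles <- numeric(config$n_frames)
  withr::with_seed(config$seed, {
    for (t in seq_len(config$n_frames)) {
      ang <- config$base_angle_deg +
        if (config$angle_jitter_deg > 0) rnorm(1, 0, config$angle_jitter_deg) else 0
      len <- l_true[t] +
        if (config$length_noise_sd_px > 0) rnorm(1, 0, config$length_noise_sd_px) else 0
      angles[t] <- ang
      cap <- render_capsule(h, w, cx, cy, max(len, config$rod_width_px), ang,
                            config$rod_width_px)
      fr <- matrix(config$bg_intensity, h, w)
      fr[cap] <- config$fg_intensity
      if (config$noise_sd > 0) fr <- fr + rnorm(h * w, 0, config$noise_sd)
      data[, , 1, t] <- pmax(fr, 0)
    }
  })

  series <- image_series(data, channels = "signal",
                         pixel_size_um = 1000 / config$px_per_mm,
                         time_step_min = config$time_step_min,
                         t_start_min = config$t_start_min)
  truth <- list(
    true_length = tibble(frame = seq_len(config$n_frames),
                         time_min = times, length_px = l_true),
    true_onset_min = config$onset_min,
    angles_deg = angles,
    config = config
  )
  list(series = series, truth = truth)
}

#' Generate a synthetic luminescence trace
#'
#' Mean region-of-interest luminescence of a transcriptional reporter:
#' constant `baseline` through the lag phase, then a saturating exponential
#' rise toward `baseline + amplitude` with time constant `rise_tau_min`. The
#' trace is continuous at the onset.
#'
#' @param baseline Pre-onset signal level.
#' @param amplitude Asymptotic rise above baseline (>= 0).
#' @param onset_min Lag-phase end in minutes.
#' @param rise_tau_min Rise time constant in minutes.
#' @param n_frames,time_step_min,t_start_min Sampling of the trace.
#' @param noise_sd Additive Gaussian noise sd.
#' @param seed Integer RNG seed.
#' @return A list with `trace` (tibble `time_min`, `value`) and `truth`
#'   (noiseless values and `true_onset_min`).
#' @export
generate_luminescence_trace <- function(baseline = 100, amplitude = 400,
                                        onset_min = 20, rise_tau_min = 40,
                                        n_frames = 12, time_step_min = 5,
                                        t_start_min = 0, noise_sd = 5,
                                        seed = 1) {
  check_number(baseline, "baseline", 0)
  check_number(amplitude, "amplitude", 0)
  check_number(onset_min, "onset_min", 0)
  check_number(rise_tau_min, "rise_tau_min", 0, strict = TRUE)
  check_number(n_frames, "n_frames", 2, integer = TRUE)
  check_number(time_step_min, "time_step_min", 0, strict = TRUE)
  check_number(noise_sd, "noise_sd", 0)
  check_number(seed, "seed", integer = TRUE)
  times <- t_start_min + (seq_len(n_frames) - 1) * time_step_min
  clean <- ifelse(times < onset_min, baseline,
                  baseline + amplitude * (1 - exp(-(times - onset_min) / rise_tau_min)))
  noisy <- withr::with_seed(seed, clean + rnorm(n_frames, 0, noise_sd))
  list(
    trace = tibble(time_min = times, value = noisy),
    truth = list(values = clean, true_onset_min = onset_min)
  )
}

#' Generate a synthetic gravitropic bending series
#'
#' Renders binary rod masks whose orientation rotates from `start_angle_deg`
#' toward `final_angle_deg` at `rate_deg_per_hr`, saturating at the final
#' angle. Angles follow the convention 0 degrees = horizontal, +90 degrees =
#' vertical (up), with image y pointing down.
#'
#' @param start_angle_deg,final_angle_deg Initial and final angles in
#'   `[-180, 180]`.
#' @param rate_deg_per_hr Rotation rate in degrees per hour (>= 0).
#' @param n_frames,time_step_min,t_start_min Sampling.
#' @param rod_length_px,rod_width_px Rod geometry in pixels.
#' @param image_height_px,image_width_px Frame size.
#' @param seed Integer RNG seed (reserved; the default series is noiseless).
#' @return A list with `series` (single-channel binary [image_series()]) and
#'   `truth` (tibble `time_min`, `angle_deg`).
#' @export
generate_bending_series <- function(start_angle_deg = 0, final_angle_deg = 90,
                                    rate_deg_per_hr = 30, n_frames = 13,
                                    time_step_min = 30, t_start_min = 0,
                                    rod_length_px = 80, rod_width_px = 7,
                                    image_height_px = 128,
                                    image_width_px = 128, seed = 1) {
  for (a in c(start_angle_deg, final_angle_deg)) {
    if (!is.finite(a) || a < -180 || a > 180) {
      abort("invalid value for field `start_angle_deg`/`final_angle_deg`: must lie in [-180, 180]",
            class = "areakymo_validation_error")
    }
  }
  check_number(rate_deg_per_hr, "rate_deg_per_hr", 0)
  check_number(n_frames, "n_frames", 1, integer = TRUE)
  check_number(time_step_min, "time_step_min", 0, strict = TRUE)
  check_number(rod_length_px, "rod_length_px", 4)
  check_number(rod_width_px, "rod_width_px", 2)
  check_number(seed, "seed", integer = TRUE)

  times <- t_start_min + (seq_len(n_frames) - 1) * time_step_min
  total <- final_angle_deg - start_angle_deg
  prog <- pmin(rate_deg_per_hr * times / 60, abs(total))
  angles <- start_angle_deg + sign(total) * prog

  h <- image_height_px; w <- image_width_px
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  data <- array(0, c(h, w, 1, n_frames))
  base_x <- base_y <- numeric(n_frames)
  for (t in seq_len(n_frames)) {
    cap <- render_capsule(h, w, cx, cy, rod_length_px, angles[t],
                          rod_width_px)
    data[, , 1, t] <- cap * 1
    a <- angles[t] * pi / 180
    base_x[t] <- cx - rod_length_px / 2 * cos(a)
    base_y[t] <- cy + rod_length_px / 2 * sin(a)
  }
  series <- image_series(data, channels = "signal",
                         time_step_min = time_step_min,
                         t_start_min = t_start_min)
  list(series = series,
       truth = list(angle = tibble(time_min = times, angle_deg = angles,
                                   base_x = base_x, base_y = base_y)))
}

#' Inject a known drift into a series
#'
#' Circularly rolls every frame of a series by a per-frame shift, emulating
#' stage drift with a known ground truth. Circular rolling keeps every pixel,
#' so translation estimation can be checked for exact recovery.
#'
#' @param series An [image_series()].
#' @param shifts A data frame with columns `dx_px`, `dy_px` (integer pixels),
#'   one row per frame: the displacement of each frame's content relative to
#'   its undrifted position (x rightward, y downward).
#' @return The drifted `image_series`.
#' @export
inject_drift <- function(series, shifts) {
  stopifnot(inherits(series, "image_series"))
  shifts <- as.data.frame(shifts)
  if (nrow(shifts) != n_frames(series)) {
    abort("`shifts` must have one row per frame",
          class = "areakymo_validation_error")
  }
  out <- series
  for (t in seq_len(n_frames(series))) {
    for (ch in seq_len(n_channels(series))) {
      out$data[, , ch, t] <- roll_matrix(series$data[, , ch, t],
                                         shifts$dx_px[t], shifts$dy_px[t])
    }
  }
  out
}
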