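#' Assay configuration
#'
#' Bundles the user inputs shared by the end-to-end assay runners: channel
#' mapping, wall threshold, area-kymograph rectangle geometry, calibration
#' and onset settings. Pixel coordinates are 0-based (x rightward,
#' y downward); time is minutes since treatment.
#'
#' @param channel_labels Channel labels in TIFF page order (reference first
#'   for ratiometric stacks).
#' @param threshold Reference-channel wall threshold (ratiometric assays) or
#'   `"auto"` (elongation/gravitropism, Otsu).
#' @param rect_width,rows_per_block Area-kymograph rectangle geometry.
#' @param px_per_mm Spatial calibration for length traces (optional).
#' @param pixel_size_um Pixel size in micrometres; `NULL` takes the value
#'   recorded in the input file or series.
#' @param time_step_min,t_start_min Temporal calibration; `NULL` takes the
#'   values recorded in the input file or series.
#' @param direction Onset direction for the assay's trace.
#' @param min_points_per_arm Passed to [detect_onset()].
#' @param register Stabilize drift before ratio analysis?
#' @param seed Seed for any stochastic step (bootstrap).
#' @param out_dir Output directory; `NULL` disables file output.
#' @return An `assay_config` list.
#' @export
assay_config <- function(channel_labels = c("ref", "sense"), threshold = 500,
                         rect_width = 50, rows_per_block = 20,
                         px_per_mm = NA_real_, pixel_size_um = NULL,
                         time_step_min = NULL, t_start_min = NULL,
                         direction = "decrease", min_points_per_arm = 2,
                         register = TRUE, seed = 1, out_dir = NULL) {
  cfg <- list(channel_labels = channel_labels, threshold = threshold,
              rect_width = rect_width, rows_per_block = rows_per_block,
              px_per_mm = px_per_mm, pixel_size_um = pixel_size_um,
              time_step_min = time_step_min, t_start_min = t_start_min,
              direction = direction,
              min_points_per_arm = min_points_per_arm,
              register = register, seed = seed, out_dir = out_dir)
  if (!identical(cfg$threshold, "auto")) {
    check_number(cfg$threshold, "threshold", 0, strict = TRUE)
  }
  check_number(cfg$rect_width, "rect_width", 1, integer = TRUE)
  check_number(cfg$rows_per_block, "rows_per_block", 1, integer = TRUE)
  if (!is.null(cfg$time_step_min)) {
    check_number(cfg$time_step_min, "time_step_min", 0, strict = TRUE)
  }
  check_number(cfg$min_points_per_arm, "min_points_per_arm", 2, integer = TRUE)
  check_flag(cfg$register, "register")
  if (!cfg$direction %in% c("increase", "decrease")) {
    abort("invalid value for field `direction`: must be \"increase\" or \"decrease\"",
          class = "areakymo_validation_error")
  }
  structure(cfg, class = "assay_config")
}

series_sidecar_path <- function(path) paste0(path, ".json")

write_series_sidecar <- function(series, path, bits) {
  jsonlite::write_json(list(
    format = "areakymo-series", version = 1L, bits = bits,
    channels = series$channels,
    pixel_size_um = series$pixel_size_um,
    time_step_min = series$time_step_min,
    t_start_min = series$t_start_min
  ), series_sidecar_path(path), auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Write an image series as a multi-page TIFF
#'
#' Pages are ordered frame by frame with channels in label order inside each
#' frame (reference before sense for ratiometric stacks). Intensities are
#' stored as integer counts at the requested bit depth — the native
#' representation of camera and scanner data — so writing rounds non-integer
#' intensities; the channel layout and calibration are recorded in a JSON
#' sidecar (`<path>.json`). Reading back an integer-valued series is
#' bit-identical.
#'
#' @param series An [image_series()].
#' @param path Output file.
#' @param bits Bits per sample (8, 16 or 32).
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, bits = 16) {
  stopifnot(inherits(series, "image_series"))
  if (!bits %in% c(8, 16, 32)) {
    abort("`bits` must be 8, 16 or 32", class = "areakymo_validation_error")
  }
  maxval <- 2^bits - 1
  vals <- round(series$data)
  vals[is.na(vals)] <- 0
  if (max(vals) > maxval) {
    abort(sprintf("intensities exceed the %d-bit range; use a higher bit depth",
                  bits), class = "areakymo_validation_error")
  }
  pages <- list()
  for (t in seq_len(n_frames(series))) {
    for (ch in seq_len(n_channels(series))) {
      pages[[length(pages) + 1]] <- vals[, , ch, t] / maxval
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits),
                  reduce = FALSE)
  write_series_sidecar(series, path, bits)
  invisible(path)
}

#' Read a multi-page TIFF as an image series
#'
#' The page count must be divisible by the channel count; pages are assumed
#' frame-major with channels in declared order within each frame (the layout
#' written by [write_series()]). Calibration recorded in the sidecar written
#' by [write_series()] is honoured; calibration passed as arguments overrides
#' it, with a warning on conflict.
#'
#' @param path TIFF file.
#' @param channels Channel labels in page order; defaults to the labels
#'   recorded in the file, else a single `"signal"` channel.
#' @param pixel_size_um,time_step_min,t_start_min Calibration overrides.
#' @return An [image_series()].
#' @export
read_series <- function(path, channels = NULL, pixel_size_um = NULL,
                        time_step_min = NULL, t_start_min = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path),
          class = "areakymo_validation_error")
  }
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, function(p) dim(p)[1:2], c(0, 0))
  bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])
  if (length(bad)) {
    abort(sprintf("inconsistent page geometry at page %d", bad[1]),
          class = "areakymo_validation_error")
  }
  meta <- list()
  sidecar <- series_sidecar_path(path)
  if (file.exists(sidecar)) {
    meta <- tryCatch(jsonlite::fromJSON(sidecar), error = function(e) list())
  }
  if (!identical(meta$format, "areakymo-series")) meta <- list()
  bits <- meta$bits %||% attr(pages[[1]], "bits.per.sample") %||% 16
  if (!is.null(channels) && !is.null(meta$channels) &&
      length(channels) != length(meta$channels)) {
    warn(sprintf(
      "declared channel count (%d) conflicts with the file's recorded layout (%d); using the file's",
      length(channels), length(meta$channels)))
    channels <- meta$channels
  }
  channels <- channels %||% meta$channels %||% "signal"
  nc <- length(channels)
  if (length(pages) %% nc != 0) {
    abort(sprintf("page count (%d) is not divisible by the channel count (%d)",
                  length(pages), nc), class = "areakymo_validation_error")
  }
  override <- function(arg, name, default) {
    file_val <- meta[[name]]
    if (is.null(arg)) return(file_val %||% default)
    if (!is.null(file_val) && !isTRUE(all.equal(arg, file_val))) {
      warn(sprintf("`%s` = %g overrides the value recorded in the file (%g)",
                   name, arg, file_val))
    }
    arg
  }
  nt <- length(pages) %/% nc
  h <- dims[1, 1]; w <- dims[2, 1]
  data <- array(0, c(h, w, nc, nt))
  maxval <- 2^bits - 1
  k <- 1
  for (t in seq_len(nt)) {
    for (ch in seq_len(nc)) {
      p <- pages[[k]]
      if (length(dim(p)) == 3) p <- p[, , 1]
      data[, , ch, t] <- round(p * maxval)
      k <- k + 1
    }
  }
  image_series(
    data, channels = channels,
    pixel_size_um = override(pixel_size_um, "pixel_size_um", 1),
    time_step_min = override(time_step_min, "time_step_min", 1),
    t_start_min = override(t_start_min, "t_start_min", 0)
  )
}

#' Simulate an assay dataset on disk
#'
#' Generates a synthetic dataset and writes the image stack (or trace), the
#' ground truth (CSV + JSON sidecar) and a run report into `out_dir`.
#'
#' @param kind One of `"ph"`, `"elongation"`, `"luminescence"`, `"bending"`.
#' @param config The matching generator configuration ([ph_series_config()],
#'   [growth_series_config()], or an argument list for the trace/bending
#'   generators).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of the written file paths.
#' @export
simulate_assay <- function(kind = c("ph", "elongation", "luminescence",
                                    "bending"),
                           config = NULL, out_dir) {
  kind <- match.arg(kind)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  write_truth <- function(truth, tbl) {
    paths$truth_csv <<- file.path(out_dir, paste0(kind, "_truth.csv"))
    readr::write_csv(tbl, paths$truth_csv)
    paths$truth_json <<- file.path(out_dir, paste0(kind, "_truth.json"))
    jsonlite::write_json(truth, paths$truth_json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  if (kind == "ph") {
    config <- config %||% ph_series_config()
    out <- generate_ph_series(config)
    paths$tiff <- file.path(out_dir, "ph_series.tif")
    write_series(out$series, paths$tiff)
    write_truth(list(true_onset_min = out$truth$true_onset_min,
                     config = unclass(config)),
                out$truth$ph)
  } else if (kind == "elongation") {
    config <- config %||% growth_series_config()
    out <- generate_elongation_series(config)
    paths$tiff <- file.path(out_dir, "elongation_series.tif")
    write_series(out$series, paths$tiff)
    write_truth(list(true_onset_min = out$truth$true_onset_min,
                     config = unclass(config)),
                out$truth$true_length)
  } else if (kind == "luminescence") {
    out <- do.call(generate_luminescence_trace, config %||% list())
    paths$trace_csv <- file.path(out_dir, "luminescence_trace.csv")
    readr::write_csv(out$trace, paths$trace_csv)
    write_truth(list(true_onset_min = out$truth$true_onset_min),
                tibble(time_min = out$trace$time_min,
                       value = out$truth$values))
  } else {
    out <- do.call(generate_bending_series, config %||% list())
    paths$tiff <- file.path(out_dir, "bending_series.tif")
    write_series(out$series, paths$tiff, bits = 8)
    write_truth(list(), out$truth$angle)
  }
  report <- run_report("simulate", list(kind = kind), paths)
  paths$report <- file.path(out_dir, "run_report.json")
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

run_report <- function(stage, provenance, files) {
  existing <- files[vapply(files, function(f)
    is.character(f) && file.exists(f), TRUE)]
  list(
    tool = "areakymo",
    version = as.character(utils::packageVersion("areakymo")),
    stage = stage,
    provenance = provenance,
    files = lapply(existing, function(f)
      list(path = f, md5 = unname(tools::md5sum(f))))
  )
}

resolve_series <- function(series, config,
                           channels = config$channel_labels) {
  if (is.character(series)) {
    read_series(series, channels = channels,
                pixel_size_um = config$pixel_size_um,
                time_step_min = config$time_step_min,
                t_start_min = config$t_start_min)
  } else {
    series
  }
}

#' Run the ratiometric pH assay end to end
#'
#' Drift stabilization (optional), wall-pixel selection on the reference
#' channel, per-pixel sense/reference ratios, area-kymograph rendering,
#' boxplot summaries, and onset detection on the per-frame median ratio.
#'
#' @param series An [image_series()] or a TIFF path.
#' @param config An [assay_config()].
#' @return A list of class `ph_assay` with `kymo` ([area_kymograph()]
#'   result), `summary` ([frame_summary()] tibble), `shifts`, `onset`
#'   ([detect_onset()] result) and `report`. When `config$out_dir` is set,
#'   the summary and shift CSVs, the kymograph (16-bit TIFF + PNG), the
#'   onset JSON and the run report are written there.
#' @export
run_ph_assay <- function(series, config = assay_config()) {
  series <- resolve_series(series, config)
  shifts <- NULL
  if (config$register && n_frames(series) >= 2) {
    shifts <- estimate_translation(series, channel = config$channel_labels[1])
    series <- apply_shifts(series, shifts)
  }
  mask <- wall_mask(series, config$threshold,
                    channel = config$channel_labels[1])
  samples <- pixel_ratios(series, mask, ref = config$channel_labels[1],
                          sense = config$channel_labels[2])
  kymo <- area_kymograph(samples, config$rect_width, config$rows_per_block)
  summary <- frame_summary(samples)
  trace <- summary |>
    dplyr::filter(!is.na(.data$median)) |>
    dplyr::transmute(time_min = .data$time_min, value = .data$median)
  onset <- detect_onset(trace, direction = config$direction,
                        min_points_per_arm = config$min_points_per_arm)
  paths <- list()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths$summary_csv <- file.path(config$out_dir, "ph_summary.csv")
    readr::write_csv(
      dplyr::left_join(summary,
                       kymo$provenance[, c("frame", "dropped")], by = "frame"),
      paths$summary_csv)
    if (!is.null(shifts)) {
      paths$shifts_csv <- file.path(config$out_dir, "shifts.csv")
      readr::write_csv(as_tibble(shifts), paths$shifts_csv)
    }
    paths$kymo_tiff <- file.path(config$out_dir, "area_kymo.tif")
    write_kymo_tiff(kymo, paths$kymo_tiff)
    paths$kymo_png <- file.path(config$out_dir, "area_kymo.png")
    ggplot2::ggsave(paths$kymo_png, autoplot(kymo), width = 4, height = 6,
                    dpi = 150)
    paths$onset_json <- file.path(config$out_dir, "ph_onset.json")
    jsonlite::write_json(as.list(glance(onset)), paths$onset_json,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report <- run_report(
    "ph_assay",
    list(threshold = mask$threshold_value,
         n_pixels = mask$n_pixels,
         dropped = kymo$provenance$dropped,
         shifts = if (is.null(shifts)) NULL else as.data.frame(shifts),
         lut_range = kymo$lut_range),
    paths)
  if (!is.null(config$out_dir)) {
    paths$report <- file.path(config$out_dir, "run_report.json")
    jsonlite::write_json(report, paths$report, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  structure(list(kymo = kymo, summary = summary, shifts = shifts,
                 onset = onset, report = report, files = paths),
            class = "ph_assay")
}

# 16-bit TIFF of the kymograph canvas, scaled to the LUT range;
# no-data cells are written as 0 and the LUT range goes to a JSON sidecar
write_kymo_tiff <- function(kymo, path) {
  lut <- kymo$lut_range
  canvas <- kymo$canvas
  if (anyNA(lut) || diff(lut) == 0) {
    scaled <- matrix(0, nrow(canvas), ncol(canvas))
  } else {
    scaled <- (canvas - lut[1]) / diff(lut) * (65534 / 65535) + 1 / 65535
    scaled[is.na(scaled)] <- 0
  }
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  jsonlite::write_json(list(lut_range = lut, no_data = 0),
                       series_sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Run the elongation assay end to end
#'
#' Per-frame silhouette segmentation, Feret-diameter length measurement,
#' normalization to the initial length, and onset detection on the
#' percentage trace.
#'
#' @param series A single-channel [image_series()] or TIFF path.
#' @param config An [assay_config()] (use `threshold = "auto"` for Otsu and
#'   `direction = "increase"`).
#' @param selection_point Optional seed `c(x, y)` passed to [segment_mask()].
#' @return A list of class `elongation_assay` with `trace`
#'   ([growth_trace()] tibble), `onset` and `report`.
#' @export
run_elongation_assay <- function(series,
                                 config = assay_config(threshold = "auto",
                                                       direction = "increase"),
                                 selection_point = NULL) {
  series <- resolve_series(series, config, channels = NULL)
  masks <- purrr::map(seq_len(n_frames(series)), function(t) {
    segment_mask(get_frame(series, t, 1), threshold = config$threshold,
                 selection_point = selection_point)
  })
  trace <- growth_trace(masks, time_step_min = series$time_step_min,
                        t_start_min = series$t_start_min,
                        px_per_mm = config$px_per_mm)
  onset <- detect_onset(
    dplyr::transmute(trace, time_min = .data$time_min,
                     value = .data$length_pct),
    direction = "increase",
    min_points_per_arm = config$min_points_per_arm)
  paths <- list()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths$trace_csv <- file.path(config$out_dir, "growth_trace.csv")
    readr::write_csv(as_tibble(trace), paths$trace_csv)
    paths$onset_json <- file.path(config$out_dir, "growth_onset.json")
    jsonlite::write_json(as.list(glance(onset)), paths$onset_json,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report <- run_report(
    "elongation_assay",
    list(thresholds = vapply(masks, attr, 0, "threshold"),
         policy = attr(masks[[1]], "policy")),
    paths)
  if (!is.null(config$out_dir)) {
    paths$report <- file.path(config$out_dir, "run_report.json")
    jsonlite::write_json(report, paths$report, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  structure(list(trace = trace, onset = onset, report = report,
                 files = paths),
            class = "elongation_assay")
}

#' Run the gravitropism assay
#'
#' Either a tip-angle trace over time (`mode = "angle"`) or a flank
#' pH-asymmetry report from a z-stack and two flank ROIs (`mode = "flank"`).
#'
#' @param series An [image_series()] or TIFF path.
#' @param config An [assay_config()].
#' @param mode `"angle"` or `"flank"`.
#' @param upper_roi,lower_roi Flank polygons (required for `mode = "flank"`).
#' @param tip_window_px,basal_point Passed to [tip_angle()].
#' @return A list of class `gravitropism_assay` with `angles`
#'   (a [bend_angle_trace()]) or `flanks` (a [flank_ratio()]), plus `report`.
#' @export
run_gravitropism <- function(series, config = assay_config(),
                             mode = c("angle", "flank"),
                             upper_roi = NULL, lower_roi = NULL,
                             tip_window_px = NULL, basal_point = NULL) {
  mode <- match.arg(mode)
  series <- resolve_series(series, config,
                           channels = if (mode == "angle") NULL else
                             config$channel_labels)
  paths <- list()
  if (mode == "angle") {
    thr <- if (identical(config$threshold, "auto")) 0.5 else config$threshold
    angles <- bend_angle_trace(series, threshold = thr,
                               tip_window_px = tip_window_px,
                               basal_point = basal_point)
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      paths$angles_csv <- file.path(config$out_dir, "bend_angles.csv")
      readr::write_csv(as_tibble(angles), paths$angles_csv)
    }
    report <- run_report("gravitropism_angle", list(threshold = thr), paths)
    result <- list(angles = angles, report = report, files = paths)
  } else {
    if (is.null(upper_roi) || is.null(lower_roi)) {
      abort("flank mode needs `upper_roi` and `lower_roi`",
            class = "areakymo_validation_error")
    }
    flanks <- flank_ratio(series, upper_roi, lower_roi, config$threshold)
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      paths$flanks_csv <- file.path(config$out_dir, "flank_ratios.csv")
      readr::write_csv(flanks$sections, paths$flanks_csv)
    }
    report <- run_report("gravitropism_flank",
                         list(threshold = config$threshold,
                              n_skipped = flanks$n_skipped), paths)
    result <- list(flanks = flanks, report = report, files = paths)
  }
  if (!is.null(config$out_dir)) {
    paths$report <- file.path(config$out_dir, "run_report.json")
    jsonlite::write_json(report, paths$report, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    result$files <- paths
  }
  structure(result, class = "gravitropism_assay")
}
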