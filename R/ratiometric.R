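#' Select cell-wall pixels on the reference channel
#'
#' The AreaKymo wall selection: per frame, every pixel whose reference-channel
#' intensity is strictly above a user-chosen threshold is taken as cell wall.
#' The threshold is set to separate the bright wall signal from background; it
#' is an analysis input, not an estimated quantity.
#'
#' @param series A two-channel [image_series()].
#' @param threshold Reference-channel cutoff (> 0); pixels strictly above it
#'   are selected.
#' @param channel Channel used for selection (default `"ref"`).
#' @return A `wall_mask`: list with `masks` (logical `H x W x T` array),
#'   `threshold_value`, `channel` and per-frame `n_pixels`. A frame with an
#'   empty mask triggers a warning and is recorded with `n_pixels = 0`.
#' @examples
#' out <- generate_ph_series(ph_series_config(noise_sd = 0, onset_min = 5,
#'                                             n_frames = 3))
#' m <- wall_mask(out$series, threshold = 500)
#' m$n_pixels
#' @export
wall_mask <- function(series, threshold, channel = "ref") {
  stopifnot(inherits(series, "image_series"))
  check_number(threshold, "threshold", 0, strict = TRUE)
  ci <- channel_index(series, channel)
  ref <- series$data[, , ci, , drop = FALSE]
  dim(ref) <- dim(series$data)[c(1, 2, 4)]
  masks <- ref > threshold
  masks[is.na(masks)] <- FALSE
  n_pixels <- apply(masks, 3, sum)
  if (any(n_pixels == 0)) {
    warn(sprintf("empty wall mask in frame(s) %s",
                 paste(which(n_pixels == 0), collapse = ", ")))
  }
  structure(
    list(masks = masks, threshold_value = threshold, channel = channel,
         n_pixels = as.integer(n_pixels)),
    class = "wall_mask"
  )
}

#' Per-pixel sense/reference ratios at wall pixels
#'
#' Computes the ratio `sense / ref` at every masked pixel of every frame. The
#' ratio is oriented so that a lower value means a more acidic apoplast (the
#' pH-sensitive channel is quenched at low pH). Pixels are listed in raster
#' order (top-to-bottom, left-to-right within a row), the order used to fill
#' the area-kymograph rectangles.
#'
#' @param series A two-channel [image_series()].
#' @param mask A [wall_mask()] conforming to `series`.
#' @param ref,sense Channel labels.
#' @return A tibble of class `ratio_sample` with columns `frame`, `time_min`,
#'   `row`, `col` (0-based y/x of the pixel), `ref`, `sense`, `ratio`. Frames
#'   with empty masks contribute no rows; the per-frame bookkeeping (including
#'   `n = 0` frames) is kept in the `frames` attribute.
#' @export
pixel_ratios <- function(series, mask, ref = "ref", sense = "sense") {
  stopifnot(inherits(series, "image_series"), inherits(mask, "wall_mask"))
  if (!all(dim(mask$masks) == dim(series$data)[c(1, 2, 4)])) {
    abort("mask geometry does not match the series",
          class = "areakymo_validation_error")
  }
  ri <- channel_index(series, ref)
  si <- channel_index(series, sense)
  times <- frame_times(series)
  per_frame <- purrr::map(seq_len(n_frames(series)), function(t) {
    m <- mask$masks[, , t]
    idx <- which(m, arr.ind = TRUE)
    if (nrow(idx) == 0) return(NULL)
    ord <- order(idx[, 1], idx[, 2])  # raster order
    idx <- idx[ord, , drop = FALSE]
    rv <- series$data[, , ri, t][idx]
    sv <- series$data[, , si, t][idx]
    if (any(!is.finite(rv)) || any(rv <= 0)) {
      abort("reference intensity at a masked pixel is not positive; this should be impossible for threshold > 0",
            class = "areakymo_internal_error")
    }
    tibble(frame = t, time_min = times[t],
           row = idx[, 1] - 1, col = idx[, 2] - 1,
           ref = rv, sense = sv, ratio = sv / rv)
  })
  out <- dplyr::bind_rows(per_frame)
  if (nrow(out) == 0) {
    out <- tibble(frame = integer(), time_min = double(), row = double(),
                  col = double(), ref = double(), sense = double(),
                  ratio = double())
  }
  attr(out, "frames") <- tibble(frame = seq_len(n_frames(series)),
                                time_min = times, n = mask$n_pixels)
  class(out) <- c("ratio_sample", class(out))
  out
}

ratio_frames_attr <- function(samples) {
  fr <- attr(samples, "frames")
  if (is.null(fr)) {
    fr <- samples |>
      dplyr::group_by(.data$frame, .data$time_min) |>
      dplyr::summarise(n = dplyr::n(), .groups = "drop")
  }
  fr
}

#' Build an area kymograph
#'
#' Packs each timepoint's wall-pixel ratios into a fixed-width rectangle and
#' stacks the rectangles top-to-bottom in time order, producing a time-space
#' plot in which every pixel of the original image contributes one cell.
#' Each block is filled row-major (left to right, top to bottom) with the
#' frame's ratios in raster order of their mask coordinates; ratios beyond the
#' block capacity (`rect_width * rows_per_block`) are dropped from the tail
#' and the drop count recorded. Unfilled cells carry `NA`, distinct from any
#' ratio value.
#'
#' @param samples A `ratio_sample` tibble from [pixel_ratios()].
#' @param rect_width Rectangle width in cells (>= 1).
#' @param rows_per_block Rectangle height in cells (>= 1).
#' @return An `area_kymo`: list with `canvas` (numeric matrix,
#'   `T * rows_per_block` rows by `rect_width` columns, `NA` = no data),
#'   `rect_width`, `rows_per_block`, `lut_range` (range of plotted ratios) and
#'   `provenance` (tibble with per-frame `n`, `placed`, `dropped`).
#' @examples
#' out <- generate_ph_series(ph_series_config(noise_sd = 0, onset_min = 5,
#'                                             n_frames = 3))
#' rs <- pixel_ratios(out$series, wall_mask(out$series, 500))
#' ak <- area_kymograph(rs, rect_width = 50, rows_per_block = 20)
#' ak$provenance
#' @export
area_kymograph <- function(samples, rect_width, rows_per_block) {
  check_number(rect_width, "rect_width", 1, integer = TRUE)
  check_number(rows_per_block, "rows_per_block", 1, integer = TRUE)
  frames <- ratio_frames_attr(samples)
  capacity <- rect_width * rows_per_block
  blocks <- vector("list", nrow(frames))
  placed <- integer(nrow(frames)); dropped <- integer(nrow(frames))
  for (i in seq_len(nrow(frames))) {
    vals <- samples$ratio[samples$frame == frames$frame[i]]
    placed[i] <- min(length(vals), capacity)
    dropped[i] <- length(vals) - placed[i]
    cells <- rep(NA_real_, capacity)
    if (placed[i] > 0) cells[seq_len(placed[i])] <- vals[seq_len(placed[i])]
    blocks[[i]] <- matrix(cells, nrow = rows_per_block, ncol = rect_width,
                          byrow = TRUE)
  }
  canvas <- do.call(rbind, blocks)
  lut <- if (all(is.na(canvas))) c(NA_real_, NA_real_) else
    range(canvas, na.rm = TRUE)
  structure(
    list(canvas = canvas, rect_width = rect_width,
         rows_per_block = rows_per_block, lut_range = lut,
         provenance = tibble(frame = frames$frame, time_min = frames$time_min,
                             n = frames$n, placed = placed, dropped = dropped)),
    class = "area_kymo"
  )
}

#' @export
print.area_kymo <- function(x, ...) {
  cat(sprintf("<area_kymo> %d timepoint block(s) of %d x %d cells; %d ratio(s) placed, %d dropped\n",
              nrow(x$provenance), x$rows_per_block, x$rect_width,
              sum(x$provenance$placed), sum(x$provenance$dropped)))
  if (!anyNA(x$lut_range)) {
    cat(sprintf("  LUT range [%.4g, %.4g]\n", x$lut_range[1], x$lut_range[2]))
  }
  invisible(x)
}

#' Per-frame ratio summaries (boxplot series)
#'
#' Five-number summary plus two mean variants of the wall-pixel ratios of
#' every frame, the quantification shown as a series of boxplots alongside an
#' area kymograph. Quartiles use linear interpolation between order
#' statistics (`stats::quantile` type 5). Two mean variants are reported:
#' `mean_of_ratios` (mean of per-pixel ratios) and `ratio_of_means`
#' (mean sense intensity over the mask divided by mean reference intensity,
#' the manual ROI protocol); the two agree exactly when the reference
#' intensity is uniform over the mask.
#'
#' @param samples A `ratio_sample` tibble from [pixel_ratios()].
#' @return A tibble of class `summary_series` with columns `frame`,
#'   `time_min`, `n`, `min`, `q1`, `median`, `q3`, `max`, `mean_of_ratios`,
#'   `ratio_of_means`. Frames with `n = 0` carry `NA` statistics.
#' @export
frame_summary <- function(samples) {
  frames <- ratio_frames_attr(samples)
  if (nrow(frames) < 1) {
    abort("at least one frame is required", class = "areakymo_validation_error")
  }
  if (nrow(samples) == 0) {
    empty <- dplyr::mutate(frames[0, "frame"], min = double(), q1 = double(),
                           median = double(), q3 = double(), max = double(),
                           mean_of_ratios = double(),
                           ratio_of_means = double())
    out <- dplyr::left_join(frames, empty, by = "frame")
    class(out) <- c("summary_series", class(out))
    return(out)
  }
  stats_tbl <- samples |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(
      min = min(.data$ratio),
      q1 = unname(quantile(.data$ratio, 0.25, type = 5)),
      median = unname(quantile(.data$ratio, 0.50, type = 5)),
      q3 = unname(quantile(.data$ratio, 0.75, type = 5)),
      max = max(.data$ratio),
      mean_of_ratios = mean(.data$ratio),
      ratio_of_means = mean(.data$sense) / mean(.data$ref),
      .groups = "drop"
    )
  out <- dplyr::left_join(frames, stats_tbl, by = "frame")
  class(out) <- c("summary_series", class(out))
  out
}

#' Flank asymmetry of the sense/reference ratio
#'
#' Quantifies the pH difference between the two epidermal flanks of a
#' gravistimulated organ: for every z-section (frame), the ratio-of-means is
#' computed within the wall mask intersected with an upper- and a lower-flank
#' polygon ROI, and the paired per-section differences (lower minus upper)
#' are reported. Sections where either flank has an empty mask intersection
#' are skipped and counted.
#'
#' @param zstack A two-channel [image_series()] whose frames are z-sections.
#' @param upper_roi,lower_roi Disjoint polygon ROIs (two-column `x`/`y`
#'   matrices in 0-based pixel coordinates).
#' @param threshold Reference-channel wall threshold (> 0).
#' @return A `flank_ratio` object: list with `sections` (tibble `section`,
#'   `upper`, `lower`, `difference`), `mean_difference`, `direction`
#'   (sign of the mean difference) and `n_skipped`.
#' @export
flank_ratio <- function(zstack, upper_roi, lower_roi, threshold) {
  stopifnot(inherits(zstack, "image_series"))
  check_number(threshold, "threshold", 0, strict = TRUE)
  upper_roi <- as_roi(upper_roi); lower_roi <- as_roi(lower_roi)
  if (isTRUE(all.equal(upper_roi, lower_roi, check.attributes = FALSE))) {
    abort("`upper_roi` and `lower_roi` must differ",
          class = "areakymo_validation_error")
  }
  h <- dim(zstack$data)[1]; w <- dim(zstack$data)[2]
  um <- polygon_mask(upper_roi, h, w)
  lm_ <- polygon_mask(lower_roi, h, w)
  if (any(um & lm_)) {
    abort("flank ROIs must be disjoint", class = "areakymo_validation_error")
  }
  mask <- wall_mask(zstack, threshold)
  rows <- purrr::map(seq_len(n_frames(zstack)), function(t) {
    wm <- mask$masks[, , t]
    up <- wm & um; lo <- wm & lm_
    if (!any(up) || !any(lo)) return(NULL)
    refm <- get_frame(zstack, t, "ref"); senm <- get_frame(zstack, t, "sense")
    tibble(section = t,
           upper = mean(senm[up]) / mean(refm[up]),
           lower = mean(senm[lo]) / mean(refm[lo]))
  })
  keep <- !vapply(rows, is.null, TRUE)
  sections <- dplyr::bind_rows(rows[keep])
  if (nrow(sections)) {
    sections$difference <- sections$lower - sections$upper
  } else {
    sections <- tibble(section = integer(), upper = double(),
                       lower = double(), difference = double())
  }
  structure(
    list(sections = sections,
         mean_difference = if (nrow(sections)) mean(sections$difference) else NA_real_,
         direction = if (nrow(sections)) sign(mean(sections$difference)) else NA_real_,
         n_skipped = sum(!keep)),
    class = "flank_ratio"
  )
}

#' @export
print.flank_ratio <- function(x, ...) {
  cat(sprintf("<flank_ratio> %d section(s), %d skipped; mean lower - upper difference: %.4g\n",
              nrow(x$sections), x$n_skipped, x$mean_difference))
  invisible(x)
}

#' @method tidy flank_ratio
#' @export
tidy.flank_ratio <- function(x, ...) x$sections

#' @method glance flank_ratio
#' @export
glance.flank_ratio <- function(x, ...) {
  tibble(n_sections = nrow(x$sections), n_skipped = x$n_skipped,
         mean_difference = x$mean_difference, direction = x$direction)
}
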