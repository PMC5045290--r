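#' Time-lapse image series
#'
#' A lightweight container for a time-ordered, multi-channel image stack with
#' spatial and temporal calibration. Pixel data are stored as a 4-dimensional
#' array `[height, width, channel, time]`; two-channel ratiometric stacks
#' conventionally carry the pH-insensitive reference channel as `"ref"` and
#' the pH-sensitive channel as `"sense"`.
#'
#' @param data A numeric array: `H x W` (single frame), `H x W x T`
#'   (single channel) or `H x W x C x T`.
#' @param channels Character vector of channel labels, one per channel.
#'   Defaults to `"signal"` for one channel and `c("ref", "sense")` for two.
#' @param pixel_size_um Pixel size in micrometres.
#' @param time_step_min Time between consecutive frames in minutes.
#' @param t_start_min Time of the first frame in minutes since treatment.
#' @return An object of class `image_series`.
#' @examples
#' s <- image_series(array(runif(8 * 8 * 3), c(8, 8, 3)))
#' n_frames(s)
#' @export
image_series <- function(data, channels = NULL, pixel_size_um = 1,
                         time_step_min = 1, t_start_min = 0) {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L, 1L)
  if (length(dim(data)) == 3) dim(data) <- c(dim(data)[1:2], 1L, dim(data)[3])
  if (length(dim(data)) != 4) {
    abort("`data` must be an H x W, H x W x T or H x W x C x T array",
          class = "areakymo_validation_error")
  }
  nc <- dim(data)[3]
  channels <- channels %||% if (nc == 1) "signal" else
    if (nc == 2) c("ref", "sense") else paste0("ch", seq_len(nc))
  if (length(channels) != nc || anyDuplicated(channels)) {
    abort("`channels` must supply one unique label per channel",
          class = "areakymo_validation_error")
  }
  check_number(pixel_size_um, "pixel_size_um", 0, strict = TRUE)
  check_number(time_step_min, "time_step_min", 0, strict = TRUE)
  check_number(t_start_min, "t_start_min")
  if (any(data < 0, na.rm = TRUE) || any(is.infinite(data))) {
    abort("intensities must be finite and >= 0",
          class = "areakymo_validation_error")
  }
  structure(
    list(data = data, channels = channels, pixel_size_um = pixel_size_um,
         time_step_min = time_step_min, t_start_min = t_start_min),
    class = "image_series"
  )
}

#' @rdname image_series
#' @param x An `image_series`.
#' @export
n_frames <- function(x) dim(x$data)[4]

#' @rdname image_series
#' @export
n_channels <- function(x) dim(x$data)[3]

#' @rdname image_series
#' @export
frame_times <- function(x) {
  x$t_start_min + (seq_len(n_frames(x)) - 1) * x$time_step_min
}

#' Extract one frame of one channel as a matrix
#'
#' @param x An `image_series`.
#' @param frame Frame index (1-based).
#' @param channel Channel label or index.
#' @return An `H x W` numeric matrix.
#' @export
get_frame <- function(x, frame = 1, channel = 1) {
  x$data[, , channel_index(x, channel), frame]
}

channel_index <- function(x, channel) {
  if (is.character(channel)) {
    i <- match(channel, x$channels)
    if (is.na(i)) {
      abort(sprintf("channel `%s` not found (have: %s)", channel,
                    paste(x$channels, collapse = ", ")),
            class = "areakymo_validation_error")
    }
    i
  } else {
    as.integer(channel)
  }
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<image_series> %d x %d px, %d channel(s) [%s], %d frame(s)\n",
    d[1], d[2], d[3], paste(x$channels, collapse = ", "), d[4]))
  cat(sprintf("  pixel size %g um, time step %g min, t0 = %g min\n",
              x$pixel_size_um, x$time_step_min, x$t_start_min))
  invisible(x)
}

#' Sum-project a z-stack
#'
#' Collapses a one-timepoint z-series into a single frame by per-pixel
#' summation across slices, independently per channel (the "SUM projection"
#' used to pool signal across optical sections before ratio analysis).
#'
#' @param zstack An `image_series` whose frame axis holds z-slices.
#' @return An `image_series` with a single frame.
#' @examples
#' z <- image_series(array(1, c(4, 4, 2, 3)))
#' max(get_frame(sum_project(z), 1, "ref"))  # 3
#' @export
sum_project <- function(zstack) {
  stopifnot(inherits(zstack, "image_series"))
  if (n_frames(zstack) < 1) {
    abort("z-stack must contain at least one slice",
          class = "areakymo_validation_error")
  }
  pro <- apply(zstack$data, c(1, 2, 3), sum)
  dim(pro) <- c(dim(pro), 1L)
  out <- zstack
  out$data <- pro
  out
}
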