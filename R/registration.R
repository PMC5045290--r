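#' Estimate translation drift of a time series
#'
#' Integer-pixel, translation-only drift estimation by cross-correlation,
#' the stabilization applied to confocal time series before ratio analysis.
#' Each frame's shift is the integer displacement maximizing the circular
#' cross-correlation (computed via FFT) of the chosen channel with the
#' reference frame; in `sequential` mode frame-to-frame shifts are estimated
#' and accumulated, which is robust when the drift is large relative to the
#' frame. Estimation is exact for integer circular shifts of any
#' non-degenerate frame. The pH-insensitive reference channel is the default,
#' since its signal is stable under the biology.
#'
#' @param series An [image_series()] with at least two frames.
#' @param channel Channel used for estimation.
#' @param mode `"to_first"` (every frame against the reference frame) or
#'   `"sequential"` (consecutive frames, shifts accumulated).
#' @param reference_frame Index of the reference frame (its shift is (0, 0)).
#' @return A `shift_trace` tibble with columns `frame`, `dx_px`, `dy_px`
#'   (displacement of each frame's content relative to the reference;
#'   x rightward, y downward) and attributes `reference_frame`, `mode`,
#'   `channel`. A zero-variance frame yields shift (0, 0) with a warning.
#' @examples
#' out <- generate_ph_series(ph_series_config(noise_sd = 0, onset_min = 5,
#'                                             n_frames = 3))
#' drift <- data.frame(dx_px = c(0, 3, 5), dy_px = c(0, -2, 1))
#' est <- estimate_translation(inject_drift(out$series, drift))
#' est$dx_px  # 0 3 5
#' @export
estimate_translation <- function(series, channel = "ref",
                                 mode = c("to_first", "sequential"),
                                 reference_frame = 1) {
  stopifnot(inherits(series, "image_series"))
  mode <- match.arg(mode)
  nt <- n_frames(series)
  if (nt < 2) {
    abort("at least two frames are required", class = "areakymo_validation_error")
  }
  ci <- channel_index(series, channel)
  get <- function(t) {
    m <- series$data[, , ci, t]
    m[is.na(m)] <- mean(m, na.rm = TRUE)
    m
  }
  if (mode == "to_first") {
    ref <- get(reference_frame)
    sh <- t(vapply(seq_len(nt), function(t) {
      if (t == reference_frame) c(0, 0) else xcorr_shift(ref, get(t))
    }, c(0, 0)))
  } else {
    step <- t(vapply(seq_len(nt), function(t) {
      if (t == 1) c(0, 0) else xcorr_shift(get(t - 1), get(t))
    }, c(0, 0)))
    sh <- apply(step, 2, cumsum)
    sh <- sweep(sh, 2, sh[reference_frame, ])
  }
  out <- tibble(frame = seq_len(nt),
                dx_px = as.integer(sh[, 1]), dy_px = as.integer(sh[, 2]))
  attr(out, "reference_frame") <- reference_frame
  attr(out, "mode") <- mode
  attr(out, "channel") <- channel
  class(out) <- c("shift_trace", class(out))
  out
}

# integer (dx, dy) maximizing circular cross-correlation of `frame` against
# `ref`: frame(x) ~ ref(x - d)
xcorr_shift <- function(ref, frame) {
  if (sd(frame) == 0 || sd(ref) == 0) {
    warn("zero-variance frame; assuming shift (0, 0)")
    return(c(0, 0))
  }
  a <- ref - mean(ref)
  b <- frame - mean(frame)
  cc <- Re(fft(fft(b) * Conj(fft(a)), inverse = TRUE))
  peak <- which.max(cc)
  h <- nrow(ref); w <- ncol(ref)
  dy <- (peak - 1) %% h
  dx <- (peak - 1) %/% h
  if (dy > h / 2) dy <- dy - h
  if (dx > w / 2) dx <- dx - w
  c(dx, dy)
}

#' Apply translation shifts to stabilize a series
#'
#' Translates every frame by the negative of its estimated shift, moving all
#' channels identically. Shifts are integer pixels, so retained pixel values
#' are untouched (no interpolation); vacated margins are filled with `NA`
#' and excluded from downstream wall masks.
#'
#' @param series An [image_series()].
#' @param shifts A [estimate_translation()] result (or data frame with
#'   `dx_px`, `dy_px`), one row per frame.
#' @return The stabilized `image_series`.
#' @export
apply_shifts <- function(series, shifts) {
  stopifnot(inherits(series, "image_series"))
  shifts <- as.data.frame(shifts)
  if (nrow(shifts) != n_frames(series)) {
    abort("`shifts` must have one row per frame",
          class = "areakymo_validation_error")
  }
  out <- series
  for (t in seq_len(n_frames(series))) {
    dx <- shifts$dx_px[t]; dy <- shifts$dy_px[t]
    if (dx == 0 && dy == 0) next
    for (ch in seq_len(n_channels(series))) {
      out$data[, , ch, t] <- translate_matrix(series$data[, , ch, t], dx, dy)
    }
  }
  out
}
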