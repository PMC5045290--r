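# internal validation and geometry helpers

check_number <- function(x, field, min = -Inf, strict = FALSE, integer = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (strict) x > min else x >= min) &&
    (!integer || x == trunc(x))
  if (!ok) {
    abort(sprintf(
      "invalid value for field `%s`: must be a finite %s %s %s",
      field,
      if (integer) "integer" else "number",
      if (strict) ">" else ">=",
      format(min)
    ), class = "areakymo_validation_error")
  }
  invisible(x)
}

check_flag <- function(x, field) {
  if (!is.logical(x) || length(x) != 1 || is.na(x)) {
    abort(sprintf("invalid value for field `%s`: must be TRUE or FALSE", field),
          class = "areakymo_validation_error")
  }
  invisible(x)
}

#' Rasterize a polygon region of interest
#'
#' Marks every pixel whose centre lies inside (or on the boundary of) a
#' polygon given in 0-based pixel coordinates (x rightward, y downward).
#'
#' @param roi A two-column matrix or data frame of polygon vertices with
#'   columns `x` and `y` (0-based pixel coordinates).
#' @param height,width Frame dimensions in pixels.
#' @return A logical `height` x `width` matrix.
#' @export
polygon_mask <- function(roi, height, width) {
  roi <- as_roi(roi)
  px <- rep(seq_len(width) - 1, each = height)
  py <- rep(seq_len(height) - 1, times = width)
  inside <- pracma::inpolygon(px, py, roi[, "x"], roi[, "y"], boundary = TRUE)
  matrix(inside, nrow = height, ncol = width)
}

as_roi <- function(roi) {
  roi <- as.matrix(as.data.frame(roi))
  if (is.null(colnames(roi)) && ncol(roi) == 2) colnames(roi) <- c("x", "y")
  if (!all(c("x", "y") %in% colnames(roi)) || nrow(roi) < 3) {
    abort("a polygon ROI needs columns `x`, `y` and at least 3 vertices",
          class = "areakymo_validation_error")
  }
  storage.mode(roi) <- "double"
  roi[, c("x", "y"), drop = FALSE]
}

# bilinear interpolation of matrix `m` at 0-based positions (x, y);
# positions are clamped to the frame border
bilinear_sample <- function(m, x, y) {
  h <- nrow(m); w <- ncol(m)
  x <- pmin(pmax(x, 0), w - 1)
  y <- pmin(pmax(y, 0), h - 1)
  x0 <- pmin(floor(x), w - 2 + (w == 1)); y0 <- pmin(floor(y), h - 2 + (h == 1))
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1, x0 + 1)
  i01 <- cbind(y0 + 1, pmin(x0 + 2, w))
  i10 <- cbind(pmin(y0 + 2, h), x0 + 1)
  i11 <- cbind(pmin(y0 + 2, h), pmin(x0 + 2, w))
  m[i00] * (1 - fx) * (1 - fy) + m[i01] * fx * (1 - fy) +
    m[i10] * (1 - fx) * fy + m[i11] * fx * fy
}

# circularly roll a matrix: content moves dy rows down, dx columns right
roll_matrix <- function(m, dx, dy) {
  h <- nrow(m); w <- ncol(m)
  ri <- ((seq_len(h) - 1 - dy) %% h) + 1
  ci <- ((seq_len(w) - 1 - dx) %% w) + 1
  m[ri, ci, drop = FALSE]
}

# translate a matrix by (dx, dy) without wrap-around; vacated cells get `fill`
translate_matrix <- function(m, dx, dy, fill = NA_real_) {
  h <- nrow(m); w <- ncol(m)
  if (abs(dx) >= w || abs(dy) >= h) {
    abort("shift is larger than the frame", class = "areakymo_validation_error")
  }
  out <- matrix(fill, h, w)
  src_r <- seq_len(h) + dy; src_c <- seq_len(w) + dx
  keep_r <- src_r >= 1 & src_r <= h
  keep_c <- src_c >= 1 & src_c <= w
  out[keep_r, keep_c] <- m[src_r[keep_r], src_c[keep_c], drop = FALSE]
  out
}
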