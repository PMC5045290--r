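#' Segment a silhouette from a scanner frame
#'
#' Thresholds a frame and returns one connected component, mirroring the
#' manual protocol of thresholding scanner images and clicking each segment:
#' the component is picked by a seed point when given, otherwise the largest
#' component is taken. With `threshold = "auto"` the cutoff is Otsu's
#' criterion on the frame histogram.
#'
#' @param frame A numeric matrix (one frame, one channel).
#' @param threshold A number (pixels strictly above are foreground) or
#'   `"auto"` for Otsu's threshold; `"auto"` requires a non-uniform frame.
#' @param selection_point Optional `c(x, y)` seed in 0-based pixel
#'   coordinates; the component containing it is returned (error if the seed
#'   falls on background).
#' @return A logical matrix with attributes `threshold` and `policy`
#'   (`"seeded"` or `"largest"`). Errors if no foreground component exists.
#' @examples
#' fr <- matrix(0, 20, 20); fr[5:15, 8:12] <- 1
#' sum(segment_mask(fr, threshold = 0.5))
#' @export
segment_mask <- function(frame, threshold = "auto", selection_point = NULL) {
  stopifnot(is.matrix(frame), is.numeric(frame))
  if (identical(threshold, "auto")) {
    rng <- range(frame)
    if (diff(rng) == 0) {
      abort("automatic thresholding needs a non-uniform frame",
            class = "areakymo_validation_error")
    }
    scaled <- (frame - rng[1]) / diff(rng)
    threshold <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1)) *
      diff(rng) + rng[1]
  } else {
    check_number(threshold, "threshold")
  }
  bin <- frame > threshold
  if (!any(bin)) {
    abort("no foreground component above the threshold",
          class = "areakymo_validation_error")
  }
  labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bin * 1)))
  if (!is.null(selection_point)) {
    r <- round(selection_point[2]) + 1; c <- round(selection_point[1]) + 1
    if (r < 1 || r > nrow(frame) || c < 1 || c > ncol(frame) ||
        labels[r, c] == 0) {
      abort("selection point does not fall on a foreground component",
            class = "areakymo_validation_error")
    }
    pick <- labels[r, c]
    policy <- "seeded"
  } else {
    sizes <- tabulate(labels[labels > 0])
    pick <- which.max(sizes)
    policy <- "largest"
  }
  out <- labels == pick
  attr(out, "threshold") <- threshold
  attr(out, "policy") <- policy
  out
}

# 0-based (x, y) corner points of the boundary pixels of a mask; each pixel
# is the unit square [x-0.5, x+0.5] x [y-0.5, y+0.5] around its centre
boundary_corners <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  interior <- pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
    pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  idx <- which(mask & !interior, arr.ind = TRUE)
  x <- idx[, 2] - 1; y <- idx[, 1] - 1
  cbind(x = c(x - 0.5, x - 0.5, x + 0.5, x + 0.5),
        y = c(y - 0.5, y + 0.5, y - 0.5, y + 0.5))
}

#' Feret's diameter (maximum caliper) of a mask
#'
#' The maximum caliper distance of a binary mask, used as segment length.
#' Every pixel is treated as a unit square: the diameter is the maximum
#' pairwise distance between corner points of boundary pixels, computed over
#' the convex hull. A single pixel therefore measures `sqrt(2)`.
#'
#' @param mask A logical matrix (or `segment_mask()` result).
#' @return Length in pixels.
#' @examples
#' m <- matrix(FALSE, 5, 6); m[2:4, 2:5] <- TRUE  # 3 x 4 rectangle
#' feret_diameter(m)  # 5
#' @export
feret_diameter <- function(mask) {
  stopifnot(is.logical(c(mask)), is.matrix(mask))
  if (!any(mask)) {
    abort("mask is empty", class = "areakymo_validation_error")
  }
  pts <- boundary_corners(mask)
  hull <- pts[chull(pts[, 1], pts[, 2]), , drop = FALSE]
  d2 <- outer(hull[, 1], hull[, 1], `-`)^2 + outer(hull[, 2], hull[, 2], `-`)^2
  sqrt(max(d2))
}

#' Growth trace of a segment
#'
#' Per-frame maximum-caliper (Feret) length of a segment, in pixels,
#' millimetres (when calibrated) and as a percentage of the initial length:
#' the first frame is taken as 100 % exactly, making the percentage trace
#' calibration-free.
#'
#' @param masks A list of per-frame logical masks (e.g. from
#'   [segment_mask()]), or a logical `H x W x T` array.
#' @param time_step_min Minutes between frames.
#' @param t_start_min Time of the first frame (minutes since treatment).
#' @param px_per_mm Optional spatial calibration; `length_mm` is `NA` when
#'   missing.
#' @return A tibble of class `growth_trace` with columns `time_min`,
#'   `length_px`, `length_mm`, `length_pct`.
#' @export
growth_trace <- function(masks, time_step_min = 1, t_start_min = 0,
                         px_per_mm = NA_real_) {
  if (is.array(masks) && length(dim(masks)) == 3) {
    masks <- purrr::map(seq_len(dim(masks)[3]), ~ masks[, , .x])
  }
  stopifnot(is.list(masks), length(masks) >= 1)
  check_number(time_step_min, "time_step_min", 0, strict = TRUE)
  lengths <- vapply(masks, feret_diameter, 0)
  out <- tibble(
    time_min = t_start_min + (seq_along(masks) - 1) * time_step_min,
    length_px = lengths,
    length_mm = if (is.na(px_per_mm)) NA_real_ else lengths / px_per_mm,
    length_pct = 100 * lengths / lengths[1]
  )
  out$length_pct[1] <- 100  # exact by convention
  class(out) <- c("growth_trace", class(out))
  out
}

#' Line kymograph along a polyline
#'
#' Samples the intensity profile along a polyline (averaged across a
#' perpendicular width) in every frame and stacks the profiles as columns in
#' time order, the classic kymograph used to visualize tip advance of a
#' growing segment.
#'
#' @param series An [image_series()].
#' @param polyline Two-column `x`/`y` matrix of vertices (0-based pixel
#'   coordinates) with positive total length.
#' @param width_px Averaging width perpendicular to the line (>= 1).
#' @param channel Channel to sample.
#' @return A numeric matrix, positions (rows, ~1 px spacing) by time
#'   (columns), with attribute `positions_px` (arc length of each row).
#' @export
line_kymograph <- function(series, polyline, width_px = 1, channel = 1) {
  stopifnot(inherits(series, "image_series"))
  check_number(width_px, "width_px", 1, integer = TRUE)
  pl <- as.matrix(as.data.frame(polyline))
  if (is.null(colnames(pl)) && ncol(pl) == 2) colnames(pl) <- c("x", "y")
  seg <- diff(pl)
  seg_len <- sqrt(rowSums(seg^2))
  total <- sum(seg_len)
  if (nrow(pl) < 2 || total <= 0) {
    abort("polyline has zero length", class = "areakymo_validation_error")
  }
  s <- seq(0, total, by = 1)
  cum <- c(0, cumsum(seg_len))
  seg_id <- pmin(findInterval(s, cum, rightmost.closed = TRUE), nrow(seg))
  frac <- (s - cum[seg_id]) / seg_len[seg_id]
  px <- pl[seg_id, "x"] + frac * seg[seg_id, 1]
  py <- pl[seg_id, "y"] + frac * seg[seg_id, 2]
  tx <- seg[seg_id, 1] / seg_len[seg_id]
  ty <- seg[seg_id, 2] / seg_len[seg_id]
  offsets <- if (width_px == 1) 0 else seq(-(width_px - 1) / 2, (width_px - 1) / 2)
  ci <- channel_index(series, channel)
  cols <- vapply(seq_len(n_frames(series)), function(t) {
    m <- series$data[, , ci, t]
    prof <- rowMeans(vapply(offsets, function(o) {
      bilinear_sample(m, px - o * ty, py + o * tx)
    }, numeric(length(s))))
    prof
  }, numeric(length(s)))
  out <- matrix(cols, nrow = length(s), ncol = n_frames(series))
  attr(out, "positions_px") <- s
  out
}

# Zhang-Suen binary thinning; returns the 1-px skeleton of a mask
skeletonize_mask <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  img <- matrix(0L, h + 2, w + 2)
  img[2:(h + 1), 2:(w + 1)] <- mask * 1L
  nb <- function(m, dr, dc) {
    m[(2:(h + 1)) + dr, (2:(w + 1)) + dc]
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      p2 <- nb(img, -1, 0); p3 <- nb(img, -1, 1); p4 <- nb(img, 0, 1)
      p5 <- nb(img, 1, 1);  p6 <- nb(img, 1, 0);  p7 <- nb(img, 1, -1)
      p8 <- nb(img, 0, -1); p9 <- nb(img, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      core <- img[2:(h + 1), 2:(w + 1)] == 1 & b >= 2 & b <= 6 & a == 1
      del <- if (pass == 1) {
        core & (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        core & (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(del)) {
        inner <- img[2:(h + 1), 2:(w + 1)]
        inner[del] <- 0L
        img[2:(h + 1), 2:(w + 1)] <- inner
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img[2:(h + 1), 2:(w + 1)] == 1
}

#' Tip angle of a segment mask
#'
#' Orientation of the free (apical) end of a segment, following the
#' gravitropism convention: 0 degrees is horizontal, +90 degrees vertical
#' (pointing up), in `[-180, 180]`. The mask is skeletonized, the free end is
#' the skeleton endpoint farthest from `basal_point` when given (otherwise
#' the uppermost endpoint, ties toward larger x), and the angle is the
#' principal-axis direction of the skeleton points within `tip_window_px`
#' arc length of that end, oriented toward it.
#'
#' @param mask A logical matrix (segment silhouette).
#' @param tip_window_px Arc length of the tip region used, in pixels;
#'   default 20 % of the skeleton length.
#' @param basal_point Optional `c(x, y)` (0-based) marking the basal end.
#' @return Angle in degrees.
#' @examples
#' b <- generate_bending_series(start_angle_deg = 90, rate_deg_per_hr = 0,
#'                              n_frames = 1)
#' tip_angle(get_frame(b$series, 1) > 0.5)  # 90
#' @export
tip_angle <- function(mask, tip_window_px = NULL, basal_point = NULL) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  if (!any(mask)) abort("mask is empty", class = "areakymo_validation_error")
  skel <- skeletonize_mask(mask)
  idx <- which(skel, arr.ind = TRUE)
  if (nrow(idx) < 2) {
    abort("skeleton has fewer than 2 points", class = "areakymo_validation_error")
  }
  # 8-neighbour adjacency among skeleton points
  key <- idx[, 1] + nrow(mask) * idx[, 2]
  lookup <- stats::setNames(seq_len(nrow(idx)), key)
  nbrs <- vector("list", nrow(idx))
  off <- expand.grid(dr = -1:1, dc = -1:1)
  off <- off[!(off$dr == 0 & off$dc == 0), ]
  for (k in seq_len(nrow(off))) {
    nk <- (idx[, 1] + off$dr[k]) + nrow(mask) * (idx[, 2] + off$dc[k])
    hit <- lookup[as.character(nk)]
    ok <- !is.na(hit)
    for (i in which(ok)) nbrs[[i]] <- c(nbrs[[i]], unname(hit[i]))
  }
  deg <- lengths(nbrs)
  ends <- which(deg == 1)
  if (length(ends) == 0) {
    abort("no free end: the skeleton is a closed curve",
          class = "areakymo_validation_error")
  }
  x <- idx[, 2] - 1; y <- idx[, 1] - 1
  if (!is.null(basal_point)) {
    d2 <- (x[ends] - basal_point[1])^2 + (y[ends] - basal_point[2])^2
    free <- ends[which.max(d2)]
  } else {
    top <- ends[y[ends] == min(y[ends])]
    free <- top[which.max(x[top])]
  }
  # geodesic arc length from the free end (Dijkstra; steps cost 1 or sqrt(2))
  dist <- rep(Inf, nrow(idx)); dist[free] <- 0
  done <- rep(FALSE, nrow(idx))
  for (iter in seq_len(nrow(idx))) {
    u <- which(!done & is.finite(dist))
    if (!length(u)) break
    u <- u[which.min(dist[u])]
    done[u] <- TRUE
    for (v in nbrs[[u]]) {
      step <- if (abs(idx[u, 1] - idx[v, 1]) + abs(idx[u, 2] - idx[v, 2]) == 2)
        sqrt(2) else 1
      if (dist[u] + step < dist[v]) dist[v] <- dist[u] + step
    }
  }
  total_len <- max(dist[is.finite(dist)])
  window <- tip_window_px %||% (0.2 * total_len)
  sel <- is.finite(dist) & dist <= window
  if (sum(sel) < 2) {
    abort("fewer than 2 skeleton points within the tip window",
          class = "areakymo_validation_error")
  }
  pts <- cbind(x[sel], y[sel])
  ctr <- colMeans(pts)
  v <- eigen(cov(pts))$vectors[, 1]
  to_end <- c(x[free], y[free]) - ctr
  if (sum(v * to_end) < 0) v <- -v
  ang <- atan2(-v[2], v[1]) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Bending-angle trace of a gravistimulated series
#'
#' Tip angle of every frame of a single-channel silhouette series.
#'
#' @param series An [image_series()] of rod masks or silhouettes.
#' @param threshold Foreground threshold (default 0.5 for binary masks).
#' @param tip_window_px,basal_point Passed to [tip_angle()].
#' @return A tibble of class `bend_angle_trace` with `time_min`, `angle_deg`.
#' @export
bend_angle_trace <- function(series, threshold = 0.5, tip_window_px = NULL,
                             basal_point = NULL) {
  stopifnot(inherits(series, "image_series"))
  angles <- vapply(seq_len(n_frames(series)), function(t) {
    tip_angle(get_frame(series, t, 1) > threshold, tip_window_px, basal_point)
  }, 0)
  out <- tibble(time_min = frame_times(series), angle_deg = angles)
  class(out) <- c("bend_angle_trace", class(out))
  out
}
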