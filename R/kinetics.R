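#' Mean-intensity trace of a region of interest
#'
#' Per-frame mean intensity within a polygon ROI, the standard quantification
#' of luciferase reporter stacks.
#'
#' @param series An [image_series()].
#' @param roi A polygon (two-column `x`/`y` matrix, 0-based pixel
#'   coordinates).
#' @param channel Channel to measure.
#' @return A tibble with columns `time_min`, `value` and attribute
#'   `value_kind`.
#' @export
extract_roi_trace <- function(series, roi, channel = 1) {
  stopifnot(inherits(series, "image_series"))
  h <- dim(series$data)[1]; w <- dim(series$data)[2]
  m <- polygon_mask(roi, h, w)
  if (!any(m)) {
    abort("ROI does not intersect the frame", class = "areakymo_validation_error")
  }
  ci <- channel_index(series, channel)
  vals <- vapply(seq_len(n_frames(series)), function(t) {
    mean(series$data[, , ci, t][m])
  }, 0)
  out <- tibble(time_min = frame_times(series), value = vals)
  attr(out, "value_kind") <- if (is.character(channel)) channel else
    series$channels[ci]
  out
}

as_trace <- function(trace) {
  trace <- as.data.frame(trace)
  if (!all(c("time_min", "value") %in% names(trace))) {
    abort("a trace needs columns `time_min` and `value`",
          class = "areakymo_validation_error")
  }
  if (any(!is.finite(trace$time_min)) || any(!is.finite(trace$value))) {
    abort("trace values must be finite with no missing points",
          class = "areakymo_validation_error")
  }
  if (any(diff(trace$time_min) <= 0)) {
    abort("trace times must be strictly increasing",
          class = "areakymo_validation_error")
  }
  trace
}

#' Detect the onset (lag-phase end) of a response
#'
#' Operationalizes lag-phase measurement as a continuous two-segment
#' piecewise-linear least-squares fit: the breakpoint is chosen by exhaustive
#' search over the observed sample times (the sampling resolution of the
#' trace), minimizing the total sum of squared errors subject to a direction
#' constraint — for `direction = "increase"` the post-onset slope must exceed
#' the pre-onset slope, and conversely for `"decrease"`. The pre-arm slope is
#' otherwise unconstrained (a flat lag phase is expected but not imposed).
#' SSE ties are broken toward the earliest breakpoint (a conservative lag).
#' If no breakpoint satisfies the direction constraint, a no-onset result is
#' returned with a diagnostic rather than an error.
#'
#' An optional bootstrap confidence half-width resamples the fit residuals
#' (`n_boot` replicates, seeded) and reports half the central 95 % interval
#' of the re-estimated breakpoints.
#'
#' @param trace A data frame with strictly increasing `time_min` and finite
#'   `value` (at least 5 points).
#' @param direction `"increase"` (growth, luminescence) or `"decrease"`
#'   (acidification of a sense/reference ratio).
#' @param min_points_per_arm Minimum samples on each side of a candidate
#'   breakpoint (>= 2).
#' @param bootstrap_ci Compute a bootstrap half-width?
#' @param n_boot Bootstrap replicates.
#' @param seed Seed for the bootstrap.
#' @return An `onset_estimate`: `t_break_min`, `slope_pre`, `slope_post`
#'   (units/min), `sse`, `direction`, `onset_detected`, `diagnostic`,
#'   `ci_halfwidth_min`, the fitted values and the candidate grid. Use
#'   [tidy()] / [glance()] for tabular access.
#' @examples
#' t <- seq(0, 100, 5)
#' y <- ifelse(t <= 20, 100, 100 + 0.5 * (t - 20))
#' glance(detect_onset(data.frame(time_min = t, value = y), "increase"))
#' @export
detect_onset <- function(trace, direction = c("increase", "decrease"),
                         min_points_per_arm = 2, bootstrap_ci = FALSE,
                         n_boot = 200, seed = 1) {
  direction <- match.arg(direction)
  check_number(min_points_per_arm, "min_points_per_arm", 2, integer = TRUE)
  trace <- as_trace(trace)
  t <- trace$time_min; y <- trace$value
  n <- length(t)
  if (n < 5) {
    abort("onset fitting needs at least 5 points",
          class = "areakymo_validation_error")
  }
  fit <- onset_grid_fit(t, y, direction, min_points_per_arm)
  est <- structure(
    c(fit[c("t_break_min", "slope_pre", "slope_post", "sse", "fitted",
            "candidates")],
      list(direction = direction, onset_detected = fit$onset_detected,
           diagnostic = fit$diagnostic, n = n,
           ci_halfwidth_min = NA_real_,
           trace = tibble(time_min = t, value = y))),
    class = "onset_estimate"
  )
  if (bootstrap_ci && fit$onset_detected) {
    res <- y - fit$fitted
    boots <- withr::with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        yb <- fit$fitted + sample(res, n, replace = TRUE)
        fb <- onset_grid_fit(t, yb, direction, min_points_per_arm)
        if (fb$onset_detected) fb$t_break_min else NA_real_
      }, 0)
    })
    qs <- quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    est$ci_halfwidth_min <- (qs[2] - qs[1]) / 2
  }
  est
}

# exhaustive search over candidate breakpoints at the sample times; the
# two-segment continuous model is fit with the hinge basis
# y ~ 1 + t + max(t - tc, 0)
onset_grid_fit <- function(t, y, direction, m) {
  cands <- t[vapply(t, function(tc) sum(t <= tc) >= m && sum(t > tc) >= m,
                    TRUE)]
  if (!length(cands)) {
    return(list(t_break_min = NA_real_, slope_pre = NA_real_,
                slope_post = NA_real_, sse = NA_real_, fitted = NULL,
                candidates = tibble(t_candidate = double(), sse = double(),
                                    feasible = logical()),
                onset_detected = FALSE,
                diagnostic = "too few points for any candidate breakpoint"))
  }
  # slope-difference tolerance: a relative epsilon on the trace's own scale,
  # so an exactly flat trace is never called an onset
  tol <- (1e-8 * diff(range(y)) + 1e-12 * max(abs(y), 1)) / diff(range(t))
  fits <- purrr::map(cands, function(tc) {
    X <- cbind(1, t, pmax(t - tc, 0))
    f <- lm.fit(X, y)
    b <- f$coefficients
    b[is.na(b)] <- 0
    list(tc = tc, sse = sum(f$residuals^2), dslope = b[3],
         slope_pre = b[2], slope_post = b[2] + b[3],
         fitted = as.numeric(X %*% b))
  })
  sses <- vapply(fits, `[[`, 0, "sse")
  dsl <- vapply(fits, `[[`, 0, "dslope")
  feasible <- if (direction == "increase") dsl > tol else dsl < -tol
  candidates <- tibble(t_candidate = cands, sse = sses, feasible = feasible)
  if (!any(feasible)) {
    return(list(t_break_min = NA_real_, slope_pre = NA_real_,
                slope_post = NA_real_, sse = NA_real_, fitted = NULL,
                candidates = candidates, onset_detected = FALSE,
                diagnostic = sprintf(
                  "no breakpoint with a %s in slope: trace is flat or trends the other way",
                  if (direction == "increase") "rise" else "drop")))
  }
  best_sse <- min(sses[feasible])
  # earliest candidate within numerical tie tolerance of the optimum
  tie_tol <- best_sse * 1e-9 + 1e-12
  pick <- which(feasible & sses <= best_sse + tie_tol)[1]
  f <- fits[[pick]]
  list(t_break_min = f$tc, slope_pre = unname(f$slope_pre),
       slope_post = unname(f$slope_post), sse = f$sse, fitted = f$fitted,
       candidates = candidates, onset_detected = TRUE, diagnostic = "ok")
}

#' @export
print.onset_estimate <- function(x, ...) {
  if (x$onset_detected) {
    cat(sprintf(
      "<onset_estimate> t_break = %.4g min (%s); slopes %.4g -> %.4g /min; SSE %.4g\n",
      x$t_break_min, x$direction, x$slope_pre, x$slope_post, x$sse))
    if (!is.na(x$ci_halfwidth_min)) {
      cat(sprintf("  bootstrap 95%% half-width: %.3g min\n", x$ci_halfwidth_min))
    }
  } else {
    cat(sprintf("<onset_estimate> no onset detected (%s)\n", x$diagnostic))
  }
  invisible(x)
}

#' @rdname detect_onset
#' @param x An `onset_estimate`.
#' @param ... Unused.
#' @method tidy onset_estimate
#' @export
tidy.onset_estimate <- function(x, ...) {
  tibble(term = c("t_break_min", "slope_pre", "slope_post"),
         estimate = c(x$t_break_min, x$slope_pre, x$slope_post))
}

#' @rdname detect_onset
#' @method glance onset_estimate
#' @export
glance.onset_estimate <- function(x, ...) {
  tibble(t_break_min = x$t_break_min, slope_pre = x$slope_pre,
         slope_post = x$slope_post, sse = x$sse,
         onset_detected = x$onset_detected, direction = x$direction,
         n = x$n, ci_halfwidth_min = x$ci_halfwidth_min)
}

#' Auxin transit time across a segment
#'
#' Time for auxin moving at a given transport velocity to reach the midpoint
#' of an excised segment. With `bilateral = TRUE` auxin enters from both cut
#' ends, so the relevant path is half the segment length; otherwise the full
#' length is used.
#'
#' @param segment_length_mm Segment length in millimetres (> 0).
#' @param velocity_mm_per_hr Transport velocity in mm/hr (> 0).
#' @param bilateral Entry from both cut ends?
#' @return Transit time in minutes.
#' @examples
#' transit_time(1.2, 8)  # 4.5 min to the midpoint of a 1.2 mm segment
#' @export
transit_time <- function(segment_length_mm, velocity_mm_per_hr,
                         bilateral = TRUE) {
  check_number(segment_length_mm, "segment_length_mm", 0, strict = TRUE)
  check_number(velocity_mm_per_hr, "velocity_mm_per_hr", 0, strict = TRUE)
  check_flag(bilateral, "bilateral")
  path_mm <- if (bilateral) segment_length_mm / 2 else segment_length_mm
  path_mm / velocity_mm_per_hr * 60
}
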