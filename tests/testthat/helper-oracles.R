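# Independent oracles used by the unit and acceptance tests. These must stay
# independent of the implementation paths they check.

# Brute-force maximum caliper: maximum pairwise distance over the corner
# points of every mask pixel (O(n^2), no convex hull, no boundary pruning).
brute_force_feret <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  x <- idx[, 2] - 1; y <- idx[, 1] - 1
  xs <- c(x - 0.5, x - 0.5, x + 0.5, x + 0.5)
  ys <- c(y - 0.5, y + 0.5, y - 0.5, y + 0.5)
  best <- 0
  for (i in seq_along(xs)) {
    d2 <- (xs - xs[i])^2 + (ys - ys[i])^2
    best <- max(best, max(d2))
  }
  sqrt(best)
}

# Exhaustive-grid changepoint oracle: for every candidate breakpoint at a
# sample time, solve the continuous two-segment least-squares problem from
# the normal equations of the (1, min(t - tc, 0), max(t - tc, 0)) basis and
# keep the earliest feasible SSE minimum. Independent parametrization and
# solver from the package's hinge-basis lm.fit route.
oracle_onset <- function(t, y, direction, m = 2) {
  cands <- t[vapply(t, function(tc) sum(t <= tc) >= m && sum(t > tc) >= m,
                    TRUE)]
  tol <- (1e-8 * diff(range(y)) + 1e-12 * max(abs(y), 1)) / diff(range(t))
  rows <- lapply(cands, function(tc) {
    X <- cbind(1, pmin(t - tc, 0), pmax(t - tc, 0))
    b <- tryCatch(solve(crossprod(X), crossprod(X, y)),
                  error = function(e) NULL)
    if (is.null(b)) return(NULL)
    r <- y - X %*% b
    list(tc = tc, sse = sum(r^2), s_pre = b[2], s_post = b[3])
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  d <- vapply(rows, function(r) r$s_post - r$s_pre, 0)
  feasible <- if (direction == "increase") d > tol else d < -tol
  if (!any(feasible)) return(list(t_break = NA_real_, sse = NA_real_))
  sses <- vapply(rows, `[[`, 0, "sse")
  best <- min(sses[feasible])
  pick <- which(feasible & sses <= best + best * 1e-9 + 1e-12)[1]
  list(t_break = rows[[pick]]$tc, sse = rows[[pick]]$sse)
}

# Seeded random connected blob grown from a centre pixel.
random_blob <- function(size = 30, steps = 120) {
  m <- matrix(FALSE, size, size)
  m[ceiling(size / 2), ceiling(size / 2)] <- TRUE
  for (i in seq_len(steps)) {
    idx <- which(m, arr.ind = TRUE)
    p <- idx[sample(nrow(idx), 1), ]
    q <- pmin(pmax(p + sample(c(-1L, 0L, 1L), 2, replace = TRUE), 1L),
              as.integer(size))
    m[q[1], q[2]] <- TRUE
  }
  m
}

# Uniform single-channel stack whose per-frame intensity follows `values`.
uniform_stack <- function(values, height = 16, width = 16,
                          time_step_min = 5) {
  image_series(array(rep(values, each = height * width),
                     c(height, width, 1, length(values))),
               time_step_min = time_step_min)
}

rect_roi <- function(x0, y0, x1, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}
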