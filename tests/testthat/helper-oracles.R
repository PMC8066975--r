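# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and grDevices::chull) so that agreement is a
# genuine cross-check.

# Gift-wrapping (Jarvis march) convex hull + shoelace area.
jarvis_hull_area <- function(points) {
  p <- unique(as.matrix(points))
  n <- nrow(p)
  if (n < 3L) return(0)
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  start <- which.min(p[, 1] + 1e-9 * p[, 2])
  hull <- integer()
  cur <- start
  repeat {
    hull <- c(hull, cur)
    nxt <- if (cur == 1L) 2L else 1L
    for (j in seq_len(n)) {
      if (j == cur) next
      cr <- cross(p[cur, ], p[nxt, ], p[j, ])
      if (cr < 0 ||
            (cr == 0 && sum((p[j, ] - p[cur, ])^2) > sum((p[nxt, ] - p[cur, ])^2))) {
        nxt <- j
      }
    }
    cur <- nxt
    if (cur == start) break
    if (length(hull) > n) break # degenerate safety
  }
  if (length(hull) < 3L) return(0)
  v <- p[hull, , drop = FALSE]
  x <- v[, 1]; y <- v[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Brute force: hull area equals the maximum, over all >= 3-point subsets, of
# the shoelace area of the subset ordered by angle about its centroid (every
# such polygon lies inside the hull; the hull's own vertex set attains it).
subset_max_hull_area <- function(points) {
  p <- as.matrix(points)
  n <- nrow(p)
  best <- 0
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) < 3L) next
    q <- p[idx, , drop = FALSE]
    ctr <- colMeans(q)
    q <- q[order(atan2(q[, 2] - ctr[2], q[, 1] - ctr[1])), , drop = FALSE]
    x <- q[, 1]; y <- q[, 2]
    a <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
    if (a > best) best <- a
  }
  best
}

# ICC(2,1) via stats::aov mean squares (independent of the package's direct
# sum-of-squares route).
icc_oracle_aov <- function(m) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(
    y = as.vector(m),
    row = factor(rep(seq_len(n), k)),
    col = factor(rep(seq_len(k), each = n))
  )
  ms <- summary(stats::aov(y ~ row + col, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Dense-sampling point-to-polyline distance.
dense_nearest <- function(point, poly, n_samples = 1e4) {
  p <- as.matrix(poly)
  segs <- nrow(p) - 1L
  L <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  per <- pmax(2L, ceiling(n_samples * L / sum(L)))
  best <- Inf
  for (s in seq_len(segs)) {
    tt <- seq(0, 1, length.out = per[s])
    xs <- p[s, 1] + tt * (p[s + 1, 1] - p[s, 1])
    ys <- p[s, 2] + tt * (p[s + 1, 2] - p[s, 2])
    best <- min(best, sqrt(min((point[1] - xs)^2 + (point[2] - ys)^2)))
  }
  best
}

# Pooled-variance two-sample t statistic, written from the closed form.
pooled_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Pearson r from the covariance formula directly.
pearson_oracle <- function(x, y) {
  mean((x - mean(x)) * (y - mean(y))) /
    sqrt(mean((x - mean(x))^2) * mean((y - mean(y))^2))
}
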