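#' Coerce a point matrix to a polyline
#'
#' A polyline is an ordered set of points in cm, stored as a two-column
#' numeric matrix with consecutive duplicate points collapsed.
#'
#' @param points Two-column numeric matrix (or coercible) of x, y in cm.
#' @return A two-column matrix of class `polyline`.
#' @export
as_polyline <- function(points) {
  p <- as.matrix(points)
  if (ncol(p) != 2L) stop("polyline points must have two columns", call. = FALSE)
  storage.mode(p) <- "double"
  if (any(!is.finite(p))) stop("polyline coordinates must be finite", call. = FALSE)
  if (nrow(p) > 1L) {
    keep <- c(TRUE, rowSums(abs(diff(p))) > 0)
    p <- p[keep, , drop = FALSE]
  }
  dimnames(p) <- NULL
  class(p) <- c("polyline", class(p))
  p
}

seg_lengths <- function(p) {
  if (nrow(p) < 2L) return(numeric())
  sqrt(rowSums(diff(unclass(p))^2))
}

#' Total arc length of a polyline
#' @param poly A polyline (see [as_polyline()]).
#' @return Length in cm.
#' @export
arc_length <- function(poly) sum(seg_lengths(as_polyline(poly)))

#' Convex hull area of a point set
#'
#' Area in cm^2 of the convex hull of the given contact points. Fewer than
#' three non-collinear points yield area 0 (closed-hand frames can be nearly
#' collinear; this is not an error).
#'
#' @param points Two-column matrix of points in cm (>= 1 point).
#' @return Hull area in cm^2.
#' @export
convex_hull_area <- function(points) {
  p <- as.matrix(points)
  if (nrow(p) == 0L) stop("convex_hull_area: empty point set", call. = FALSE)
  if (any(!is.finite(p))) stop("convex_hull_area: non-finite coordinates", call. = FALSE)
  if (nrow(p) < 3L) return(0)
  h <- grDevices::chull(p[, 1], p[, 2])
  if (length(h) < 3L) return(0)
  shoelace(p[h, , drop = FALSE])
}

shoelace <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Resample a polyline to equally spaced points by arc length
#'
#' @param poly A polyline with total length > 0.
#' @param n Number of output points (>= 2). The first and last output points
#'   coincide with the polyline endpoints; consecutive spacing along the
#'   polyline is constant.
#' @return An `n` x 2 matrix of points on the polyline.
#' @export
resample_polyline <- function(poly, n) {
  p <- as_polyline(poly)
  if (n < 2L) stop("resample_polyline: n must be >= 2", call. = FALSE)
  L <- seg_lengths(p)
  total <- sum(L)
  if (nrow(p) < 2L || total <= 0) {
    stop("resample_polyline: zero-length polyline", call. = FALSE)
  }
  s <- c(0, cumsum(L))
  target <- seq(0, total, length.out = n)
  seg <- findInterval(target, s, rightmost.closed = TRUE)
  seg[seg >= nrow(p)] <- nrow(p) - 1L
  frac <- (target - s[seg]) / L[seg]
  out <- unclass(p)[seg, , drop = FALSE] * (1 - frac) +
    unclass(p)[seg + 1L, , drop = FALSE] * frac
  out[1, ] <- unclass(p)[1, ]
  out[n, ] <- unclass(p)[nrow(p), ]
  out
}

#' Minimum distance from points to a polyline
#'
#' Euclidean distance to the nearest point of any segment of the polyline
#' (not just its vertices). Vectorised over query points.
#'
#' @param points Two-column matrix (or length-2 vector) of query points in cm.
#' @param poly A polyline.
#' @return Numeric vector of distances in cm, one per query point.
#' @export
nearest_distance <- function(points, poly) {
  q <- if (is.null(dim(points))) matrix(points, ncol = 2) else as.matrix(points)
  p <- as_polyline(poly)
  if (nrow(p) == 1L) {
    return(sqrt((q[, 1] - p[1, 1])^2 + (q[, 2] - p[1, 2])^2))
  }
  a <- unclass(p)[-nrow(p), , drop = FALSE]
  b <- unclass(p)[-1, , drop = FALSE]
  d <- b - a
  len2 <- rowSums(d^2)
  len2[len2 == 0] <- 1 # degenerate guard; duplicates already collapsed
  # t = clamp(((q - a) . d) / |d|^2); distance to a + t d, minimised over segments
  out <- numeric(nrow(q))
  for (i in seq_len(nrow(q))) {
    tt <- ((q[i, 1] - a[, 1]) * d[, 1] + (q[i, 2] - a[, 2]) * d[, 2]) / len2
    tt <- pmin(pmax(tt, 0), 1)
    px <- a[, 1] + tt * d[, 1]
    py <- a[, 2] + tt * d[, 2]
    out[i] <- sqrt(min((q[i, 1] - px)^2 + (q[i, 2] - py)^2))
  }
  out
}
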