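#' Point-in-polygon test (even-odd rule)
#'
#' Vectorised even-odd ray-casting over a set of query points. Points lying
#' on the boundary (within a relative tolerance of an edge) count as inside
#' when `include_boundary = TRUE`, the package-wide tie-break for gating.
#'
#' @param px,py query point coordinates.
#' @param vx,vy polygon vertex coordinates (closed ring; a repeated final
#'   vertex is tolerated).
#' @param include_boundary logical; count boundary points as inside.
#' @return Logical vector, one entry per query point.
#' @export
point_in_polygon <- function(px, py, vx, vy, include_boundary = TRUE) {
  stopifnot(length(px) == length(py), length(vx) == length(vy), length(vx) >= 3)
  nv <- length(vx)
  if (vx[1] == vx[nv] && vy[1] == vy[nv]) {
    vx <- vx[-nv]; vy <- vy[-nv]; nv <- nv - 1L
  }
  n <- length(px)
  inside <- logical(n)
  onb <- logical(n)
  # per-axis scales make the boundary tolerance meaningful when the two
  # axes live on very different numeric ranges
  sx <- max(abs(vx), 1); sy <- max(abs(vy), 1)
  eps2 <- 1e-20
  j <- nv
  for (i in seq_len(nv)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    crosses <- (y2 > py) != (y1 > py)
    if (any(crosses)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, crosses & (px < xint))
    }
    if (include_boundary) {
      ax <- (px - x1) / sx; ay <- (py - y1) / sy
      dx <- (x2 - x1) / sx; dy <- (y2 - y1) / sy
      L2 <- dx * dx + dy * dy
      if (L2 == 0) {
        onb <- onb | (ax * ax + ay * ay <= eps2)
      } else {
        t <- pmin(1, pmax(0, (ax * dx + ay * dy) / L2))
        qx <- ax - t * dx; qy <- ay - t * dy
        onb <- onb | (qx * qx + qy * qy <= eps2)
      }
    }
    j <- i
  }
  if (include_boundary) inside | onb else inside
}

# Shoelace area (absolute) of a ring given as an n x 2 matrix.
polygon_area <- function(v) {
  v <- ring_open(v)
  n <- nrow(v)
  if (n < 3) return(0)
  x <- v[, 1]; y <- v[, 2]
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Drop a duplicated closing vertex; input and output are n x 2 matrices.
ring_open <- function(v) {
  n <- nrow(v)
  if (n > 1 && v[1, 1] == v[n, 1] && v[1, 2] == v[n, 2]) v[-n, , drop = FALSE] else v
}

# Append the first vertex to close the ring.
ring_close <- function(v) {
  v <- ring_open(v)
  rbind(v, v[1, , drop = FALSE])
}

ring_centroid <- function(v) colMeans(ring_open(v))

# Resample an open polyline (n x 2) to exactly m points at equal arc length,
# keeping both endpoints exactly.
resample_polyline <- function(v, m) {
  stopifnot(nrow(v) >= 2, m >= 2)
  seg <- sqrt(diff(v[, 1])^2 + diff(v[, 2])^2)
  s <- c(0, cumsum(seg))
  if (s[length(s)] == 0) {
    return(matrix(rep(v[1, ], each = m), ncol = 2))
  }
  target <- seq(0, s[length(s)], length.out = m)
  cbind(stats::approx(s, v[, 1], xout = target, ties = "ordered")$y,
        stats::approx(s, v[, 2], xout = target, ties = "ordered")$y)
}

#' Discrete symmetric Hausdorff distance between two polylines
#'
#' Each polyline is resampled to `m` equally spaced points along its arc
#' length; the distance is the larger of the two directed maximum
#' nearest-neighbour distances. Coordinates may be pre-scaled by the caller
#' (recommended when the axes carry different units). Used by the
#' gate-diagnostic sweeps.
#'
#' @param a,b polylines as n x 2 matrices.
#' @param m resampling density.
#' @return Non-negative scalar distance.
#' @export
polyline_hausdorff <- function(a, b, m = 200) {
  pa <- resample_polyline(a, m)
  pb <- resample_polyline(b, m)
  d2 <- outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2
  max(sqrt(max(apply(d2, 1, min))), sqrt(max(apply(d2, 2, min))))
}
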