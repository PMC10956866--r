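#' Estimate the 2D event density on the gating plane
#'
#' Bins the events of a sample on a regular grid over the
#' (fluorescence, back-scatter) plane — the data range of each axis padded
#' by 5% on each side — smooths the histogram with a separable Gaussian
#' kernel, and normalises to unit mass. The result is the density field the
#' contour and gate machinery operates on.
#'
#' Below 100 events gating is refused as unreliable; an axis with zero
#' spread is rejected because no 2D density exists.
#'
#' @param table an [event_table()] with at least 100 events.
#' @param axis an [axis_mapping()].
#' @param grid_size number of bins per axis (default 256).
#' @param smoothing_bandwidth Gaussian kernel standard deviation in bins
#'   (default 2); 0 disables smoothing.
#' @return An object of class `density_grid` with fields `x_edges`,
#'   `y_edges`, `x_mids`, `y_mids`, `mass` (a `grid_size` x `grid_size`
#'   matrix summing to 1), `axis`, `transform_tags` and `n_events`.
#' @export
estimate_density <- function(table, axis, grid_size = 256, smoothing_bandwidth = 2) {
  xy <- axis_values(table, axis)
  n <- nrow(xy)
  if (n < 100) {
    sg_stop("sortgate_error_insufficient_events",
            sprintf("sample '%s' has %d events; at least 100 are required for density estimation",
                    table$sample_id, n))
  }
  if (!is.numeric(grid_size) || grid_size < 8) {
    sg_stop("sortgate_error_invalid_config", "grid_size must be at least 8")
  }
  if (!is.numeric(smoothing_bandwidth) || smoothing_bandwidth < 0) {
    sg_stop("sortgate_error_invalid_config", "smoothing_bandwidth must be >= 0")
  }
  grid_size <- as.integer(grid_size)

  edges <- lapply(1:2, function(k) {
    r <- range(xy[, k])
    if (diff(r) == 0) {
      sg_stop("sortgate_error_degenerate_data",
              sprintf("axis '%s' has zero variance; density is degenerate",
                      c(axis$fluorescence, axis$backscatter)[k]))
    }
    pad <- 0.05 * diff(r)
    seq(r[1] - pad, r[2] + pad, length.out = grid_size + 1L)
  })
  x_edges <- edges[[1]]; y_edges <- edges[[2]]

  ix <- pmin.int(pmax.int(findInterval(xy[, 1], x_edges, all.inside = TRUE), 1L), grid_size)
  iy <- pmin.int(pmax.int(findInterval(xy[, 2], y_edges, all.inside = TRUE), 1L), grid_size)
  counts <- matrix(tabulate((iy - 1L) * grid_size + ix, nbins = grid_size * grid_size),
                   nrow = grid_size)

  raw_mass <- counts / sum(counts)
  mass <- counts
  if (smoothing_bandwidth > 0) {
    half <- ceiling(4 * smoothing_bandwidth)
    offs <- (-half):half
    k <- dnorm(offs, sd = smoothing_bandwidth)
    k <- k / sum(k)
    # banded convolution matrix; edge loss is repaired by the final
    # renormalisation
    K <- matrix(0, grid_size, grid_size)
    idx <- abs(row(K) - col(K)) <= half
    K[idx] <- k[abs(row(K) - col(K))[idx] + 1L]
    mass <- K %*% mass %*% t(K)
  }
  mass <- mass / sum(mass)

  structure(
    list(x_edges = x_edges, y_edges = y_edges,
         x_mids = (head(x_edges, -1) + tail(x_edges, -1)) / 2,
         y_mids = (head(y_edges, -1) + tail(y_edges, -1)) / 2,
         mass = mass, raw_mass = raw_mass,
         axis = axis, transform_tags = axis_tags(table, axis),
         n_events = n, sample_id = table$sample_id),
    class = "density_grid")
}

# HDR threshold: the density value t such that the super-level set
# {smoothed density >= t} holds alpha of the EVENT mass. Cells are ranked
# by smoothed density (which fixes the region's shape) but the level is
# calibrated against the raw histogram mass, which removes the outward
# bias kernel smoothing would otherwise give the enclosed event fraction.
hdr_threshold <- function(grid, alpha) {
  sm <- as.vector(grid$mass)
  ord <- order(sm, decreasing = TRUE)
  cum <- cumsum(as.vector(grid$raw_mass)[ord])
  k <- which(cum >= alpha - 1e-12)[1]
  if (is.na(k)) k <- length(ord)
  sm[ord[k]]
}

#' Extract closed contour polygons of the highest-density region
#'
#' Finds the density threshold whose super-level set holds `alpha` of the
#' total event mass (the highest-density region, the convention of
#' cytometry probability-contour plots), then traces the iso-contours at
#' that threshold with marching squares. Contours that run into the grid
#' boundary are closed along it. Polygons are returned sorted by enclosed
#' mass, largest first.
#'
#' @param grid a [estimate_density()] result.
#' @param alpha mass fraction in (0, 1).
#' @return List of `contour_polygon` objects, each with fields `vertices`
#'   (closed ring, n x 2), `level_mass` (= `alpha`), `threshold` and
#'   `enclosed_mass` (grid mass whose cell centres fall inside the ring).
#' @export
contour_at_mass <- function(grid, alpha) {
  stopifnot(inherits(grid, "density_grid"))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    sg_stop("sortgate_error_invalid_config", "alpha must lie strictly between 0 and 1")
  }
  t0 <- hdr_threshold(grid, alpha)
  # trace marginally below the threshold so cells at exactly t0 fall inside
  lev <- t0 * (1 - 1e-9)
  cl <- contourLines(grid$x_mids, grid$y_mids, grid$mass, levels = lev)
  polys <- list()
  for (line in cl) {
    v <- cbind(line$x, line$y)
    if (nrow(v) < 3) next
    rings <- close_contour_ring(v, grid, t0)
    for (ring in rings) {
      if (nrow(ring_open(ring)) < 3) next
      polys[[length(polys) + 1L]] <- structure(
        list(vertices = ring_close(ring),
             level_mass = alpha,
             threshold = t0,
             enclosed_mass = enclosed_grid_mass(ring, grid),
             sample_id = grid$sample_id),
        class = "contour_polygon")
    }
  }
  if (!length(polys)) {
    sg_stop("sortgate_error_no_contour",
            sprintf("no closed contour found at mass level %.3f", alpha))
  }
  polys[order(vapply(polys, `[[`, 0, "enclosed_mass"), decreasing = TRUE)]
}

# Event mass whose cell centres fall inside the ring; restricted to the
# ring's bounding box for speed.
enclosed_grid_mass <- function(ring, grid) {
  v <- ring_open(ring)
  xi <- which(grid$x_mids >= min(v[, 1]) & grid$x_mids <= max(v[, 1]))
  yi <- which(grid$y_mids >= min(v[, 2]) & grid$y_mids <= max(v[, 2]))
  if (!length(xi) || !length(yi)) return(0)
  px <- rep(grid$x_mids[xi], times = length(yi))
  py <- rep(grid$y_mids[yi], each = length(xi))
  inside <- point_in_polygon(px, py, v[, 1], v[, 2])
  sum(grid$raw_mass[xi, yi, drop = FALSE][inside])
}

# Close an open marching-squares contour along the grid boundary. Both
# boundary paths (clockwise and counter-clockwise insertion of the corner
# points) are tried; the closure enclosing more grid mass is kept, since
# the super-level set is on the denser side of the contour.
close_contour_ring <- function(v, grid, threshold) {
  n <- nrow(v)
  if (v[1, 1] == v[n, 1] && v[1, 2] == v[n, 2]) return(list(v))
  xr <- range(grid$x_mids); yr <- range(grid$y_mids)
  w <- diff(xr); h <- diff(yr)
  peri <- function(p) {
    # perimeter coordinate, counter-clockwise from (xmin, ymin); the point
    # is snapped to its nearest rectangle side
    x <- min(max(p[1], xr[1]), xr[2]); y <- min(max(p[2], yr[1]), yr[2])
    d <- c(y - yr[1], xr[2] - x, yr[2] - y, x - xr[1])  # bottom/right/top/left
    switch(which.min(d),
           x - xr[1],
           w + (y - yr[1]),
           w + h + (xr[2] - x),
           2 * w + h + (yr[2] - y))
  }
  corners <- rbind(c(xr[2], yr[1]), c(xr[2], yr[2]), c(xr[1], yr[2]), c(xr[1], yr[1]))
  corner_s <- c(diff(xr), diff(xr) + diff(yr), 2 * diff(xr) + diff(yr),
                2 * (diff(xr) + diff(yr)))
  total <- 2 * (diff(xr) + diff(yr))
  s_end <- peri(v[n, ]); s_start <- peri(v[1, ])
  path_ccw <- {
    ds <- (corner_s - s_end) %% total
    dlim <- (s_start - s_end) %% total
    ord <- order(ds)
    corners[ord, , drop = FALSE][ds[ord] > 1e-12 & ds[ord] < dlim - 1e-12, , drop = FALSE]
  }
  path_cw <- {
    ds <- (s_end - corner_s) %% total
    dlim <- (s_end - s_start) %% total
    ord <- order(ds)
    corners[ord, , drop = FALSE][ds[ord] > 1e-12 & ds[ord] < dlim - 1e-12, , drop = FALSE]
  }
  cand <- list(rbind(v, path_ccw), rbind(v, path_cw))
  masses <- vapply(cand, enclosed_grid_mass, 0, grid = grid)
  list(cand[[which.max(masses)]])
}

#' Select the main population's contour
#'
#' Multimodal densities yield several contour rings at one threshold; the
#' gate derives from the main population, i.e. the ring enclosing the most
#' mass (ties broken by larger area).
#'
#' @param polygons non-empty list of `contour_polygon`s.
#' @return The selected `contour_polygon`.
#' @export
main_component <- function(polygons) {
  if (!length(polygons)) {
    sg_stop("sortgate_error_no_contour", "no contour polygons to choose from")
  }
  masses <- vapply(polygons, `[[`, 0, "enclosed_mass")
  areas <- vapply(polygons, function(p) polygon_area(p$vertices), 0)
  best <- order(-masses, -areas)[1]
  polygons[[best]]
}
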