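#' Gating configuration
#'
#' Parameters of the automated gating strategy. Defaults reproduce the
#' standard protocol: capture the brightest 1% of profiled events with a
#' gate whose vertical (back-scatter) extent comes from the 80% mass
#' contour and whose side shape comes from the 25% mass contour, as a
#' concave polygon of at most 60 vertices.
#'
#' @param target_fraction fraction of events the fitted gate must capture
#'   (default 0.01).
#' @param height_contour_mass HDR mass level fixing the gate's vertical
#'   extent (default 0.80).
#' @param side_contour_mass HDR mass level whose rightmost boundary arc
#'   shapes the gate's sides (default 0.25).
#' @param max_vertices vertex budget of the emitted gate (default 60).
#' @param fraction_tolerance absolute convergence tolerance on the captured
#'   fraction (default 0.001, about 50 events at n = 50,000).
#' @param max_rotation rotation search bound in degrees (default 15); 0
#'   disables the rotation phase.
#' @param grid_size,smoothing_bandwidth density-estimation parameters, see
#'   [estimate_density()].
#' @return An object of class `gate_config`.
#' @export
gate_config <- function(target_fraction = 0.01, height_contour_mass = 0.80,
                        side_contour_mass = 0.25, max_vertices = 60,
                        fraction_tolerance = 0.001, max_rotation = 15,
                        grid_size = 256, smoothing_bandwidth = 2) {
  bad <- function(msg) sg_stop("sortgate_error_invalid_config", msg)
  if (!is.numeric(target_fraction) || target_fraction <= 0 || target_fraction >= 1) {
    bad("target_fraction must lie strictly between 0 and 1")
  }
  for (m in c(height_contour_mass, side_contour_mass)) {
    if (!is.numeric(m) || m <= 0 || m >= 1) bad("contour mass levels must lie in (0, 1)")
  }
  if (!is.numeric(max_vertices) || max_vertices < 3) bad("max_vertices must be at least 3")
  if (!is.numeric(fraction_tolerance) || fraction_tolerance <= 0) bad("fraction_tolerance must be > 0")
  if (!is.numeric(max_rotation) || max_rotation < 0) bad("max_rotation must be >= 0")
  structure(list(target_fraction = target_fraction,
                 height_contour_mass = height_contour_mass,
                 side_contour_mass = side_contour_mass,
                 max_vertices = as.integer(max_vertices),
                 fraction_tolerance = fraction_tolerance,
                 max_rotation = max_rotation,
                 grid_size = grid_size,
                 smoothing_bandwidth = smoothing_bandwidth),
            class = "gate_config")
}

new_gate_polygon <- function(vertices, axis, transform_tags, sample_id = "") {
  v <- ring_open(vertices)
  structure(list(vertices = ring_close(v),
                 n_vertices = nrow(v),
                 axis = axis,
                 transform_tags = transform_tags,
                 sample_id = sample_id),
            class = "gate_polygon")
}

#' @export
print.gate_polygon <- function(x, ...) {
  cat(sprintf("<gate_polygon> %d vertices, axes %s (%s) x %s (%s)\n",
              x$n_vertices, x$axis$fluorescence, x$transform_tags[["fluorescence"]],
              x$axis$backscatter, x$transform_tags[["backscatter"]]))
  invisible(x)
}

#' Extract the high-fluorescence boundary arc of a contour
#'
#' Splits a closed contour ring at its lowest and highest back-scatter
#' vertices and returns the arc on the bright (high-fluorescence) side,
#' ordered by increasing back-scatter and made y-monotone. This arc is what
#' shapes the sides of the sorting gate, and the same extraction is used by
#' the gate diagnostics.
#'
#' @param polygon a `contour_polygon` (or any object with closed-ring
#'   `vertices`).
#' @return An m x 2 matrix (fluorescence, back-scatter), y strictly
#'   increasing.
#' @export
contour_side_arc <- function(polygon) {
  v <- ring_open(polygon$vertices)
  n <- nrow(v)
  i_lo <- which.min(v[, 2]); i_hi <- which.max(v[, 2])
  walk <- function(from, to) {
    idx <- from
    i <- from
    while (i != to) {
      i <- if (i == n) 1L else i + 1L
      idx <- c(idx, i)
    }
    idx
  }
  arc1 <- walk(i_lo, i_hi)
  arc2 <- walk(i_hi, i_lo)
  pick <- if (max(v[arc1, 1]) >= max(v[arc2, 1])) arc1 else rev(arc2)
  arc <- v[pick, , drop = FALSE]
  # enforce y-monotonicity so the arc is a function x(y)
  arc <- arc[order(arc[, 2]), , drop = FALSE]
  dup <- duplicated(arc[, 2])
  if (any(dup)) {
    keep <- !logical(nrow(arc))
    for (y in unique(arc[dup, 2])) {
      at <- which(arc[, 2] == y)
      keep[at[-which.max(arc[at, 1])]] <- FALSE
    }
    arc <- arc[keep, , drop = FALSE]
  }
  arc
}

#' Build the template sorting gate from the two shaping contours
#'
#' Constructs the unfitted ("template") gate polygon: the back-scatter
#' extent is the height contour's (by default the 80% mass contour), the
#' left boundary is the side contour's bright-edge arc (by default 25%)
#' extended/clipped to that extent with constant-fluorescence segments, the
#' right boundary is the left boundary translated brighter by the side
#' contour's fluorescence span, and top/bottom edges join the two curves.
#' Both side curves are resampled by arc length so the closed ring respects
#' the vertex budget.
#'
#' @param contour80 `contour_polygon` fixing the vertical extent.
#' @param contour25 `contour_polygon` shaping the sides.
#' @param config a [gate_config()].
#' @param axis an [axis_mapping()] recorded in the gate.
#' @param transform_tags per-axis transform tags recorded in the gate.
#' @return A `gate_polygon` with positive area and at most
#'   `config$max_vertices` vertices.
#' @export
build_template_gate <- function(contour80, contour25, config = gate_config(),
                                axis = axis_mapping(),
                                transform_tags = c(fluorescence = "asinh",
                                                   backscatter = "linear")) {
  v80 <- ring_open(contour80$vertices)
  v25 <- ring_open(contour25$vertices)
  y_lo <- min(v80[, 2]); y_hi <- max(v80[, 2])
  if (max(v25[, 2]) < y_lo || min(v25[, 2]) > y_hi) {
    sg_stop("sortgate_error_geometry",
            "the two shaping contours have disjoint back-scatter ranges")
  }
  arc <- contour_side_arc(contour25)
  # clip to [y_lo, y_hi] ...
  inb <- arc[, 2] >= y_lo & arc[, 2] <= y_hi
  if (sum(inb) < 2) {
    xf <- function(y) stats::approx(arc[, 2], arc[, 1], xout = y, rule = 2,
                                    ties = "ordered")$y
    arc <- cbind(xf(c(y_lo, y_hi)), c(y_lo, y_hi))
  } else {
    arc <- arc[inb, , drop = FALSE]
  }
  # ... and extend with constant-fluorescence segments so the gate's
  # vertical extent equals the height contour's
  if (arc[1, 2] > y_lo) arc <- rbind(c(arc[1, 1], y_lo), arc)
  if (arc[nrow(arc), 2] < y_hi) arc <- rbind(arc, c(arc[nrow(arc), 1], y_hi))

  width <- diff(range(v25[, 1]))
  m <- max(2L, config$max_vertices %/% 2L)
  left <- resample_polyline(arc, m)
  right <- left[rev(seq_len(m)), , drop = FALSE]
  right[, 1] <- right[, 1] + width
  ring <- rbind(left, right)
  gate <- new_gate_polygon(ring, axis, transform_tags,
                           sample_id = contour80$sample_id %||% "")
  if (polygon_area(gate$vertices) <= 0) {
    sg_stop("sortgate_error_geometry", "degenerate template gate (zero area)")
  }
  gate
}

#' Fraction of a sample's events captured by a gate
#'
#' Even-odd point-in-polygon membership over all events; points on the gate
#' boundary count as inside.
#'
#' @param gate a `gate_polygon`.
#' @param table an [event_table()] in the same transform space as the gate.
#' @param axis an [axis_mapping()]; defaults to the gate's own.
#' @return Captured fraction in \[0, 1\].
#' @export
captured_fraction <- function(gate, table, axis = gate$axis) {
  stopifnot(inherits(gate, "gate_polygon"))
  tags <- axis_tags(table, axis)
  if (!identical(unname(tags), unname(gate$transform_tags[c("fluorescence", "backscatter")]))) {
    sg_stop("sortgate_error_transform_mismatch",
            sprintf("gate transform (%s/%s) does not match table transform (%s/%s)",
                    gate$transform_tags[["fluorescence"]], gate$transform_tags[["backscatter"]],
                    tags[["fluorescence"]], tags[["backscatter"]]))
  }
  xy <- axis_values(table, axis)
  if (nrow(xy) == 0L) return(0)
  v <- ring_open(gate$vertices)
  mean(point_in_polygon(xy[, 1], xy[, 2], v[, 1], v[, 2]))
}

translate_gate <- function(gate, dx) {
  v <- ring_open(gate$vertices)
  v[, 1] <- v[, 1] + dx
  new_gate_polygon(v, gate$axis, gate$transform_tags, gate$sample_id)
}

# Rotation in axis-standardised coordinates (each axis divided by the event
# sd) about the gate centroid: degrees are not comparable across axes of
# different units.
rotate_gate <- function(gate, degrees, scale) {
  v <- ring_open(gate$vertices)
  c0 <- ring_centroid(v)
  th <- degrees * pi / 180
  u <- sweep(v, 2, c0)
  u[, 1] <- u[, 1] / scale[1]; u[, 2] <- u[, 2] / scale[2]
  r <- cbind(u[, 1] * cos(th) - u[, 2] * sin(th),
             u[, 1] * sin(th) + u[, 2] * cos(th))
  r[, 1] <- r[, 1] * scale[1]; r[, 2] <- r[, 2] * scale[2]
  new_gate_polygon(sweep(r, 2, c0, `+`), gate$axis, gate$transform_tags, gate$sample_id)
}

#' Fit the template gate to capture the target fraction
#'
#' Phase 1 translates the template along the fluorescence axis — on the
#' bright tail a rightward shift captures fewer events — and bisects the
#' translation until the captured fraction is within tolerance of the
#' target or the bracket collapses. If phase 1 does not converge, phase 2
#' runs a golden-section search on a rotation about the gate centroid
#' within the configured bound, repeating phase 1 at each candidate angle.
#' The search is fully deterministic.
#'
#' An unreachable target (e.g. a target fraction larger than any placement
#' can capture) yields the best attainable result flagged
#' `converged = FALSE`, never an exception.
#'
#' @param template a `gate_polygon` from [build_template_gate()].
#' @param table the profiled [event_table()] (at least 100 events).
#' @param axis an [axis_mapping()]; defaults to the template's.
#' @param config a [gate_config()].
#' @return An object of class `gate_fit` with fields `gate` (the fitted
#'   `gate_polygon`), `achieved_fraction`, `translation`, `rotation`,
#'   `iterations` and `converged`.
#' @export
fit_gate <- function(template, table, axis = template$axis, config = gate_config()) {
  stopifnot(inherits(template, "gate_polygon"))
  if (table$n_events < 100) {
    sg_stop("sortgate_error_insufficient_events",
            sprintf("sample '%s' has %d events; at least 100 are required for gate fitting",
                    table$sample_id, table$n_events))
  }
  xy <- axis_values(table, axis)
  target <- config$target_fraction
  tol <- config$fraction_tolerance
  iterations <- 0L

  frac_at <- function(gate) {
    v <- ring_open(gate$vertices)
    iterations <<- iterations + 1L
    mean(point_in_polygon(xy[, 1], xy[, 2], v[, 1], v[, 2]))
  }

  phase1 <- function(base) {
    v <- ring_open(base$vertices)
    # events outside the gate's (translation-invariant) back-scatter band
    # can never enter; restrict to the band once
    band <- xy[, 2] >= min(v[, 2]) & xy[, 2] <= max(v[, 2])
    n_all <- nrow(xy)
    sub <- xy[band, , drop = FALSE]
    vx_min <- min(v[, 1]); vx_max <- max(v[, 1])
    f_sub <- function(dx) {
      if (nrow(sub) == 0L) return(0)
      iterations <<- iterations + 1L
      # only events inside the translated bounding box can be captured
      cand <- sub[, 1] >= vx_min + dx & sub[, 1] <= vx_max + dx
      if (!any(cand)) return(0)
      sum(point_in_polygon(sub[cand, 1] - dx, sub[cand, 2], v[, 1], v[, 2])) / n_all
    }
    d_hi <- max(xy[, 1]) - min(v[, 1])            # gate fully right: captures 0
    d_lo_lim <- min(xy[, 1]) - max(v[, 1])        # gate fully left: captures 0
    nstep <- 200L
    step <- (d_hi - d_lo_lim) / nstep
    best <- list(dx = d_hi, f = 0)
    d_lo <- NA_real_
    d <- d_hi
    for (k in seq_len(nstep + 1L)) {
      f <- f_sub(d)
      if (abs(f - target) <= abs(best$f - target)) best <- list(dx = d, f = f)
      if (f >= target) { d_lo <- d; break }
      d <- d - step
    }
    if (is.na(d_lo)) {
      return(list(dx = best$dx, f = best$f, converged = abs(best$f - target) <= tol))
    }
    # bisect to bracket collapse, keeping the translation whose capture is
    # closest to the target: stopping at the first in-tolerance value
    # would bias the achieved fraction toward the approach side
    hi <- d_lo + step
    lo <- d_lo
    f_lo <- f_sub(lo)
    best <- list(dx = lo, f = f_lo)
    while ((hi - lo) > step * 1e-10) {
      mid <- (lo + hi) / 2
      f_mid <- f_sub(mid)
      if (abs(f_mid - target) < abs(best$f - target)) best <- list(dx = mid, f = f_mid)
      if (f_mid >= target) lo <- mid else hi <- mid
    }
    list(dx = best$dx, f = best$f, converged = abs(best$f - target) <= tol)
  }

  res1 <- phase1(template)
  rotation <- 0
  result <- res1
  scale <- c(max(sd(xy[, 1]), .Machine$double.eps),
             max(sd(xy[, 2]), .Machine$double.eps))
  if (!res1$converged && config$max_rotation > 0) {
    obj <- function(theta) abs(phase1(rotate_gate(template, theta, scale))$f - target)
    opt <- optimize(obj, interval = c(-config$max_rotation, config$max_rotation),
                    tol = 0.05)
    cand <- phase1(rotate_gate(template, opt$minimum, scale))
    if (abs(cand$f - target) < abs(result$f - target)) {
      rotation <- opt$minimum
      result <- cand
    }
  }
  base <- if (rotation != 0) rotate_gate(template, rotation, scale) else template
  gate <- translate_gate(base, result$dx)
  gate$sample_id <- table$sample_id
  structure(list(gate = gate,
                 achieved_fraction = result$f,
                 translation = result$dx,
                 rotation = rotation,
                 iterations = iterations,
                 converged = isTRUE(result$converged)),
            class = "gate_fit")
}

#' @export
print.gate_fit <- function(x, ...) {
  cat(sprintf("<gate_fit> captured %.4f (target met: %s), translation %.4g, rotation %.2f deg, %d evaluations\n",
              x$achieved_fraction, x$converged, x$translation, x$rotation, x$iterations))
  invisible(x)
}

#' Export / import a gate as a plain-text vertex file
#'
#' Open vertex hand-off format: `key: value` header lines (sample id,
#' channels, transform tags, vertex count) followed by one `x,y` line per
#' vertex with 17 significant digits, so a re-imported gate reproduces the
#' original exactly — including its captured fraction, to the last bit.
#'
#' @param gate a `gate_polygon`.
#' @param path file path.
#' @return `export_gate`: `path`, invisibly. `import_gate`: a
#'   `gate_polygon`.
#' @export
export_gate <- function(gate, path) {
  stopifnot(inherits(gate, "gate_polygon"))
  v <- ring_open(gate$vertices)
  lines <- c(
    "# sortgate vertex file v1",
    paste0("sample_id: ", gate$sample_id),
    paste0("fluorescence_channel: ", gate$axis$fluorescence),
    paste0("backscatter_channel: ", gate$axis$backscatter),
    paste0("fluorescence_transform: ", gate$transform_tags[["fluorescence"]]),
    paste0("backscatter_transform: ", gate$transform_tags[["backscatter"]]),
    paste0("n_vertices: ", nrow(v)),
    sprintf("%.17g,%.17g", v[, 1], v[, 2]))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) sg_stop("sortgate_error_io", sprintf("cannot write gate file: %s", path))
  invisible(path)
}

#' @rdname export_gate
#' @export
import_gate <- function(path) {
  if (!file.exists(path)) {
    sg_stop("sortgate_error_io", sprintf("gate file not found: %s", path))
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  hdr <- grep("^[a-z_]+: ", lines, value = TRUE)
  get <- function(key) {
    hit <- grep(paste0("^", key, ": "), hdr, value = TRUE)
    if (!length(hit)) sg_stop("sortgate_error_io", sprintf("gate file missing field '%s'", key))
    sub(paste0("^", key, ": "), "", hit[1])
  }
  vlines <- grep("^[-0-9]", lines, value = TRUE)
  parts <- strsplit(vlines, ",", fixed = TRUE)
  v <- cbind(as.numeric(vapply(parts, `[[`, "", 1)),
             as.numeric(vapply(parts, `[[`, "", 2)))
  if (nrow(v) != as.integer(get("n_vertices"))) {
    sg_stop("sortgate_error_io", "gate file vertex count does not match header")
  }
  new_gate_polygon(v,
                   axis_mapping(get("fluorescence_channel"), get("backscatter_channel")),
                   c(fluorescence = get("fluorescence_transform"),
                     backscatter = get("backscatter_transform")),
                   sample_id = get("sample_id"))
}

#' One-call gating of a profiled sample
#'
#' Convenience wrapper running the full gating chain: density estimation,
#' height/side HDR contours, main-component selection, template
#' construction and fitting.
#'
#' @param table profiled [event_table()].
#' @param axis an [axis_mapping()].
#' @param config a [gate_config()].
#' @return A list with the `gate_fit` (`fit`), the `density_grid`
#'   (`density`), both main contours (`contour_height`, `contour_side`) and
#'   the unfitted `template`.
#' @export
auto_gate <- function(table, axis = axis_mapping(), config = gate_config()) {
  grid <- estimate_density(table, axis, grid_size = config$grid_size,
                           smoothing_bandwidth = config$smoothing_bandwidth)
  c_h <- main_component(contour_at_mass(grid, config$height_contour_mass))
  c_s <- main_component(contour_at_mass(grid, config$side_contour_mass))
  template <- build_template_gate(c_h, c_s, config, axis = axis,
                                  transform_tags = axis_tags(table, axis))
  fit <- fit_gate(template, table, axis, config)
  list(fit = fit, density = grid, contour_height = c_h, contour_side = c_s,
       template = template)
}
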