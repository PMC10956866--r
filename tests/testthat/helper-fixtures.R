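# Shared fixtures and independent oracles for the test suite.

# Small multi-channel table with reproducible values.
make_test_table <- function(n = 100, k = 4, seed = 42, sample_id = "fixture") {
  withr::with_seed(seed, {
    m <- matrix(abs(rnorm(n * k, mean = 100, sd = 25)), ncol = k)
    colnames(m) <- paste0("CH", seq_len(k))
    event_table(m, sample_id = sample_id)
  })
}

# Isotropic standard bivariate Gaussian sample as an event table.
make_gaussian_table <- function(n = 50000, seed = 7, sd_x = 1, sd_y = 1) {
  withr::with_seed(seed, {
    m <- cbind(FL1 = rnorm(n, 0, sd_x), BSC = rnorm(n, 0, sd_y))
    event_table(m, sample_id = "gauss",
                transform_tags = c(FL1 = "asinh", BSC = "linear"))
  })
}

# Independent point-in-polygon oracle: winding number by summed signed
# angles. Valid for simple polygons and points off the boundary.
winding_inside <- function(px, py, vx, vy) {
  nv <- length(vx)
  if (vx[1] == vx[nv] && vy[1] == vy[nv]) {
    vx <- vx[-nv]; vy <- vy[-nv]; nv <- nv - 1
  }
  vapply(seq_along(px), function(i) {
    ang <- atan2(vy - py[i], vx - px[i])
    d <- diff(c(ang, ang[1]))
    d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
    abs(sum(d)) > pi  # |winding| >= 1
  }, TRUE)
}

# Random simple (star-shaped) polygon around a centre.
make_star_polygon <- function(n_vertices = 12, seed = 1, centre = c(0, 0), scale = 1) {
  withr::with_seed(seed, {
    ang <- sort(runif(n_vertices, 0, 2 * pi))
    rad <- runif(n_vertices, 0.3, 1) * scale
    cbind(centre[1] + rad * cos(ang), centre[2] + rad * sin(ang))
  })
}

# Rectangle gate covering [x1, x2] x [y1, y2].
make_rect_gate <- function(x1, x2, y1, y2,
                           tags = c(fluorescence = "asinh", backscatter = "linear")) {
  v <- cbind(c(x1, x2, x2, x1), c(y1, y1, y2, y2))
  sortgate:::new_gate_polygon(v, axis_mapping(), tags)
}

expect_sg_error <- function(expr, class) {
  expect_error(expr, class = class)
}

# Page count of a PDF: /Type /Page occurrences minus the /Type /Pages tree
# nodes; byte-level so binary stream content is harmless.
count_pdf_pages <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  length(grepRaw("/Type /Page", raw, all = TRUE, fixed = TRUE)) -
    length(grepRaw("/Type /Pages", raw, all = TRUE, fixed = TRUE))
}
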