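# Shared gating fixture: one mid-panel synthetic sample, gated once.
fixture_sample <- simulate_sample(panel_sample_spec("gfix", 0.1, 3, n_events = 50000, seed = 11))
fixture_gating <- auto_gate(fixture_sample)

test_that("gate_config validates its fields", {
  expect_error(gate_config(target_fraction = 0), class = "sortgate_error_invalid_config")
  expect_error(gate_config(max_vertices = 2), class = "sortgate_error_invalid_config")
  expect_error(gate_config(fraction_tolerance = -1), class = "sortgate_error_invalid_config")
  cfg <- gate_config()
  expect_equal(cfg$target_fraction, 0.01)
  expect_equal(cfg$height_contour_mass, 0.80)
  expect_equal(cfg$side_contour_mass, 0.25)
  expect_equal(cfg$max_vertices, 60L)
})

test_that("template gate takes its vertical extent from the height contour", {
  g <- fixture_gating
  v80 <- g$contour_height$vertices
  cell <- diff(g$density$y_edges)[1]
  tmpl <- g$template
  expect_lte(abs(min(tmpl$vertices[, 2]) - min(v80[, 2])), cell)
  expect_lte(abs(max(tmpl$vertices[, 2]) - max(v80[, 2])), cell)
  expect_lte(tmpl$n_vertices, 60)
  expect_gt(sortgate:::polygon_area(tmpl$vertices), 0)
})

test_that("a rectangular side contour yields a rectangular template", {
  rect25 <- structure(list(vertices = cbind(c(0, 1, 1, 0, 0), c(2, 2, 6, 6, 2)),
                           enclosed_mass = 0.25, level_mass = 0.25), class = "contour_polygon")
  rect80 <- structure(list(vertices = cbind(c(-1, 2, 2, -1, -1), c(0, 0, 8, 8, 0)),
                           enclosed_mass = 0.8, level_mass = 0.8), class = "contour_polygon")
  tmpl <- build_template_gate(rect80, rect25, gate_config())
  v <- sortgate:::ring_open(tmpl$vertices)
  # height from the 80% contour, width from the 25% contour's span
  expect_equal(range(v[, 2]), c(0, 8))
  expect_equal(diff(range(v[, 1])), 1)       # left edge at x=1, width 1
  expect_equal(range(v[, 1]), c(1, 2))
  # all vertices sit on the rectangle outline
  on_edge <- (v[, 1] %in% c(1, 2)) | (v[, 2] %in% c(0, 8))
  expect_true(all(on_edge))
})

test_that("disjoint shaping contours raise a geometry error", {
  lo <- structure(list(vertices = cbind(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0))),
                  class = "contour_polygon")
  hi <- structure(list(vertices = cbind(c(0, 1, 1, 0, 0), c(5, 5, 6, 6, 5))),
                  class = "contour_polygon")
  expect_error(build_template_gate(hi, lo, gate_config()),
               class = "sortgate_error_geometry")
})

test_that("captured_fraction handles the limiting gates", {
  tab <- fixture_sample
  xy <- tab$values
  bbox <- make_rect_gate(min(xy[, "FL1"]), max(xy[, "FL1"]),
                         min(xy[, "BSC"]), max(xy[, "BSC"]))
  expect_equal(captured_fraction(bbox, tab), 1.0)

  outside <- make_rect_gate(max(xy[, "FL1"]) + 1, max(xy[, "FL1"]) + 2,
                            min(xy[, "BSC"]), max(xy[, "BSC"]))
  expect_equal(captured_fraction(outside, tab), 0.0)

  raw <- event_table(tab$values, transform_tags = c(FL1 = "linear", BSC = "linear"))
  expect_error(captured_fraction(bbox, raw),
               class = "sortgate_error_transform_mismatch")
})

test_that("point-in-polygon agrees with the winding-number oracle", {
  poly <- make_star_polygon(12, seed = 2)
  withr::with_seed(3, {
    px <- runif(500, -1.2, 1.2); py <- runif(500, -1.2, 1.2)
  })
  mine <- point_in_polygon(px, py, poly[, 1], poly[, 2])
  oracle <- winding_inside(px, py, poly[, 1], poly[, 2])
  expect_identical(mine, oracle)
})

test_that("default fit captures the top 1% on a panel sample", {
  fit <- fixture_gating$fit
  expect_true(fit$converged)
  expect_equal(fit$achieved_fraction, 0.01, tolerance = 0.1)  # relative
  expect_lte(abs(fit$achieved_fraction - 0.01), 0.001)
  expect_lte(fit$gate$n_vertices, 60)
  # the reported fraction matches an independent recount through the gate
  expect_equal(captured_fraction(fit$gate, fixture_sample), fit$achieved_fraction,
               tolerance = 1e-12)
})

test_that("near-total target converges at the leftmost useful translation", {
  tab <- make_gaussian_table(n = 5000, seed = 14)
  xy <- tab$values
  big <- make_rect_gate(0, diff(range(xy[, 1])) * 1.2,
                        min(xy[, 2]) - 1, max(xy[, 2]) + 1)
  cfg <- gate_config(target_fraction = 0.995, fraction_tolerance = 0.005)
  fit <- fit_gate(big, tab, axis_mapping(), cfg)
  expect_true(fit$converged)
  expect_gte(fit$achieved_fraction, 0.99)
})

test_that("unreachable targets return an unconverged result, not an error", {
  tab <- make_gaussian_table(n = 2000, seed = 15)
  tiny <- make_rect_gate(0, 1e-6, -0.01, 0.01)  # captures at most a sliver
  cfg <- gate_config(target_fraction = 0.5, max_rotation = 5)
  fit <- fit_gate(tiny, tab, axis_mapping(), cfg)
  expect_false(fit$converged)
  expect_lt(fit$achieved_fraction, 0.5)
})

test_that("a tall rectangle at 5% places its left edge at the 95th percentile", {
  withr::with_seed(16, {
    m <- cbind(FL1 = rexp(40000, rate = 1), BSC = rnorm(40000, 5, 1))
  })
  tab <- event_table(m, transform_tags = c(FL1 = "asinh", BSC = "linear"))
  gate <- make_rect_gate(0, 50, min(m[, 2]) - 1, max(m[, 2]) + 1)
  cfg <- gate_config(target_fraction = 0.05, max_rotation = 0)
  fit <- fit_gate(gate, tab, axis_mapping(), cfg)
  expect_true(fit$converged)
  left <- min(sortgate:::ring_open(fit$gate$vertices)[, 1])
  band <- quantile(m[, "FL1"], c(0.945, 0.955))
  expect_gte(left, band[[1]])
  expect_lte(left, band[[2]])
})

test_that("capture is monotone non-increasing along rightward translation", {
  g <- fixture_gating
  tab <- fixture_sample
  fracs <- vapply(seq(0, 4, length.out = 15), function(dx) {
    captured_fraction(sortgate:::translate_gate(g$fit$gate, dx), tab)
  }, 0)
  expect_true(all(diff(fracs) <= 0))
})

test_that("gate fitting is deterministic", {
  f1 <- fit_gate(fixture_gating$template, fixture_sample, config = gate_config())
  f2 <- fit_gate(fixture_gating$template, fixture_sample, config = gate_config())
  expect_identical(f1$gate$vertices, f2$gate$vertices)
  expect_identical(f1$achieved_fraction, f2$achieved_fraction)
})

test_that("gate export/import round-trips exactly", {
  tri <- sortgate:::new_gate_polygon(cbind(c(0, 1, 0.5), c(0, 0, 1)),
                                     axis_mapping(),
                                     c(fluorescence = "asinh", backscatter = "linear"),
                                     sample_id = "tri")
  p <- withr::local_tempfile(fileext = ".gate")
  export_gate(tri, p)
  lines <- readLines(p)
  expect_length(grep("^[-0-9]", lines), 3)
  back <- import_gate(p)
  expect_identical(back$vertices, tri$vertices)
  expect_equal(back$sample_id, "tri")

  g <- fixture_gating$fit$gate
  p2 <- withr::local_tempfile(fileext = ".gate")
  export_gate(g, p2)
  expect_length(grep("^[-0-9]", readLines(p2)), g$n_vertices)
  back2 <- import_gate(p2)
  expect_identical(back2$vertices, g$vertices)
  expect_identical(captured_fraction(back2, fixture_sample),
                   captured_fraction(g, fixture_sample))
})
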