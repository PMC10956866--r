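test_that("event_table validates structure and drops non-finite events", {
  m <- cbind(FL1 = c(1, 2, NA, 4), BSC = c(5, Inf, 7, 8))
  expect_message(tab <- event_table(m), "dropped 2 event")
  expect_equal(tab$n_events, 2)
  expect_true(all(is.finite(tab$values)))

  expect_error(event_table(cbind(1:3, 4:6)), class = "sortgate_error_invalid_table")
  dup <- cbind(a = 1:3, a = 4:6)
  expect_error(event_table(dup * 1.0), class = "sortgate_error_invalid_table")
  expect_error(event_table(cbind(FL1 = 1), transform_tags = c(FL1 = "weird")),
               class = "sortgate_error_invalid_table")
})

test_that("FCS write/read round-trips tables exactly", {
  tab <- make_test_table(n = 100, k = 4)
  path <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(tab, path)
  back <- read_fcs(path)
  expect_equal(back$n_events, 100)
  expect_equal(back$channels, tab$channels)
  expect_equal(back$sample_id, tab$sample_id)
  expect_identical(unname(back$values), unname(tab$values))
  expect_equal(back$transform_tags, tab$transform_tags)
})

test_that("FCS handles zero-event files and rejects corrupt input", {
  empty <- event_table(matrix(numeric(0), ncol = 2,
                              dimnames = list(NULL, c("FL1", "BSC"))))
  path <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(empty, path)
  back <- read_fcs(path)
  expect_equal(back$n_events, 0)
  expect_equal(back$channels, c("FL1", "BSC"))

  # truncated header
  trunc <- withr::local_tempfile(fileext = ".fcs")
  writeBin(charToRaw("FCS3.1  "), trunc)
  expect_error(read_fcs(trunc), "HEADER", class = "sortgate_error_fcs_format")

  # truncated data segment
  tab <- make_test_table(n = 50, k = 2)
  full <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(tab, full)
  raw <- readBin(full, "raw", file.info(full)$size)
  cut <- withr::local_tempfile(fileext = ".fcs")
  writeBin(raw[1:(length(raw) - 100)], cut)
  expect_error(read_fcs(cut), "DATA", class = "sortgate_error_fcs_format")
})

test_that("FCS fixture of 10,000 events recovers generator means", {
  spec <- panel_sample_spec("fcs_stat", 0.3, 3, n_events = 10000, seed = 5)
  tab <- simulate_sample(spec)
  path <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(tab, path)
  back <- read_fcs(path)
  # mixture means and standard errors from the generative parameters
  for (ch in c("FL1", "BSC")) {
    mu <- sum(vapply(spec$populations, function(p) {
      p$weight * if (ch == "FL1") p$fluo_mean else p$bsc_mean
    }, 0))
    se <- sd(tab$values[, ch]) / sqrt(10000)
    expect_lt(abs(mean(back$values[, ch]) - mu), 3 * se)
  }
})

test_that("CSV write/read round-trips, including 60,000-event tables", {
  small <- event_table(cbind(FL1 = c(1.5, 2.25, -3.125), BSC = c(4, 5, 6)),
                       sample_id = "small")
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_events_csv(small, p1)
  back <- read_events_csv(p1, sample_id = "small")
  expect_identical(unname(back$values), unname(small$values))
  expect_equal(back$channels, small$channels)

  big <- simulate_sample(panel_sample_spec("big", 0.2, 2.5, n_events = 60000, seed = 9))
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_events_csv(big, p2)
  back2 <- read_events_csv(p2)
  rel <- abs(back2$values - big$values) / pmax(abs(big$values), 1e-300)
  expect_lt(max(rel), 1e-9)
})

test_that("CSV edge cases: header-only file, non-numeric cell", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines("FL1,BSC", p)
  tab <- read_events_csv(p)
  expect_equal(tab$n_events, 0)
  expect_equal(tab$channels, c("FL1", "BSC"))

  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("FL1,BSC", "1,2", "3,oops"), p2)
  err <- tryCatch(read_events_csv(p2), error = identity)
  expect_s3_class(err, "sortgate_error_csv_parse")
  expect_match(conditionMessage(err), "row 2")
  expect_match(conditionMessage(err), "BSC")
})

test_that("apply_transform implements the documented schemes", {
  tab <- event_table(cbind(FL1 = c(0, 150, 1000), BSC = c(1, 2, 3)))
  ax <- axis_mapping("FL1", "BSC")

  lin <- apply_transform(tab, ax, "linear")
  expect_identical(lin$values, tab$values)

  lg <- apply_transform(tab, ax, "log10")
  expect_equal(unname(lg$values[1, "FL1"]), 0)                 # log10(0 + 1)
  expect_equal(unname(lg$values[3, "FL1"]), log10(1001))
  expect_equal(unname(lg$transform_tags["FL1"]), "log10")
  expect_equal(unname(lg$transform_tags["BSC"]), "linear")

  as <- apply_transform(tab, ax, "asinh", cofactor = 150)
  expect_equal(unname(as$values[2, "FL1"]), asinh(1), tolerance = 1e-12)
  expect_equal(unname(as$values[2, "FL1"]), 0.8813736, tolerance = 1e-6)

  neg <- event_table(cbind(FL1 = c(-5, 1), BSC = c(1, 2)))
  expect_error(apply_transform(neg, ax, "log10"), "asinh",
               class = "sortgate_error_negative_log")
})

test_that("apply_transform is monotone per channel", {
  tab <- make_test_table(n = 500, k = 2, seed = 13)
  colnames(tab$values) <- c("FL1", "BSC")
  tab <- event_table(tab$values, transform_tags = NULL)
  ax <- axis_mapping("FL1", "BSC")
  for (scheme in c("log10", "asinh")) {
    tr <- apply_transform(tab, ax, scheme, which = "both")
    for (ch in c("FL1", "BSC")) {
      expect_identical(order(tr$values[, ch]), order(tab$values[, ch]),
                       info = paste(scheme, ch))
    }
  }
})
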