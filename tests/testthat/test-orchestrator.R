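# Small panel shared across the orchestration tests (kept light; the full
# 50,000-event study panel is exercised in the acceptance suite).
orc_panel <- make_panel(4, seed = 30, n_events = 8000)
orc_tables <- lapply(orc_panel, simulate_sample)
orc_worklist <- data.frame(name = names(orc_panel),
                           position = seq_along(orc_panel),
                           well = valid_wells()[seq_along(orc_panel)])

run_small_batch <- function(tables = orc_tables, worklist = orc_worklist, ...) {
  run_batch(worklist, tables, n_profile = 4000, n_sort = 50,
            seed = 55, ...)
}

test_that("a batch processes every sample in worklist order", {
  batch <- run_small_batch()
  expect_length(batch$results, 4)
  expect_identical(names(batch$results), orc_worklist$name)
  expect_true(all(batch$status == "done"))
  fits <- lapply(batch$results, function(r) r$gating$fit)
  expect_true(all(vapply(fits, `[[`, TRUE, "converged")))
  infos <- Filter(function(r) r$severity == "info", batch$notifier$records())
  expect_gte(length(infos), 4)
})

test_that("failures are isolated and reported, and do not disturb other samples", {
  tables <- orc_tables
  tables[["S02"]] <- event_table(tables[["S02"]]$values[1:50, ],
                                 sample_id = "S02",
                                 transform_tags = tables[["S02"]]$transform_tags)
  tables[["S03"]] <- NULL  # missing data entirely
  batch <- run_small_batch(tables = tables)
  expect_equal(unname(batch$status),
               c("done", "failed", "failed", "done"))
  errs <- Filter(function(r) r$severity == "error", batch$notifier$records())
  expect_length(errs, 2)
  expect_setequal(vapply(errs, `[[`, "", "sample"), c("S02", "S03"))
  expect_true(all(nzchar(vapply(errs, `[[`, "", "phase"))))

  # untouched samples give identical results to the clean run
  clean <- run_small_batch()
  expect_identical(batch$results[["S01"]]$gating$fit$achieved_fraction,
                   clean$results[["S01"]]$gating$fit$achieved_fraction)
  expect_identical(batch$results[["S04"]]$session$events_sorted,
                   clean$results[["S04"]]$session$events_sorted)
})

test_that("an empty worklist is rejected before any processing", {
  empty <- data.frame(name = character(), position = integer(), well = character())
  expect_error(run_batch(empty, list()), class = "sortgate_error_worklist")
})

test_that("error notifications always name sample and phase", {
  sink <- notifier_collect()
  expect_error(notify(sink, "error", "boom"),
               class = "sortgate_error_notification")
  notify(sink, "error", "boom", sample = "S01", phase = "sorting")
  notify(sink, "info", "fine")
  recs <- sink$records()
  expect_length(recs, 2)
  expect_equal(recs[[1]]$sample, "S01")
})

test_that("run controls follow the pause/resume/stop state machine", {
  ctl <- run_control()
  ctl <- control_transition(ctl, "pause")
  expect_equal(ctl$state, "paused")
  ctl <- control_transition(ctl, "resume")
  expect_equal(ctl$state, "running")
  ctl <- control_transition(ctl, "stop")
  expect_equal(ctl$state, "stopped")
  expect_error(control_transition(ctl, "resume"), class = "sortgate_error_state")
})

test_that("reports and summaries are written and deterministic", {
  report1 <- withr::local_tempfile(fileext = ".pdf")
  report2 <- withr::local_tempfile(fileext = ".pdf")
  sum1 <- withr::local_tempfile(fileext = ".json")
  sum2 <- withr::local_tempfile(fileext = ".json")
  b1 <- run_small_batch(report_path = report1, summary_path = sum1)
  b2 <- run_small_batch(report_path = report2, summary_path = sum2)

  # one header page + one panel per processed sample
  expect_equal(count_pdf_pages(report1), 1 + sum(b1$status == "done"))

  expect_identical(readBin(report1, "raw", file.info(report1)$size),
                   readBin(report2, "raw", file.info(report2)$size))
  expect_identical(readLines(sum1), readLines(sum2))

  js <- jsonlite::read_json(sum1)
  expect_length(js, 4)
  expect_equal(js[[1]]$name, "S01")
  expect_true(is.numeric(js[[1]]$achieved_fraction))
})

test_that("single-result reports render one sample panel", {
  batch <- run_batch(orc_worklist[1, , drop = FALSE], orc_tables["S01"],
                     n_profile = 4000, n_sort = 50, seed = 5)
  p <- withr::local_tempfile(fileext = ".pdf")
  render_report(batch, p)
  expect_equal(count_pdf_pages(p), 2)  # header + 1 panel
})

test_that("configuration files load with defaults and reject unknown fields", {
  cfg <- load_config(NULL)
  expect_s3_class(cfg$gating, "gate_config")
  expect_s3_class(cfg$instrument, "instrument_model")
  expect_equal(cfg$protocol$n_sort, 1200)

  p <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("gating:",
               "  target_fraction: 0.02",
               "instrument:",
               "  eps_target: 1500",
               "seed: 9"), p)
  cfg2 <- load_config(p)
  expect_equal(cfg2$gating$target_fraction, 0.02)
  expect_equal(cfg2$instrument$eps_target, 1500)
  expect_equal(cfg2$seed, 9L)

  bad <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("gating:", "  target_percent: 1"), bad)
  expect_error(load_config(bad), class = "sortgate_error_invalid_config")
})
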