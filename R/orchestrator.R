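#' Run a worklist-driven batch of samples
#'
#' Drives the per-sample state machine — pending, profiling, gating,
#' sorting, done/failed — over the entries of a worklist, in order. For
#' each sample: the first `n_profile` events of its table are profiled,
#' the density and the two shaping contours computed, the template gate
#' built and fitted, and a sorter session simulated on the full table.
#' Failures (missing sample, too few events, geometry errors) are isolated:
#' the sample is marked failed with an error notification and the batch
#' continues. Unconverged gates and sort shortfalls yield warning
#' notifications. An end-of-run PDF report and a machine-readable JSON
#' summary are written when paths are given.
#'
#' @param worklist a [parse_worklist()] result or data.frame with columns
#'   `name`, `position`, `well`; must be non-empty.
#' @param samples named list of [event_table()]s, one per worklist name.
#' @param axis an [axis_mapping()].
#' @param config a [gate_config()].
#' @param model an [instrument_model()].
#' @param n_profile,n_sort protocol counts for the per-sample [sort_plan()].
#' @param notifier a notification sink; defaults to an in-memory collector.
#' @param seed integer; sample `k` streams with seed `seed + k`.
#' @param concentrations optional named numeric vector of true
#'   concentrations (cells/mL) per sample; default 2e6 for all.
#' @param report_path optional path for the PDF report.
#' @param summary_path optional path for the JSON summary.
#' @param report_timestamps logical; `FALSE` makes report/summary bytes
#'   reproducible.
#' @return A list of class `batch_result`: `results` (per-sample records in
#'   worklist order), `status` (named character), `notifier`, and the
#'   report/summary paths.
#' @export
run_batch <- function(worklist, samples, axis = axis_mapping(),
                      config = gate_config(), model = instrument_model(),
                      n_profile = 10000, n_sort = 1200,
                      notifier = notifier_collect(), seed = 1L,
                      concentrations = NULL,
                      report_path = NULL, summary_path = NULL,
                      report_timestamps = FALSE) {
  if (is.null(worklist) || nrow(worklist) == 0L) {
    sg_stop("sortgate_error_worklist", "worklist is empty; nothing to process")
  }
  stopifnot(all(c("name", "position", "well") %in% names(worklist)))

  status <- stats::setNames(rep("pending", nrow(worklist)), worklist$name)
  results <- vector("list", nrow(worklist))
  names(results) <- worklist$name

  for (k in seq_len(nrow(worklist))) {
    name <- worklist$name[k]
    rec <- list(name = name, position = worklist$position[k],
                well = worklist$well[k])
    phase <- "load"
    out <- tryCatch({
      tab <- samples[[name]]
      if (is.null(tab)) {
        sg_stop("sortgate_error_missing_sample",
                sprintf("no event data supplied for sample '%s'", name))
      }
      phase <- "profiling"
      status[k] <- "profiling"
      n_prof <- min(n_profile, tab$n_events)
      profile <- event_table(tab$values[seq_len(n_prof), , drop = FALSE],
                             sample_id = tab$sample_id,
                             transform_tags = tab$transform_tags)
      phase <- "gating"
      status[k] <- "gating"
      gating <- auto_gate(profile, axis, config)
      if (!gating$fit$converged) {
        notify(notifier, "warning",
               sprintf("gate for '%s' did not reach the target fraction (achieved %.4f)",
                       name, gating$fit$achieved_fraction),
               sample = name, phase = "gating")
      }
      phase <- "sorting"
      status[k] <- "sorting"
      conc <- if (!is.null(concentrations) && name %in% names(concentrations)) {
        concentrations[[name]]
      } else 2e6
      plan <- sort_plan(gating$fit$gate, n_profile = n_prof, n_sort = n_sort)
      session <- run_session(tab, plan, model, seed = as.integer(seed) + k,
                             concentration = conc)
      if (!session$completed) {
        notify(notifier, "warning",
               sprintf("sample '%s' exhausted after %d of %d cells sorted",
                       name, session$events_sorted, n_sort),
               sample = name, phase = "sorting")
      }
      status[k] <- "done"
      notify(notifier, "info",
             sprintf("sample '%s' done: captured %.4f, sorted %d cells to %s",
                     name, gating$fit$achieved_fraction, session$events_sorted,
                     worklist$well[k]),
             sample = name, phase = "done")
      c(rec, list(status = "done", gating = gating, session = session))
    }, error = function(e) {
      status[k] <<- "failed"
      notify(notifier, "error",
             sprintf("sample '%s' failed during %s: %s", name, phase,
                     conditionMessage(e)),
             sample = name, phase = phase)
      c(rec, list(status = "failed", error = conditionMessage(e)))
    })
    results[[k]] <- out
  }

  batch <- structure(list(results = results, status = status,
                          notifier = notifier,
                          report_path = report_path,
                          summary_path = summary_path),
                     class = "batch_result")
  if (!is.null(summary_path)) write_run_summary(batch, summary_path)
  if (!is.null(report_path)) {
    render_report(batch, report_path, timestamps = report_timestamps)
  }
  batch
}

#' Write the machine-readable JSON summary of a batch
#'
#' One record per sample, in worklist order: identity, status, gate
#' geometry and fit metrics, and session outcome. Deterministic bytes for
#' identical inputs.
#'
#' @param batch a [run_batch()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(batch, path) {
  recs <- lapply(batch$results, function(r) {
    base <- list(name = r$name, position = r$position, well = r$well,
                 status = r$status)
    if (r$status != "done") {
      return(c(base, list(error = r$error %||% "")))
    }
    fit <- r$gating$fit
    c(base, list(
      achieved_fraction = fit$achieved_fraction,
      converged = fit$converged,
      translation = fit$translation,
      rotation = fit$rotation,
      n_vertices = fit$gate$n_vertices,
      events_profiled = r$session$events_profiled,
      events_sorted = r$session$events_sorted,
      completed = r$session$completed,
      estimated_concentration = r$session$estimated_concentration,
      phase_times = as.list(r$session$phase_times),
      total_time = r$session$total_time))
  })
  jsonlite::write_json(unname(recs), path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(path)
}

#' Pause/resume/stop state transitions of a run
#'
#' The interactive controls of a run are modelled as explicit state
#' transitions on a `run_control` object so they are testable without a
#' keyboard listener: `pause` suspends between samples, `resume` lifts the
#' pause, `stop` is terminal.
#'
#' @param control a `run_control` object (created with `run_control()`).
#' @param action one of `"pause"`, `"resume"`, `"stop"`.
#' @return The updated `run_control`.
#' @export
run_control <- function() {
  structure(list(state = "running"), class = "run_control")
}

#' @rdname run_control
#' @export
control_transition <- function(control, action = c("pause", "resume", "stop")) {
  action <- match.arg(action)
  if (control$state == "stopped") {
    sg_stop("sortgate_error_state", "a stopped run cannot change state")
  }
  control$state <- switch(action,
    pause = if (control$state == "running") "paused" else control$state,
    resume = if (control$state == "paused") "running" else control$state,
    stop = "stopped")
  control
}
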