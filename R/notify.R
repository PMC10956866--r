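#' Notification sinks
#'
#' The orchestrator reports run status through a pluggable notification
#' interface (the deployment analogue would post to an instant-messaging
#' channel; adapters are out of scope plug-ins). Two sinks ship with the
#' package: `notifier_collect()` accumulates notifications in memory (used
#' in tests and returned from [run_batch()]), `notifier_log()` appends
#' plain-text lines to a file or the console, optionally timestamped.
#'
#' Every notification has a severity (`info`, `warning`, `error`), a
#' message, and optionally the sample, phase and a figure attachment
#' reference. Error notifications must name the sample and phase.
#'
#' @param path log file path, or `NULL` for console output.
#' @param timestamps prepend wall-clock timestamps to log lines (disable
#'   for reproducible logs).
#' @return A notifier object with a `send(record)` function.
#' @export
notifier_collect <- function() {
  env <- new.env(parent = emptyenv())
  env$records <- list()
  structure(list(
    send = function(rec) env$records[[length(env$records) + 1L]] <- rec,
    records = function() env$records
  ), class = "sortgate_notifier")
}

#' @rdname notifier_collect
#' @export
notifier_log <- function(path = NULL, timestamps = TRUE) {
  structure(list(
    send = function(rec) {
      stamp <- if (timestamps) format(Sys.time(), "[%Y-%m-%d %H:%M:%S] ") else ""
      line <- sprintf("%s%s%s: %s", stamp, toupper(rec$severity),
                      if (!is.null(rec$sample)) paste0(" [", rec$sample,
                                                       if (!is.null(rec$phase)) paste0("/", rec$phase), "]")
                      else "",
                      rec$message)
      if (is.null(path)) message(line) else cat(line, "\n", sep = "", file = path, append = TRUE)
    },
    records = function() list()
  ), class = "sortgate_notifier")
}

#' Send a notification to a sink
#'
#' @param notifier a notifier from [notifier_collect()] or
#'   [notifier_log()].
#' @param severity one of `"info"`, `"warning"`, `"error"`.
#' @param message message text.
#' @param sample,phase sample name and run phase; mandatory for errors.
#' @param attachment optional figure reference (file path).
#' @return The notification record, invisibly.
#' @export
notify <- function(notifier, severity = c("info", "warning", "error"),
                   message, sample = NULL, phase = NULL, attachment = NULL) {
  severity <- match.arg(severity)
  if (severity == "error" && (is.null(sample) || is.null(phase))) {
    sg_stop("sortgate_error_notification",
            "error notifications must name the sample and phase")
  }
  rec <- list(severity = severity, message = message, sample = sample,
              phase = phase, attachment = attachment)
  notifier$send(rec)
  invisible(rec)
}
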