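#' Read or write event tables in the package CSV dialect
#'
#' The dialect is fixed to avoid locale drift: comma-separated, `.` decimal
#' mark, UTF-8, a mandatory header row of channel names, one row per event,
#' numeric cells only. `write_events_csv` followed by `read_events_csv` is
#' the identity up to floating-point text round-trip (values are written
#' with 17 significant digits, so doubles round-trip exactly).
#'
#' The CSV carries no metadata: the sample id defaults to the file name and
#' transform tags default to linear unless supplied.
#'
#' @param path file path.
#' @param sample_id sample identity for the returned table; defaults to the
#'   file base name.
#' @param transform_tags optional named character vector of per-channel tags.
#' @return `read_events_csv`: an [event_table()]; `write_events_csv`: `path`,
#'   invisibly.
#' @export
read_events_csv <- function(path, sample_id = NULL, transform_tags = NULL) {
  if (!file.exists(path)) {
    sg_stop("sortgate_error_io", sprintf("CSV file not found: %s", path))
  }
  dt <- data.table::fread(path, sep = ",", dec = ".", header = TRUE,
                          colClasses = "character", data.table = FALSE,
                          encoding = "UTF-8")
  ch <- names(dt)
  if (nrow(dt) == 0L) {
    m <- matrix(numeric(0), ncol = length(ch), dimnames = list(NULL, ch))
  } else {
    m <- matrix(NA_real_, nrow = nrow(dt), ncol = length(ch), dimnames = list(NULL, ch))
    for (j in seq_along(ch)) {
      v <- suppressWarnings(as.numeric(dt[[j]]))
      bad <- which(is.na(v) & !(dt[[j]] %in% c("NA", "NaN", "Inf", "-Inf", "")))
      if (length(bad)) {
        sg_stop("sortgate_error_csv_parse",
                sprintf("non-numeric cell '%s' at row %d, column '%s'",
                        dt[[j]][bad[1]], bad[1], ch[j]))
      }
      na_like <- which(dt[[j]] %in% c("NA", ""))
      v[na_like] <- NA_real_
      inf <- which(dt[[j]] == "Inf"); v[inf] <- Inf
      ninf <- which(dt[[j]] == "-Inf"); v[ninf] <- -Inf
      nan <- which(dt[[j]] == "NaN"); v[nan] <- NaN
      m[, j] <- v
    }
  }
  event_table(m,
              sample_id = sample_id %||% tools::file_path_sans_ext(basename(path)),
              transform_tags = transform_tags)
}

#' @param table an [event_table()].
#' @rdname read_events_csv
#' @export
write_events_csv <- function(table, path) {
  stopifnot(inherits(table, "event_table"))
  con <- file(path, "wb")  # binary mode: LF endings on every platform
  on.exit(close(con))
  writeLines(paste(table$channels, collapse = ","), con)
  if (table$n_events > 0L) {
    cols <- lapply(seq_along(table$channels),
                   function(j) sprintf("%.17g", table$values[, j]))
    writeLines(do.call(paste, c(cols, sep = ",")), con)
  }
  invisible(path)
}
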