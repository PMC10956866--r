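#' Per-event measurement table for one cytometry sample
#'
#' The central container of the package: a matrix of per-event channel
#' measurements together with the sample identity and a per-channel record of
#' the scale the values live on (`"linear"`, `"log10"` or `"asinh"`). Gating
#' operates on two of these channels — one fluorescence and one back-scatter
#' axis — selected by an [axis_mapping()].
#'
#' Rows containing any non-finite value (instrument saturation, parse
#' artifacts) are dropped at construction time with a message, because all
#' downstream geometry requires finite coordinates.
#'
#' @param values numeric matrix, one row per event, with channel names as
#'   column names (unique, non-empty).
#' @param sample_id character scalar identifying the sample.
#' @param transform_tags named character vector giving the scale of each
#'   channel; missing channels default to `"linear"`.
#' @return An object of class `event_table` with fields `sample_id`,
#'   `n_events`, `channels`, `values` and `transform_tags`.
#' @export
#' @examples
#' m <- cbind(FL1 = c(1, 2, 3), BSC = c(10, 20, 30))
#' tab <- event_table(m, sample_id = "demo")
#' tab$n_events
event_table <- function(values, sample_id = "sample", transform_tags = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    sg_stop("sortgate_error_invalid_table", "`values` must be a numeric matrix")
  }
  ch <- colnames(values)
  if (is.null(ch) || anyNA(ch) || any(!nzchar(ch))) {
    sg_stop("sortgate_error_invalid_table", "`values` must have channel names as column names")
  }
  if (anyDuplicated(ch)) {
    sg_stop("sortgate_error_invalid_table",
            sprintf("duplicate channel name: %s", ch[duplicated(ch)][1]))
  }
  bad <- !is.finite(values)
  if (any(bad)) {
    drop <- rowSums(bad) > 0L
    message(sprintf("event_table: dropped %d event(s) with non-finite values", sum(drop)))
    values <- values[!drop, , drop = FALSE]
  }
  tags <- rep("linear", length(ch))
  names(tags) <- ch
  if (!is.null(transform_tags)) {
    unknown <- setdiff(names(transform_tags), ch)
    if (length(unknown)) {
      sg_stop("sortgate_error_invalid_table",
              sprintf("transform tag for unknown channel: %s", unknown[1]))
    }
    bad_tag <- setdiff(unique(transform_tags), c("linear", "log10", "asinh"))
    if (length(bad_tag)) {
      sg_stop("sortgate_error_invalid_table",
              sprintf("unknown transform tag: %s", bad_tag[1]))
    }
    tags[names(transform_tags)] <- transform_tags
  }
  structure(
    list(sample_id = as.character(sample_id)[1],
         n_events = nrow(values),
         channels = ch,
         values = values,
         transform_tags = tags),
    class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> sample '%s': %d events x %d channels\n",
              x$sample_id, x$n_events, length(x$channels)))
  cat("  channels:", paste(sprintf("%s [%s]", x$channels, x$transform_tags), collapse = ", "), "\n")
  invisible(x)
}

#' Map instrument channels to the two gating axes
#'
#' @param fluorescence name of the fluorescence channel (gate x axis).
#' @param backscatter name of the back-scatter channel (gate y axis).
#' @return An object of class `axis_mapping`.
#' @export
axis_mapping <- function(fluorescence = "FL1", backscatter = "BSC") {
  stopifnot(is.character(fluorescence), length(fluorescence) == 1L,
            is.character(backscatter), length(backscatter) == 1L)
  if (fluorescence == backscatter) {
    sg_stop("sortgate_error_invalid_axis", "fluorescence and back-scatter channels must differ")
  }
  structure(list(fluorescence = fluorescence, backscatter = backscatter),
            class = "axis_mapping")
}

# Check the mapping against a table and return the n x 2 matrix of
# (fluorescence, back-scatter) coordinates.
axis_values <- function(table, axis) {
  stopifnot(inherits(table, "event_table"), inherits(axis, "axis_mapping"))
  missing <- setdiff(c(axis$fluorescence, axis$backscatter), table$channels)
  if (length(missing)) {
    sg_stop("sortgate_error_invalid_axis",
            sprintf("channel '%s' not present in sample '%s'", missing[1], table$sample_id))
  }
  cbind(x = table$values[, axis$fluorescence],
        y = table$values[, axis$backscatter])
}

axis_tags <- function(table, axis) {
  c(fluorescence = unname(table$transform_tags[axis$fluorescence]),
    backscatter = unname(table$transform_tags[axis$backscatter]))
}
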