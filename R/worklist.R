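#' The 96 valid destination-well labels
#'
#' Rows A-H crossed with columns 1-12, in row-major plate order.
#'
#' @return Character vector of length 96 (`"A1"` ... `"H12"`).
#' @export
valid_wells <- function() {
  as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
}

#' Parse and validate a worklist file
#'
#' The worklist prescribes one batch: sample names, positions in the
#' 18-tube housing and destination wells of the 96-well rescue plate. CSV
#' with a mandatory header of columns `name`, `position`, `well`; entries
#' are returned in file order.
#'
#' Rejected with a classed error: positions outside 1-18
#' (`sortgate_error_capacity`), invalid well labels
#' (`sortgate_error_well`), duplicate names, positions or wells
#' (`sortgate_error_duplicate`), and empty names.
#'
#' @param path worklist CSV path.
#' @return A data.frame with columns `name`, `position` (integer), `well`,
#'   of class `worklist`.
#' @export
parse_worklist <- function(path) {
  if (!file.exists(path)) {
    sg_stop("sortgate_error_io", sprintf("worklist file not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("name", "position", "well")
  if (!all(need %in% names(df))) {
    sg_stop("sortgate_error_worklist",
            sprintf("worklist must have columns %s", paste(need, collapse = ", ")))
  }
  df <- df[, need]
  if (nrow(df)) {
    pos_num <- suppressWarnings(as.numeric(df$position))
    if (anyNA(pos_num) || any(pos_num != round(pos_num))) {
      sg_stop("sortgate_error_worklist", "tube positions must be integers")
    }
    if (any(pos_num < 1 | pos_num > 18)) {
      bad <- df$position[which(pos_num < 1 | pos_num > 18)[1]]
      sg_stop("sortgate_error_capacity",
              sprintf("tube position %s outside the 18-tube housing capacity", bad))
    }
    df$position <- as.integer(pos_num)
    bad_well <- setdiff(df$well, valid_wells())
    if (length(bad_well)) {
      sg_stop("sortgate_error_well",
              sprintf("invalid destination well '%s' (valid: A1-H12)", bad_well[1]))
    }
    if (any(!nzchar(trimws(df$name)))) {
      sg_stop("sortgate_error_worklist", "sample names must be non-empty")
    }
    for (col in c("name", "position", "well")) {
      if (anyDuplicated(df[[col]])) {
        sg_stop("sortgate_error_duplicate",
                sprintf("duplicate %s in worklist: %s",
                        col, df[[col]][duplicated(df[[col]])][1]))
      }
    }
  }
  class(df) <- c("worklist", "data.frame")
  df
}

#' Write a worklist data.frame to CSV
#'
#' @param worklist data.frame with columns `name`, `position`, `well`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_worklist <- function(worklist, path) {
  utils::write.csv(worklist[, c("name", "position", "well")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
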