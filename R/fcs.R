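#' Read a flow-cytometry standard (FCS 3.0/3.1) file
#'
#' Minimal list-mode FCS reader covering the subset this package writes and
#' the common instrument-export case: a single dataset, `$MODE L`, float
#' (`$DATATYPE F`) or double (`$DATATYPE D`) storage, little- or big-endian.
#' All parameters become channels. Channels declared with log amplification
#' (`$PnE` with a positive first field) are tagged `"log10"`; a custom
#' `PnTRANSFORM` keyword written by [write_fcs()] overrides the tag. Events
#' with non-finite values are dropped with a message.
#'
#' Keyword preservation beyond channel structure, spillover/compensation and
#' multi-dataset files are out of scope.
#'
#' @param path path to an FCS file.
#' @return An [event_table()].
#' @export
read_fcs <- function(path) {
  if (!file.exists(path)) {
    sg_stop("sortgate_error_io", sprintf("FCS file not found: %s", path))
  }
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 58L) {
    sg_stop("sortgate_error_fcs_format",
            sprintf("truncated FCS HEADER segment in %s", path))
  }
  version <- rawToChar(raw[1:6])
  if (!startsWith(version, "FCS3.")) {
    sg_stop("sortgate_error_fcs_format",
            sprintf("HEADER segment: unsupported FCS version '%s' (need FCS 3.0/3.1)", version))
  }
  off <- function(a, b) {
    s <- trimws(rawToChar(raw[a:b]))
    if (!grepl("^[0-9]*$", s)) {
      sg_stop("sortgate_error_fcs_format", "HEADER segment: non-numeric offset field")
    }
    if (s == "") 0 else as.numeric(s)
  }
  # FCS offsets are 0-based byte positions of the first and last byte
  tb <- off(11, 18); te <- off(19, 26)
  db <- off(27, 34); de <- off(35, 42)
  if (tb <= 0 || te < tb || te + 1 > length(raw)) {
    sg_stop("sortgate_error_fcs_format", "HEADER segment: invalid TEXT offsets")
  }

  text <- rawToChar(raw[(tb + 1):(te + 1)])
  delim <- substr(text, 1, 1)
  parts <- strsplit(text, delim, fixed = TRUE)[[1]][-1]
  parts <- parts[!(seq_along(parts) == length(parts) & parts == "")]
  if (length(parts) < 2L || length(parts) %% 2L != 0L) {
    sg_stop("sortgate_error_fcs_format", "TEXT segment: malformed keyword/value pairs")
  }
  keys <- parts[seq(1, length(parts), by = 2)]
  vals <- parts[seq(2, length(parts), by = 2)]
  keys <- ifelse(startsWith(keys, "$"), toupper(keys), keys)
  kw <- stats::setNames(as.list(vals), keys)
  need <- function(k) {
    if (is.null(kw[[k]])) {
      sg_stop("sortgate_error_fcs_format", sprintf("TEXT segment: required keyword %s missing", k))
    }
    kw[[k]]
  }

  mode <- need("$MODE")
  if (mode != "L") {
    sg_stop("sortgate_error_fcs_format", sprintf("TEXT segment: unsupported $MODE '%s'", mode))
  }
  dtype <- need("$DATATYPE")
  size <- switch(dtype, F = 4L, D = 8L,
                 sg_stop("sortgate_error_fcs_format",
                         sprintf("TEXT segment: unsupported $DATATYPE '%s'", dtype)))
  endian <- switch(need("$BYTEORD"),
                   "1,2,3,4" = "little", "4,3,2,1" = "big",
                   sg_stop("sortgate_error_fcs_format", "TEXT segment: unsupported $BYTEORD"))
  npar <- as.integer(need("$PAR"))
  ntot <- as.integer(need("$TOT"))
  if (is.na(npar) || npar < 1L || is.na(ntot) || ntot < 0L) {
    sg_stop("sortgate_error_fcs_format", "TEXT segment: invalid $PAR/$TOT")
  }

  if (db == 0) db <- as.numeric(need("$BEGINDATA"))
  if (de == 0) de <- as.numeric(need("$ENDDATA"))
  nbytes <- npar * ntot * size
  if (ntot > 0L && (db <= 0 || de - db + 1 != nbytes || de + 1 > length(raw))) {
    sg_stop("sortgate_error_fcs_format",
            sprintf("DATA segment: expected %d bytes, file has %d usable", nbytes,
                    max(0, length(raw) - db)))
  }

  chans <- character(npar)
  tags <- character(npar)
  for (i in seq_len(npar)) {
    chans[i] <- need(sprintf("$P%dN", i))
    tag <- kw[[sprintf("P%dTRANSFORM", i)]]
    if (is.null(tag)) {
      pne <- kw[[sprintf("$P%dE", i)]]
      decades <- if (is.null(pne)) 0 else suppressWarnings(as.numeric(strsplit(pne, ",")[[1]][1]))
      tag <- if (isTRUE(decades > 0)) "log10" else "linear"
    }
    tags[i] <- tag
  }

  values <- if (ntot > 0L) {
    matrix(readBin(raw[(db + 1):(de + 1)], "double", n = npar * ntot, size = size, endian = endian),
           ncol = npar, byrow = TRUE)
  } else {
    matrix(numeric(0), ncol = npar)
  }
  colnames(values) <- chans
  event_table(values,
              sample_id = kw[["$SRC"]] %||% tools::file_path_sans_ext(basename(path)),
              transform_tags = stats::setNames(tags, chans))
}

#' Write an event table as a minimal FCS 3.1 file
#'
#' Writes a single-dataset list-mode file with `$DATATYPE D` (64-bit floats,
#' so numeric round-trips are exact), little-endian byte order, the sample id
#' in `$SRC`, and a custom `PnTRANSFORM` keyword per channel recording the
#' transform tag. [read_fcs()] of the result reproduces the table.
#'
#' @param table an [event_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(table, path) {
  stopifnot(inherits(table, "event_table"))
  if (any(grepl("/", table$channels, fixed = TRUE))) {
    sg_stop("sortgate_error_io", "channel names may not contain '/' in FCS output")
  }
  npar <- length(table$channels)
  ntot <- table$n_events
  text_begin <- 256L
  nbytes <- npar * ntot * 8L

  kv <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$BEGINDATA", "@BD@", "$ENDDATA", "@ED@",
          "$BYTEORD", "1,2,3,4", "$DATATYPE", "D", "$MODE", "L",
          "$NEXTDATA", "0",
          "$PAR", as.character(npar), "$TOT", as.character(ntot),
          "$SRC", table$sample_id)
  for (i in seq_len(npar)) {
    rng <- if (ntot > 0) max(abs(table$values[, i]), 1) else 1
    kv <- c(kv,
            sprintf("$P%dN", i), table$channels[i],
            sprintf("$P%dB", i), "64",
            sprintf("$P%dE", i), "0,0",
            sprintf("$P%dR", i), sprintf("%.6g", rng),
            sprintf("P%dTRANSFORM", i), unname(table$transform_tags[i]))
  }
  if (any(grepl("/", kv, fixed = TRUE))) {
    sg_stop("sortgate_error_io", "keyword values may not contain the '/' delimiter")
  }
  make_text <- function(bd, ed) {
    paste0("/", paste(sub("@ED@", ed, sub("@BD@", bd, kv), fixed = TRUE),
                      collapse = "/"), "/")
  }
  # fixed-width offsets keep the TEXT length independent of their value
  text <- make_text(sprintf("%010d", 0), sprintf("%010d", 0))
  text_end <- text_begin + nchar(text) - 1L
  data_begin <- text_end + 1L
  data_end <- data_begin + nbytes - 1L  # data_begin - 1 when empty
  text <- make_text(sprintf("%010d", if (ntot > 0) data_begin else 0),
                    sprintf("%010d", if (ntot > 0) data_end else 0))

  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    text_begin, text_end,
                    if (ntot > 0) data_begin else 0,
                    if (ntot > 0) data_end else 0, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(strrep(" ", text_begin - nchar(header)), con, eos = NULL)
  writeChar(text, con, eos = NULL)
  if (ntot > 0) {
    writeBin(as.vector(t(table$values)), con, size = 8L, endian = "little")
  }
  invisible(path)
}
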