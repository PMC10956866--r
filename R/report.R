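#' Render the end-of-run PDF report
#'
#' One header page with the batch table (sample, tube, well, status,
#' captured fraction, cells sorted), then one page per processed sample
#' showing the density contours of its profile with the fitted gate
#' overlaid and the fit/sort figures annotated. Layout is deterministic
#' given the inputs; with `timestamps = FALSE` the PDF's embedded
#' creation/modification dates are neutralised so regenerated reports are
#' byte-identical.
#'
#' @param batch a [run_batch()] result (at least one sample record).
#' @param path output PDF path.
#' @param timestamps keep the PDF timestamps (default `FALSE`).
#' @return `path`, invisibly.
#' @export
render_report <- function(batch, path, timestamps = FALSE) {
  results <- batch$results
  if (!length(results)) {
    sg_stop("sortgate_error_report", "nothing to report: no sample results")
  }
  ok <- tryCatch({
    pdf(path, width = 7.5, height = 6, onefile = TRUE, useDingbats = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) sg_stop("sortgate_error_io", sprintf("cannot open report file: %s", path))
  on.exit(if (names(grDevices::dev.cur()) == "pdf") dev.off(), add = TRUE)

  # header page
  op <- par(mar = c(1, 1, 3, 1))
  plot.new()
  title(main = "Sorting run summary", adj = 0)
  hdr <- c("sample", "tube", "well", "status", "captured", "sorted")
  rows <- lapply(results, function(r) {
    if (r$status == "done") {
      c(r$name, r$position, r$well, r$status,
        sprintf("%.4f", r$gating$fit$achieved_fraction),
        r$session$events_sorted)
    } else {
      c(r$name, r$position, r$well, r$status, "-", "-")
    }
  })
  tab <- rbind(hdr, do.call(rbind, rows))
  nshow <- nrow(tab)
  xcol <- seq(0.02, 0.98, length.out = ncol(tab))
  yrow <- seq(0.95, max(0.05, 0.95 - 0.05 * (nshow - 1)), length.out = nshow)
  for (i in seq_len(nshow)) {
    text(xcol, yrow[i], tab[i, ], adj = 0, cex = if (i == 1) 0.9 else 0.8,
         font = if (i == 1) 2 else 1)
  }
  par(op)

  # one panel per processed sample
  for (r in results) {
    if (r$status != "done") next
    g <- r$gating
    grid <- g$density
    plot(NA, xlim = range(grid$x_mids), ylim = range(grid$y_mids),
         xlab = sprintf("%s (%s)", grid$axis$fluorescence,
                        grid$transform_tags[["fluorescence"]]),
         ylab = sprintf("%s (%s)", grid$axis$backscatter,
                        grid$transform_tags[["backscatter"]]),
         main = r$name)
    levs <- sort(unique(c(g$contour_height$threshold, g$contour_side$threshold)))
    cl <- contourLines(grid$x_mids, grid$y_mids, grid$mass, levels = levs)
    for (line in cl) lines(line$x, line$y, col = "grey40")
    gv <- g$fit$gate$vertices
    lines(gv[, 1], gv[, 2], col = "red", lwd = 2)
    mtext(sprintf("captured %.4f  |  sorted %d cells  |  %s",
                  g$fit$achieved_fraction, r$session$events_sorted,
                  if (r$session$completed) "completed" else "shortfall"),
          side = 3, cex = 0.8)
  }
  dev.off()
  if (!timestamps) strip_pdf_timestamps(path)
  invisible(path)
}

# Overwrite the digits of /CreationDate and /ModDate entries with zeros of
# equal byte length, keeping the xref offsets valid. Works on raw bytes so
# binary stream content cannot break the rewrite.
strip_pdf_timestamps <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  digits <- charToRaw("0123456789")
  for (key in c("/CreationDate (D:", "/ModDate (D:")) {
    pat <- charToRaw(key)
    np <- length(pat)
    hits <- which(raw == pat[1])
    for (h in hits) {
      if (h + np - 1L > length(raw)) next
      if (!all(raw[h:(h + np - 1L)] == pat)) next
      i <- h + np
      while (i <= length(raw) && raw[i] %in% digits) {
        raw[i] <- charToRaw("0")
        i <- i + 1L
      }
    }
  }
  writeBin(raw, path)
  invisible(path)
}
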