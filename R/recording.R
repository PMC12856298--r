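#' Multichannel hemodynamic recording container
#'
#' @description
#' `hemo_recording()` bundles a uniformly sampled multichannel physiologic
#' recording: a time grid, named channels with declared units, the sampling
#' rate and free-form metadata (animal, group, ground-truth block for
#' synthetic data). All analysis functions consume this container.
#'
#' @param data data.frame with a `time` column (seconds, uniform grid) and one
#'   column per channel.
#' @param units named character vector, one unit per non-time column.
#' @param fs sampling rate, Hz.
#' @param meta list of metadata (may include a `truth` block for synthetic
#'   recordings).
#' @return An object of class `hemo_recording`.
#' @export
hemo_recording <- function(data, units, fs, meta = list()) {
  stopifnot(is.data.frame(data), "time" %in% names(data))
  chans <- setdiff(names(data), "time")
  missing_units <- setdiff(chans, names(units))
  if (length(missing_units))
    stop("unit-less channel(s): ", paste(missing_units, collapse = ", "),
         call. = FALSE)
  if (nrow(data) > 1) {
    dt <- diff(data$time)
    jitter <- max(abs(dt - 1 / fs))
    if (jitter > 0.1 / fs)
      stop(sprintf("non-uniform time grid: max jitter %.3g s exceeds 0.1/fs",
                   jitter), call. = FALSE)
  }
  structure(list(data = data, units = units[chans], fs = fs, meta = meta),
            class = "hemo_recording")
}

#' @export
print.hemo_recording <- function(x, ...) {
  chans <- setdiff(names(x$data), "time")
  cat(sprintf("<hemo_recording: %d samples @ %g Hz (%.2f s)>\n",
              nrow(x$data), x$fs, nrow(x$data) / x$fs))
  cat("  channels:",
      paste(sprintf("%s [%s]", chans, x$units[chans]), collapse = ", "), "\n")
  if (!is.null(x$meta$preset))
    cat("  synthetic preset:", x$meta$preset, "\n")
  invisible(x)
}

#' Write a recording as tab-separated text plus a JSON metadata sidecar
#'
#' The data file has two header lines (channel names, then units) followed by
#' the sample matrix; the sidecar (`<path>.json`) carries the sampling rate,
#' channel units and any metadata, including the synthetic ground-truth block.
#'
#' @param rec a [hemo_recording].
#' @param path path of the `.tsv` data file to write; the sidecar is written
#'   next to it with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "hemo_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  cols <- names(rec$data)
  units <- c(time = "s", rec$units)[cols]
  writeLines(paste(cols, collapse = "\t"), con)
  writeLines(paste(units, collapse = "\t"), con)
  utils::write.table(format(rec$data, digits = 10, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  side <- c(list(fs = rec$fs, units = as.list(units)), rec$meta)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)

#' Read a recording written by [write_recording()]
#'
#' @param path path to the `.tsv` data file; a `.json` sidecar is read if
#'   present (required for the sampling rate unless it can be inferred from
#'   the time column).
#' @return A [hemo_recording].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  hdr <- readLines(path, n = 2)
  cols <- strsplit(hdr[1], "\t")[[1]]
  units <- strsplit(hdr[2], "\t")[[1]]
  if (length(units) != length(cols))
    stop("header must declare one unit per channel", call. = FALSE)
  if (!"time" %in% cols) stop("recording lacks a time column", call. = FALSE)
  dat <- utils::read.table(path, sep = "\t", skip = 2, header = FALSE,
                           col.names = cols, check.names = FALSE)
  names(units) <- cols
  meta <- list()
  fs <- NULL
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    side <- jsonlite::read_json(sp, simplifyVector = TRUE)
    fs <- side$fs
    meta <- side[setdiff(names(side), c("fs", "units"))]
  }
  if (is.null(fs)) fs <- 1 / stats::median(diff(dat$time))
  # reject recordings with dropped-sample runs longer than 5 ms
  if (nrow(dat) > 1 && max(diff(dat$time)) > 1 / fs + 0.005)
    stop("missing-sample run exceeds 5 ms", call. = FALSE)
  hemo_recording(dat, units[setdiff(cols, "time")], fs = fs, meta = meta)
}
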