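#' Read a multi-channel EEG recording
#'
#' Supports delimited text (CSV/TSV: one header row of channel labels, one
#' column per channel, one row per sample) and EDF/BDF containers. For
#' delimited text the sampling rate must come from the `sampling_rate`
#' argument or from a JSON sidecar `<path>.json` with a `sampling_rate`
#' field; EDF/BDF carry it in the header (all channels must share one rate).
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"`, `"edf"` or
#'   `"bdf"`.
#' @param sampling_rate Sampling rate in Hz (required for delimited text
#'   without a sidecar).
#' @return An `eeg_recording`: `data` (samples x channels matrix),
#'   `channels`, `sampling_rate`, `source`, `format`.
#' @export
read_recording <- function(path, format = c("auto", "csv", "tsv", "edf", "bdf"),
                           sampling_rate = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     csv = "csv", tsv = "tsv", txt = "csv",
                     edf = "edf", bdf = "bdf",
                     stop("cannot infer format from extension '.", ext,
                          "'; pass `format`"))
  }
  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "tsv") "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE)
    if (is.null(sampling_rate)) {
      sidecar <- paste0(path, ".json")
      if (file.exists(sidecar)) {
        meta <- jsonlite::read_json(sidecar)
        sampling_rate <- meta$sampling_rate
      }
    }
    if (is.null(sampling_rate))
      stop("`sampling_rate` is required for delimited text (or provide ",
           path, ".json with a sampling_rate field)")
    structure(
      list(data = as.matrix(df),
           channels = colnames(df),
           sampling_rate = as.numeric(sampling_rate),
           source = path, format = format),
      class = "eeg_recording")
  } else {
    .read_edf(path, bdf = format == "bdf")
  }
}

# Minimal EDF/BDF reader: fixed-width ASCII header plus little-endian
# 16-bit (EDF) or 24-bit (BDF) integer data records.
.read_edf <- function(path, bdf = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nc) readChar(con, nc, useBytes = TRUE)
  ver <- readBin(con, "raw", 8)
  if (bdf && ver[1] != as.raw(255))
    stop("not a BDF file: ", path)
  rd(80); rd(80); rd(8); rd(8) # patient, recording, date, time
  rd(8) # header bytes
  rd(44)
  n_records <- as.integer(rd(8))
  duration <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), character(1)))
  for (i in seq_len(ns)) rd(80) # transducer
  for (i in seq_len(ns)) rd(8) # physical dimension
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80) # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)

  rates <- spr / duration
  if (length(unique(rates)) > 1)
    stop("channels have mismatched sampling rates: ",
         paste(unique(rates), collapse = ", "))

  data <- matrix(0, nrow = n_records * spr[1], ncol = ns)
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      dig <- if (bdf) {
        raw3 <- readBin(con, "raw", 3L * spr[s])
        b <- matrix(as.integer(raw3), nrow = 3)
        v <- b[1, ] + 256L * b[2, ] + 65536L * b[3, ]
        ifelse(v >= 2^23, v - 2^24, v)
      } else {
        readBin(con, "integer", spr[s], size = 2, signed = TRUE,
                endian = "little")
      }
      phys <- pmin[s] + (dig - dmin[s]) * (pmax[s] - pmin[s]) / (dmax[s] - dmin[s])
      data[((r - 1L) * spr[s] + 1L):(r * spr[s]), s] <- phys
    }
  }
  structure(
    list(data = data, channels = labels, sampling_rate = rates[1],
         source = path, format = if (bdf) "bdf" else "edf"),
    class = "eeg_recording")
}

#' Write a recording to CSV or EDF
#'
#' CSV keeps full numeric precision; EDF quantises each channel to 16 bits
#' over a symmetric physical range covering its data. A JSON sidecar with
#' the sampling rate accompanies CSV output so it can be read back without
#' extra arguments.
#'
#' @param x An `eeg_recording`, or a numeric matrix/vector of samples.
#' @param path Output path.
#' @param sampling_rate Required when `x` is not an `eeg_recording`.
#' @param channels Channel labels (defaults to those in `x` or `V1..Vn`).
#' @param format `"auto"` (by extension), `"csv"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(x, path, sampling_rate = NULL, channels = NULL,
                            format = c("auto", "csv", "edf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", edf = "edf",
                     stop("cannot infer output format; pass `format`"))
  if (inherits(x, "eeg_recording")) {
    data <- x$data
    if (is.null(sampling_rate)) sampling_rate <- x$sampling_rate
    if (is.null(channels)) channels <- x$channels
  } else {
    data <- as.matrix(x)
  }
  if (is.null(sampling_rate)) stop("`sampling_rate` is required")
  if (is.null(channels)) channels <- colnames(data)
  if (is.null(channels)) channels <- paste0("V", seq_len(ncol(data)))
  colnames(data) <- channels

  if (format == "csv") {
    utils::write.csv(as.data.frame(data), path, row.names = FALSE)
    jsonlite::write_json(list(sampling_rate = sampling_rate),
                         paste0(path, ".json"), auto_unbox = TRUE)
  } else {
    .write_edf(data, sampling_rate, path)
  }
  invisible(path)
}

.write_edf <- function(data, sampling_rate, path) {
  ns <- ncol(data)
  n <- nrow(data)
  duration <- n / sampling_rate
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) {
    s <- formatC(as.character(x), width = width, flag = "-")
    writeChar(substr(s, 1, width), con, eos = NULL)
  }
  amax <- vapply(seq_len(ns), function(s) {
    m <- max(abs(data[, s]), 1e-6)
    signif(m * 1.01, 6)
  }, numeric(1))

  wr("0", 8) # version
  wr("synthetic", 80)
  wr("wavescrub export", 80)
  wr(format(Sys.Date(), "%d.%m.%y"), 8)
  wr("00.00.00", 8)
  wr(256 + ns * 256, 8)
  wr("", 44)
  wr(1, 8) # one data record holding the whole signal
  wr(format(duration, digits = 7), 8)
  wr(ns, 4)
  for (s in seq_len(ns)) wr(colnames(data)[s], 16)
  for (s in seq_len(ns)) wr("", 80)
  for (s in seq_len(ns)) wr("uV", 8)
  for (s in seq_len(ns)) wr(format(-amax[s], digits = 6), 8)
  for (s in seq_len(ns)) wr(format(amax[s], digits = 6), 8)
  for (s in seq_len(ns)) wr(-32768, 8)
  for (s in seq_len(ns)) wr(32767, 8)
  for (s in seq_len(ns)) wr("", 80)
  for (s in seq_len(ns)) wr(n, 8)
  for (s in seq_len(ns)) wr("", 32)
  for (s in seq_len(ns)) {
    dig <- round((data[, s] + amax[s]) / (2 * amax[s]) * 65535) - 32768
    dig <- pmin(pmax(dig, -32768), 32767)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Anomaly intervals of a run as a table
#'
#' One row per contiguous run of mitigated coefficient columns, with 0-based
#' half-open sample intervals in recording coordinates, the number of
#' columns actually flagged (before expansion) inside the run, and the
#' maximum anomaly score.
#'
#' @param run A [denoise_stream()] result.
#' @return Data frame: `window_index`, `start_sample`, `end_sample`,
#'   `n_flagged_columns`, `max_score`.
#' @export
anomaly_intervals <- function(run) {
  stopifnot(inherits(run, "denoise_run"))
  spw <- run$config$samples_per_window
  rows <- list()
  for (r in run$reports) {
    if (length(r$at_exp) == 0) next
    runs <- split(r$at_exp, cumsum(c(1, diff(r$at_exp) != 1)))
    for (rr in runs) {
      rows[[length(rows) + 1L]] <- data.frame(
        window_index = r$window_index,
        start_sample = r$window_index * spw + 2L * (min(rr) - 1L),
        end_sample = r$window_index * spw + 2L * max(rr),
        n_flagged_columns = sum(r$at %in% rr),
        max_score = max(r$scores[rr]))
    }
  }
  if (length(rows) == 0)
    return(data.frame(window_index = integer(0), start_sample = integer(0),
                      end_sample = integer(0), n_flagged_columns = integer(0),
                      max_score = numeric(0)))
  do.call(rbind, rows)
}

#' Write the artefacts of a denoising run to a directory
#'
#' Emits the denoised signal (`denoised.csv` plus sampling-rate sidecar),
#' the anomaly interval table (`intervals.tsv`), the fully resolved
#' configuration (`config.json`, enabling exact replay) and a per-window
#' latency log (`run_log.txt`).
#'
#' @param run A [denoise_stream()] result.
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_outputs <- function(run, out_dir) {
  stopifnot(inherits(run, "denoise_run"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    denoised = file.path(out_dir, "denoised.csv"),
    intervals = file.path(out_dir, "intervals.tsv"),
    config = file.path(out_dir, "config.json"),
    log = file.path(out_dir, "run_log.txt"))

  m <- matrix(run$denoised, ncol = 1)
  colnames(m) <- run$channel_label
  write_recording(m, paths[["denoised"]],
                  sampling_rate = run$config$sampling_rate, format = "csv")
  utils::write.table(anomaly_intervals(run), paths[["intervals"]],
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(unclass(run$config), paths[["config"]],
                       auto_unbox = TRUE, null = "null", digits = NA)
  lines <- c(
    sprintf("windows: %d; modified: %d; dropped trailing samples: %d",
            run$n_windows, sum(run$modified), run$dropped_samples),
    sprintf("mean latency: %.1f ms (budget %g ms); exceeded in %d windows",
            mean(run$latency_ms), run$config$window_ms,
            sum(run$latency_ms > run$config$window_ms)),
    sprintf("window %d: %.1f ms%s", seq_len(run$n_windows) - 1L,
            run$latency_ms,
            ifelse(run$modified, " [modified]", "")))
  writeLines(lines, paths[["log"]])
  invisible(paths)
}
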