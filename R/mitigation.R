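#' Expand flagged columns to their neighbourhood
#'
#' Wavelet coefficients around an anomalous column are typically similar in
#' magnitude, so mitigation extends `expansion_step` columns to each side of
#' every flagged column. Overlapping expansions merge; the result is clipped
#' to the window's column range.
#'
#' @param at Sorted 1-based flagged column indices.
#' @param expansion_step Columns added on each side (>= 0).
#' @param n_columns Total columns in the window.
#' @return Sorted, deduplicated expanded indices in `[1, n_columns]`.
#' @export
expand_timestamps <- function(at, expansion_step, n_columns) {
  if (expansion_step < 0) stop("`expansion_step` must be >= 0")
  at <- as.integer(at)
  if (length(at) == 0) return(integer(0))
  if (any(at < 1L | at > n_columns))
    stop("flagged columns must lie in [1, ", n_columns, "]")
  v <- unique(unlist(lapply(at, function(a)
    (a - expansion_step):(a + expansion_step))))
  sort(v[v >= 1L & v <= n_columns])
}

#' Mitigator vector of one coefficient column
#'
#' Per scale row `j`, the complement of the column's distance from the buffer
#' medoid relative to the buffer's maximum distance at that row:
#' `mtg[j] = 1 - |a[j] - medoid[j]| / maxdist[j]`, clamped into `[0, 1]`
#' (rows with zero spread get 1, i.e. no attenuation). Columns close to the
#' medoid are barely touched; columns far from it - the likely artefacts -
#' are attenuated aggressively, possibly differently at each scale.
#'
#' @param a Raw coefficient column (numeric or `coefficient_vector`).
#' @param medoid Output of [compute_medoid()]; computed from `buffer` when
#'   omitted.
#' @param buffer A full [sliding_buffer()].
#' @return Numeric vector of attenuation factors in `[0, 1]`, one per row.
#' @export
mitigator_vector <- function(a, medoid = NULL, buffer) {
  if (inherits(a, "coefficient_vector")) {
    if (isTRUE(a$normalized))
      stop("mitigation operates on raw coefficient vectors")
    a <- a$values
  }
  a <- as.numeric(a)
  if (is.null(medoid)) medoid <- compute_medoid(buffer)
  if (length(a) != length(medoid$values))
    stop("column dimension does not match the medoid")
  mtg <- 1 - abs(a - medoid$values) / medoid$maxdist
  mtg[medoid$maxdist == 0] <- 1
  pmin(pmax(mtg, 0), 1)
}

#' Attenuate the flagged columns of a raw scaleogram
#'
#' Replaces every column in `at_exp` with its element-wise (Hadamard) product
#' with its mitigator vector; all other columns are returned bit-identical.
#' Mitigation happens on the raw coefficient scale: attenuating normalised
#' coefficients and inverting would distort the reconstructed signal.
#'
#' @param scaleogram The current window's raw `scaleogram`.
#' @param at_exp Expanded flagged column indices ([expand_timestamps()]).
#' @param buffer A full [sliding_buffer()].
#' @return The mitigated `scaleogram`.
#' @export
apply_mitigation <- function(scaleogram, at_exp, buffer) {
  stopifnot(inherits(scaleogram, "scaleogram"))
  if (scaleogram$normalized)
    stop("mitigation operates on the raw (non-normalised) scaleogram")
  if (length(at_exp) == 0) return(scaleogram)
  med <- compute_medoid(buffer)
  A <- scaleogram$matrix[, at_exp, drop = FALSE]
  mtg <- 1 - abs(A - med$values) / med$maxdist
  mtg[med$maxdist == 0, ] <- 1
  mtg <- pmin(pmax(mtg, 0), 1)
  out <- scaleogram
  out$matrix[, at_exp] <- A * mtg
  attr(out, "coeffs") <- attr(scaleogram, "coeffs")
  out
}

#' Process one window through the full denoising chain
#'
#' Orchestrates decompose, replicate, normalise, detect (once the buffer is
#' full), expand, mitigate on the raw scale, dereplicate and reconstruct,
#' then pushes the window's original vectors into the buffer. During cold
#' start (buffer not yet full) the window passes through untouched and only
#' fills the buffer. A window whose anomaly list is empty is returned with
#' samples bit-identical to the input.
#'
#' @param current The current `eeg_window` (or numeric vector).
#' @param previous The preceding window, or `NULL`.
#' @param buffer The stream's [sliding_buffer()].
#' @param config An [pipeline_config()] object.
#' @return List with `window` (a `denoised_window`: `samples`,
#'   `window_index`, `modified`, `modified_columns`), `report` (an
#'   `anomaly_report`) and `latency_ms`.
#' @export
denoise_window <- function(current, previous = NULL, buffer, config) {
  stopifnot(inherits(config, "eeg_pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  wi <- if (inherits(current, "eeg_window")) current$window_index else NA_integer_
  cur_samples <- .window_samples(current)

  coeffs <- dwt_decompose(current, previous, config)
  sc <- replicate_coefficients(coeffs)
  scn <- normalize_scaleogram(sc)

  out_samples <- cur_samples
  modified <- FALSE
  at_exp <- integer(0)

  if (buffer_full(buffer)) {
    forest <- build_forest(buffer_vectors(buffer, "norm"), config)
    report <- detect_anomalies(forest, scn, config$anomaly_threshold)
    report$window_index <- wi
    if (length(report$at) > 0) {
      at_exp <- expand_timestamps(report$at, config$expansion_step,
                                  config$columns_per_window)
      report$at_exp <- at_exp
      sc_mit <- apply_mitigation(sc, at_exp, buffer)
      out_samples <- dwt_reconstruct(dereplicate_scaleogram(sc_mit))
      modified <- TRUE
    }
  } else {
    report <- .empty_report(wi)
  }

  buffer_push(buffer, wi, t(sc$matrix), t(scn$matrix))

  latency <- (proc.time()[["elapsed"]] - t0) * 1000
  list(window = structure(
         list(samples = out_samples,
              window_index = wi,
              modified = modified,
              modified_columns = at_exp),
         class = "denoised_window"),
       report = report,
       latency_ms = latency)
}

#' Denoise a continuous signal window by window
#'
#' Runs the online pipeline over a whole recording: the signal is cut into
#' consecutive windows, each processed with [denoise_window()] using only the
#' windows recorded before it. The first `buffer_capacity` windows (the cold
#' start) pass through unmodified while the buffer fills.
#'
#' @param signal Numeric vector of samples (microvolts).
#' @param config An [pipeline_config()] object; `config$seed` governs all
#'   randomness of the run.
#' @param channel_label Label attached to the windows.
#' @param verbose Print per-window progress.
#' @return A `denoise_run`: `denoised` (concatenated output samples),
#'   `original` (the windowed prefix of the input), `reports`, `modified`
#'   (logical per window), `latency_ms` (per window), `n_windows`,
#'   `dropped_samples`, `config`.
#' @export
denoise_stream <- function(signal, config, channel_label = "EEG",
                           verbose = FALSE) {
  stopifnot(inherits(config, "eeg_pipeline_config"))
  windows <- slide_windows(signal, config, channel_label)
  n_win <- length(windows)
  spw <- config$samples_per_window

  with_local_seed(config$seed, {
    buffer <- sliding_buffer(config$buffer_capacity)
    denoised <- numeric(n_win * spw)
    reports <- vector("list", n_win)
    modified <- logical(n_win)
    latency <- numeric(n_win)
    prev <- NULL
    for (i in seq_len(n_win)) {
      res <- denoise_window(windows[[i]], prev, buffer, config)
      denoised[((i - 1L) * spw + 1L):(i * spw)] <- res$window$samples
      reports[[i]] <- res$report
      modified[i] <- res$window$modified
      latency[i] <- res$latency_ms
      prev <- windows[[i]]
      if (verbose)
        message(sprintf("window %d/%d: %s (%.0f ms)", i, n_win,
                        if (res$window$modified)
                          paste0(length(res$report$at), " anomalous columns")
                        else "clean", res$latency_ms))
    }
    n_over <- sum(latency > config$window_ms)
    if (n_over > 0)
      warning(n_over, " of ", n_win, " windows took longer than the ",
              config$window_ms, " ms real-time budget", call. = FALSE)
    structure(
      list(denoised = denoised,
           original = signal[seq_len(n_win * spw)],
           reports = reports,
           modified = modified,
           latency_ms = latency,
           n_windows = n_win,
           dropped_samples = length(signal) - n_win * spw,
           channel_label = channel_label,
           config = config),
      class = "denoise_run")
  })
}

#' @export
print.denoise_run <- function(x, ...) {
  cat(sprintf("online denoising run: %d windows of %d samples (%s)\n",
              x$n_windows, x$config$samples_per_window, x$channel_label))
  warm <- !vapply(x$reports, function(r) r$cold, logical(1))
  cat(sprintf("  cold-start windows: %d; screened: %d; modified: %d\n",
              sum(!warm), sum(warm), sum(x$modified)))
  cat(sprintf("  mean latency: %.1f ms per window (budget %g ms)\n",
              mean(x$latency_ms), x$config$window_ms))
  invisible(x)
}
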