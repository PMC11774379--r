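#' Pipeline configuration
#'
#' Bundles every tunable parameter of the online denoising pipeline and
#' derives the quantities that follow from them (samples per window,
#' scaleogram columns, decomposition depth). Defaults are the blink
#' instantiation: 1-second windows at 1024 Hz, `sym4` mother wavelet, a
#' 20-window sliding buffer, 100 isolation trees on 512-vector sub-samples,
#' anomaly threshold 0.55 and expansion step 35.
#'
#' @param window_ms Window length in milliseconds. Together with
#'   `sampling_rate` it must yield an integer, power-of-two number of samples
#'   per window (or a multiple of `2^max_level` when `max_level` is given),
#'   as required by the dyadic sub-band scheme.
#' @param sampling_rate Sampling rate in Hz.
#' @param mother_wavelet Name of the orthogonal mother wavelet; one of
#'   `"haar"`, `"db2"`, `"db4"`, `"sym4"`, `"sym8"`. `sym4` resembles the
#'   positive-peaked shape of an eye blink.
#' @param buffer_capacity Number of past windows held in the sliding buffer.
#' @param if_subsample Vectors drawn (without replacement) to grow each
#'   isolation tree. Must not exceed the buffer's total vector count.
#' @param if_trees Number of isolation trees in the ensemble.
#' @param anomaly_threshold Score above which a coefficient column is flagged;
#'   strictly between 0 and 1.
#' @param expansion_step Number of neighbouring columns on each side of a
#'   flagged column that are also mitigated.
#' @param extension_level Extension level of the isolation forest, between 0
#'   (axis-parallel splits, the original algorithm) and the vector dimension
#'   minus one. `NULL` (default) means fully extended.
#' @param boundary_mode Boundary extension used by the wavelet pyramid:
#'   `"symmetric"` (mirror reflection, default) or `"smooth"` (straight-line
#'   continuation of the edge slope). Reflection keeps boundary-influenced
#'   coefficients on the scale of the signal at every level; the straight-line
#'   mode extrapolates over the equivalent of seconds at coarse levels and is
#'   offered for comparison.
#' @param max_level Optional decomposition depth. By default the pyramid
#'   runs to `floor(log2(2 * samples_per_window / (L - 1)))` levels (`L` the
#'   filter length; 8 for `sym4` at 1024 samples) - the deepest scales whose
#'   coefficients are still estimable from the two-window context; deeper
#'   levels are boundary-dominated. Set `max_level = log2(samples_per_window)`
#'   for the full pyramid.
#' @param seed Integer seed governing all randomness of a run.
#' @param min_anomalies_for_positive Minimum number of flagged columns for a
#'   window to count as a detection when classifying windows.
#' @return A validated object of class `eeg_pipeline_config` with derived
#'   fields `samples_per_window`, `columns_per_window`, `levels` (decomposition
#'   depth) and `n_rows` (scaleogram rows, levels + approximation).
#' @seealso [validate_config()], [denoise_stream()]
#' @examples
#' cfg <- pipeline_config()
#' cfg$samples_per_window # 1024
#' cfg$columns_per_window # 512
#' @export
pipeline_config <- function(window_ms = 1000,
                            sampling_rate = 1024,
                            mother_wavelet = "sym4",
                            buffer_capacity = 20,
                            if_subsample = 512,
                            if_trees = 100,
                            anomaly_threshold = 0.55,
                            expansion_step = 35,
                            extension_level = NULL,
                            boundary_mode = c("symmetric", "smooth"),
                            max_level = NULL,
                            seed = 0,
                            min_anomalies_for_positive = 1) {
  cfg <- structure(
    list(window_ms = window_ms,
         sampling_rate = sampling_rate,
         mother_wavelet = mother_wavelet,
         buffer_capacity = buffer_capacity,
         if_subsample = if_subsample,
         if_trees = if_trees,
         anomaly_threshold = anomaly_threshold,
         expansion_step = expansion_step,
         extension_level = extension_level,
         boundary_mode = match.arg(boundary_mode),
         max_level = max_level,
         seed = seed,
         min_anomalies_for_positive = min_anomalies_for_positive),
    class = "eeg_pipeline_config")
  validate_config(cfg)
}

#' Validate a pipeline configuration and fill derived fields
#'
#' Checks every invariant (integer power-of-two window length, threshold in
#' (0, 1), sub-sample not larger than the buffer population, extension level
#' within the vector dimension) and computes `samples_per_window`,
#' `columns_per_window`, `levels` and `n_rows`.
#'
#' @param config An `eeg_pipeline_config`, e.g. from [pipeline_config()].
#' @return The config with derived fields populated.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "eeg_pipeline_config"))
  c_ <- config
  if (!is.numeric(c_$window_ms) || c_$window_ms <= 0)
    stop("`window_ms` must be a positive number")
  if (!is.numeric(c_$sampling_rate) || c_$sampling_rate <= 0)
    stop("`sampling_rate` must be a positive number")
  spw <- c_$window_ms * c_$sampling_rate / 1000
  if (abs(spw - round(spw)) > 1e-9)
    stop("window_ms x sampling_rate / 1000 must be an integer number of samples")
  spw <- as.integer(round(spw))
  filt <- wavelet_filters(c_$mother_wavelet) # errors on unknown wavelet

  if (is.null(c_$max_level)) {
    # Default depth: the standard rule floor(log2(n / (L - 1))) applied to the
    # two-window context the transform actually sees (n = 2 spw). Deeper
    # levels of a window this short are dominated by boundary effects (the
    # cone of influence covers the whole window), which would poison the
    # anomaly vectors; the full pyramid remains available via `max_level`.
    levels <- min(floor(log2(spw)),
                  floor(log2(2 * spw / (filt$length - 1))))
    levels <- as.integer(levels)
  } else {
    levels <- as.integer(c_$max_level)
    if (levels < 1) stop("`max_level` must be >= 1")
  }
  if (levels < 1) stop("window too short to decompose")
  if (spw %% 2^levels != 0)
    stop("samples per window (", spw, ") is not a multiple of 2^levels (2^",
         levels, "); the dyadic sub-band scheme needs a power-of-2-compatible ",
         "window length")

  cols <- spw %/% 2L
  n_rows <- levels + 1L # detail rows plus the approximation row

  if (!is.numeric(c_$anomaly_threshold) ||
      c_$anomaly_threshold <= 0 || c_$anomaly_threshold >= 1)
    stop("`anomaly_threshold` must lie strictly between 0 and 1")
  if (c_$expansion_step < 0) stop("`expansion_step` must be >= 0")
  if (c_$buffer_capacity < 1) stop("`buffer_capacity` must be >= 1")
  if (c_$if_trees < 1) stop("`if_trees` must be >= 1")
  if (c_$if_subsample < 2) stop("`if_subsample` must be >= 2")
  if (c_$if_subsample > c_$buffer_capacity * cols)
    stop("`if_subsample` (", c_$if_subsample, ") exceeds the buffer population (",
         c_$buffer_capacity * cols, " vectors)")
  if (is.null(c_$extension_level)) {
    c_$extension_level <- n_rows - 1L
  } else {
    if (c_$extension_level < 0 || c_$extension_level > n_rows - 1)
      stop("`extension_level` must lie in [0, ", n_rows - 1, "]")
    c_$extension_level <- as.integer(c_$extension_level)
  }
  if (c_$min_anomalies_for_positive < 1)
    stop("`min_anomalies_for_positive` must be >= 1")
  if (is.null(c_$boundary_mode)) c_$boundary_mode <- "symmetric"
  if (!c_$boundary_mode %in% c("symmetric", "smooth"))
    stop("`boundary_mode` must be \"symmetric\" or \"smooth\"")

  c_$buffer_capacity <- as.integer(c_$buffer_capacity)
  c_$if_subsample <- as.integer(c_$if_subsample)
  c_$if_trees <- as.integer(c_$if_trees)
  c_$expansion_step <- as.integer(c_$expansion_step)
  c_$min_anomalies_for_positive <- as.integer(c_$min_anomalies_for_positive)
  c_$samples_per_window <- spw
  c_$columns_per_window <- cols
  c_$levels <- levels
  c_$n_rows <- n_rows
  c_
}

#' @export
print.eeg_pipeline_config <- function(x, ...) {
  cat("EEG denoising pipeline configuration\n")
  cat(sprintf("  window: %g ms at %g Hz (%d samples, %d scaleogram columns)\n",
              x$window_ms, x$sampling_rate, x$samples_per_window,
              x$columns_per_window))
  cat(sprintf("  wavelet: %s, %d decomposition levels (+ approximation row)\n",
              x$mother_wavelet, x$levels))
  cat(sprintf("  buffer: %d windows; forest: %d trees x %d vectors, extension level %d\n",
              x$buffer_capacity, x$if_trees, x$if_subsample, x$extension_level))
  cat(sprintf("  anomaly threshold: %g; expansion step: %d columns; seed: %s\n",
              x$anomaly_threshold, x$expansion_step, format(x$seed)))
  invisible(x)
}

#' Highest frequency meaningfully contained in one window
#'
#' Given a window of `window_ms` milliseconds sampled at `sampling_rate` Hz,
#' only frequencies up to `(window_ms * sampling_rate) / 1000 * 0.5` can be
#' extracted (the Nyquist bound applied to the per-window sample count).
#'
#' @param window_ms Window length in milliseconds (positive).
#' @param sampling_rate Sampling rate in Hz (positive).
#' @return The bound in Hz.
#' @examples
#' max_frequency(500, 1024) # 256
#' @export
max_frequency <- function(window_ms, sampling_rate) {
  if (!is.numeric(window_ms) || any(window_ms <= 0))
    stop("`window_ms` must be positive")
  if (!is.numeric(sampling_rate) || any(sampling_rate <= 0))
    stop("`sampling_rate` must be positive")
  (window_ms * sampling_rate) / 1000 * 0.5
}

#' Cut a continuous signal into consecutive pipeline windows
#'
#' Splits a recording into non-overlapping windows of
#' `config$samples_per_window` samples, in recording order. A trailing
#' remainder shorter than one window is dropped (the online setting never
#' completes it) and reported via a message.
#'
#' @param signal Numeric vector of samples (microvolts).
#' @param config An [pipeline_config()] object.
#' @param channel_label Label stored on each window.
#' @return A list of `eeg_window` objects, each with fields `samples`,
#'   `window_index` (0-based), `start_sample` (0-based offset into the
#'   recording) and `channel_label`.
#' @export
slide_windows <- function(signal, config, channel_label = "EEG") {
  stopifnot(inherits(config, "eeg_pipeline_config"))
  signal <- as.numeric(signal)
  spw <- config$samples_per_window
  if (length(signal) < spw)
    stop("signal (", length(signal), " samples) is shorter than one window (",
         spw, " samples)")
  n_win <- length(signal) %/% spw
  rem <- length(signal) - n_win * spw
  if (rem > 0)
    message("dropping trailing remainder of ", rem, " samples (< one window)")
  lapply(seq_len(n_win) - 1L, function(w) {
    structure(
      list(samples = signal[(w * spw + 1L):((w + 1L) * spw)],
           window_index = w,
           start_sample = w * spw,
           channel_label = channel_label),
      class = "eeg_window")
  })
}
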