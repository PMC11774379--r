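#' Synthetic background EEG
#'
#' Gaussian noise shaped to a 1/f power spectrum (flattened below 1 Hz to
#' keep the variance finite), band-limited by the acquisition front-end every
#' EEG system applies (emulated as a low-pass with half-power at one fifth of
#' the sampling rate, the anti-aliasing setting of the active-electrode
#' system the blink instantiation targets), plus a 10 Hz alpha-band
#' oscillation contributing 20% of the total RMS; the whole trace is scaled
#' so the overall RMS equals `rms_uV`. Emulates ongoing neural background
#' activity as it appears in a recorded channel; it has none of the
#' non-stationarity, electrode drifts or non-blink artefacts of real
#' recordings.
#'
#' @param duration_s Duration in seconds (>= 1).
#' @param sampling_rate Sampling rate in Hz.
#' @param rms_uV Target RMS amplitude in microvolts.
#' @param seed Optional seed (caller's RNG state is preserved).
#' @return Numeric vector of `duration_s * sampling_rate` samples.
#' @export
generate_background <- function(duration_s, sampling_rate, rms_uV = 15,
                                seed = NULL) {
  if (duration_s < 1) stop("`duration_s` must be >= 1 second")
  if (sampling_rate <= 0) stop("`sampling_rate` must be positive")
  n <- round(duration_s * sampling_rate)
  with_local_seed(seed, {
    white <- stats::rnorm(n)
    freqs <- c(0, seq_len(n - 1)) * sampling_rate / n
    freqs <- pmin(freqs, sampling_rate - freqs) # two-sided spectrum
    weight <- 1 / sqrt(pmax(freqs, 1)) # 1/f power, flat below 1 Hz
    f_aa <- sampling_rate / 5 # acquisition anti-aliasing half-power point
    weight <- weight / sqrt(1 + (freqs / f_aa)^10)
    weight[1] <- 0 # no DC offset
    shaped <- Re(stats::fft(stats::fft(white) * weight, inverse = TRUE)) / n
    shaped <- shaped / stats::sd(shaped) * sqrt(1 - 0.2^2)
    t <- (seq_len(n) - 1) / sampling_rate
    alpha <- 0.2 * sqrt(2) * sin(2 * pi * 10 * t + stats::runif(1, 0, 2 * pi))
    x <- shaped + alpha
    x / sqrt(mean(x^2)) * rms_uV
  })
}

#' Synthetic eye-blink artefact train
#'
#' Positive squared-cosine (Hann) pulses at Poisson-like arrival times with a
#' 500 ms refractory gap (inter-blink gaps are 0.5 s plus an exponential with
#' mean chosen so the overall rate is `rate_per_min`). Widths are uniform in
#' `width_ms_range`, amplitudes uniform within +/- 20% of `amp_uV`. The
#' squared-cosine template is deliberately not a sampled wavelet atom, so
#' detection tests do not trivially favour the analysing wavelet.
#'
#' @param duration_s Duration in seconds.
#' @param sampling_rate Sampling rate in Hz.
#' @param rate_per_min Mean blink rate per minute.
#' @param amp_uV Nominal peak amplitude in microvolts.
#' @param width_ms_range Blink width range in ms, within `[100, 700]`.
#' @param double_blink When `TRUE` every event is a pair of pulses 300 ms
#'   apart (the double-blink failure mode).
#' @param seed Optional seed.
#' @return List: `artefact` (numeric vector, everywhere >= 0) and `peaks`
#'   (1-based sample indices of the pulse maxima).
#' @export
generate_blinks <- function(duration_s, sampling_rate, rate_per_min = 12,
                            amp_uV = 80, width_ms_range = c(100, 400),
                            double_blink = FALSE, seed = NULL) {
  if (rate_per_min <= 0) stop("`rate_per_min` must be positive")
  if (width_ms_range[1] < 100 || width_ms_range[2] > 700 ||
      width_ms_range[1] > width_ms_range[2])
    stop("`width_ms_range` must be an increasing range within [100, 700] ms")
  refractory <- 0.5
  mean_gap <- 60 / rate_per_min
  if (mean_gap <= refractory)
    stop("rate of ", rate_per_min,
         "/min is infeasible with a 500 ms refractory gap")
  n <- round(duration_s * sampling_rate)
  with_local_seed(seed, {
    artefact <- numeric(n)
    peaks <- integer(0)
    t <- refractory + stats::rexp(1, 1 / (mean_gap - refractory))
    while (TRUE) {
      width <- stats::runif(1, width_ms_range[1], width_ms_range[2]) / 1000
      amp <- amp_uV * stats::runif(1, 0.8, 1.2)
      centers <- t
      if (double_blink) centers <- c(t, t + 0.3)
      if (max(centers) + width / 2 > duration_s) break
      for (tc in centers) {
        ctr <- round(tc * sampling_rate)
        hw <- round(width / 2 * sampling_rate)
        idx <- max(1L, ctr - hw):min(n, ctr + hw)
        u <- (idx - ctr) / (2 * hw)
        artefact[idx] <- artefact[idx] + amp * cos(pi * u)^2
        peaks <- c(peaks, ctr)
      }
      t <- t + refractory + stats::rexp(1, 1 / (mean_gap - refractory))
    }
    list(artefact = artefact, peaks = peaks)
  })
}

#' Combine clean background and artefact into a recording with ground truth
#'
#' The contaminated trace is the exact element-wise sum of the clean neural
#' signal and the artefact (the additive contamination model), so the clean
#' reference can be recovered by subtraction and every evaluation metric has
#' an exact oracle.
#'
#' @param clean Clean signal (microvolts).
#' @param artefact Artefact signal, same length.
#' @param sampling_rate Sampling rate in Hz.
#' @param blink_peaks Ground-truth peak sample indices.
#' @param parameters List of generator parameters, echoed into the object.
#' @return A `synthetic_recording`: `clean`, `artefact`, `contaminated`,
#'   `sampling_rate`, `blink_peaks`, `parameters`.
#' @export
mix_signals <- function(clean, artefact, sampling_rate,
                        blink_peaks = integer(0), parameters = list()) {
  if (length(clean) != length(artefact))
    stop("`clean` and `artefact` must have equal lengths")
  structure(
    list(clean = as.numeric(clean),
         artefact = as.numeric(artefact),
         contaminated = as.numeric(clean) + as.numeric(artefact),
         sampling_rate = sampling_rate,
         blink_peaks = as.integer(blink_peaks),
         parameters = parameters),
    class = "synthetic_recording")
}

#' Simulate a blink-contaminated EEG recording
#'
#' One-call generator combining [generate_background()] and
#' [generate_blinks()] via [mix_signals()]. The defaults emulate a frontal
#' EEG channel: 15 uV RMS background, 80 uV positive blinks of 100-400 ms at
#' 12 blinks per minute (blink-to-background amplitude ratio around 5).
#'
#' @inheritParams generate_background
#' @inheritParams generate_blinks
#' @param seed Seed for both generators.
#' @return A `synthetic_recording`.
#' @examples
#' rec <- simulate_blink_eeg(duration_s = 10, seed = 1)
#' length(rec$blink_peaks)
#' @export
simulate_blink_eeg <- function(duration_s = 60, sampling_rate = 1024,
                               rms_uV = 15, rate_per_min = 12, amp_uV = 80,
                               width_ms_range = c(100, 400),
                               double_blink = FALSE, seed = NULL) {
  clean <- generate_background(duration_s, sampling_rate, rms_uV, seed = seed)
  bl <- generate_blinks(duration_s, sampling_rate, rate_per_min, amp_uV,
                        width_ms_range, double_blink,
                        seed = if (is.null(seed)) NULL else seed + 1L)
  mix_signals(clean, bl$artefact, sampling_rate, bl$peaks,
              parameters = list(duration_s = duration_s,
                                sampling_rate = sampling_rate,
                                rms_uV = rms_uV, rate_per_min = rate_per_min,
                                amp_uV = amp_uV,
                                width_ms_range = width_ms_range,
                                double_blink = double_blink, seed = seed))
}
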