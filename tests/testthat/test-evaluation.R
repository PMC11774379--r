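test_that("peak detection ignores flat signals and respects its preconditions", {
  expect_length(detect_peaks(numeric(1024), 256, k = 2), 0)
  expect_error(detect_peaks(rnorm(100), 256, k = 2), "2 seconds")
  expect_error(detect_peaks(rnorm(1024), 256, k = 0), "positive")
})

test_that("a single synthetic blink is located within 50 ms", {
  fs <- 256
  for (seed in 1:10) {
    bg <- generate_background(10, fs, rms_uV = 15, seed = seed)
    centre <- 5 * fs
    idx <- (centre - 30):(centre + 30)
    x <- bg
    x[idx] <- x[idx] + 80 * cos(pi * (idx - centre) / 61)^2
    pk <- detect_peaks(x, fs, k = 2)
    expect_true(any(abs(pk - centre) <= 0.05 * fs))
  }
})

test_that("peak counts are monotone non-decreasing in k", {
  fs <- 256
  rec <- simulate_blink_eeg(20, fs, seed = 5)
  n_prev <- -1
  for (k in c(0.5, 1, 2, 4, 8)) {
    n <- length(detect_peaks(rec$contaminated, fs, k))
    expect_gte(n, n_prev)
    n_prev <- n
  }
})

test_that("threshold tuning recovers planted well-separated blinks", {
  fs <- 256
  bg <- generate_background(30, fs, rms_uV = 15, seed = 11)
  centres <- fs * seq(2, 29, by = 3) # 10 blinks, 3 s apart
  x <- bg
  for (ctr in centres) {
    idx <- (ctr - 35):(ctr + 35)
    x[idx] <- x[idx] + 80 * cos(pi * (idx - ctr) / 71)^2
  }
  gt <- tune_k(x, fs)
  expect_true(all(vapply(centres, function(ctr)
    any(abs(gt$peak_samples - ctr) <= 0.05 * fs), logical(1))))
  expect_true(gt$k_used %in% c(1.5, 2, 2.5, 3, 4, 6))
})

test_that("the plausibility filter rejects nearly all background peaks", {
  fs <- 256
  for (seed in 1:3) {
    bg <- generate_background(60, fs, rms_uV = 15, seed = 100 + seed)
    gt <- tune_k(bg, fs)
    # > 100 raw local maxima exist; plausible accepts are at most a couple
    expect_lte(length(gt$peak_samples), 2)
  }
})

test_that("tuning stops after `patience` non-improving steps", {
  fs <- 256
  bg <- generate_background(10, fs, rms_uV = 15, seed = 21)
  ctr <- 5 * fs
  idx <- (ctr - 35):(ctr + 35)
  bg[idx] <- bg[idx] + 90 * cos(pi * (idx - ctr) / 71)^2
  gt <- tune_k(bg, fs, patience = 1)
  # the single blink is found at the first k; the count cannot improve, so
  # the loop visits exactly one further k
  expect_length(gt$k_trace, 2)
  expect_identical(gt$k_used, 1.5)
  expect_error(tune_k(bg, fs, k_grid = numeric(0)), "empty")
  expect_error(tune_k(bg, fs, k_grid = c(3, 2)), "ascending")
})

test_that("window classification follows the standard confusion convention", {
  mk <- function(n_at) structure(list(window_index = 0, scores = NULL,
                                      at = seq_len(n_at), at_exp = integer(0),
                                      cold = FALSE), class = "anomaly_report")
  reports <- list(mk(3), mk(0), mk(2), mk(0))
  labels <- c(TRUE, TRUE, FALSE, FALSE)
  expect_identical(as.character(classify_windows(reports, labels)),
                   c("TP", "FN", "FP", "TN"))
  # raising min_anomalies can only move TP->FN and FP->TN
  cls2 <- classify_windows(reports, labels, min_anomalies = 3)
  expect_identical(as.character(cls2), c("TP", "FN", "TN", "TN"))
  expect_error(classify_windows(reports, labels[1:2]), "same length")
})

test_that("accuracy is the share of correct windows", {
  expect_equal(accuracy(c(TP = 1, TN = 1, FP = 1, FN = 1)), 0.5)
  expect_equal(accuracy(c(TP = 3, TN = 5, FP = 1, FN = 1)), 0.8)
  expect_equal(accuracy(c(TP = 2, TN = 3, FP = 0, FN = 0)), 1)
  expect_error(accuracy(c(TP = 1, TN = 1)), "must contain")
})

test_that("oracle SNR follows its defining identities", {
  clean <- sin(seq(0, 10, length.out = 500))
  expect_identical(oracle_snr(clean, clean), 100)
  expect_equal(oracle_snr(clean, clean + clean), 0) # residual power = clean power
  resid <- rnorm(500, sd = 0.2)
  full <- oracle_snr(clean, clean + resid)
  halved <- oracle_snr(clean, clean + resid / 2)
  expect_equal(halved - full, 20 * log10(2), tolerance = 1e-9)
  expect_error(oracle_snr(clean, clean[-1]), "equal lengths")
})

test_that("Jensen-Shannon divergence is bounded, symmetric and sharp at the ends", {
  a <- rnorm(500)
  expect_identical(js_divergence(a, a), 0)
  expect_equal(js_divergence(rnorm(400), rnorm(400, mean = 100)), 1)
  for (seed in 1:5) {
    set.seed(seed)
    x <- rnorm(200)
    y <- rnorm(300, mean = runif(1, 0, 2))
    d1 <- js_divergence(x, y)
    expect_identical(d1, js_divergence(y, x))
    expect_gte(d1, 0)
    expect_lte(d1, 1)
  }
  expect_error(js_divergence(numeric(0), a), "non-empty")
})

test_that("run evaluation partitions windows and zeroes the untouched categories", {
  cfg <- tiny_config(buffer_capacity = 3, if_subsample = 48, seed = 2)
  fs <- cfg$sampling_rate
  clean <- generate_background(10, fs, rms_uV = 10, seed = 31)
  art <- numeric(length(clean))
  ctr <- 6 * fs + 32
  idx <- (ctr - 12):(ctr + 12)
  art[idx] <- 60 * cos(pi * (idx - ctr) / 25)^2
  rec <- mix_signals(clean, art, fs, blink_peaks = ctr)
  run <- suppressWarnings(denoise_stream(rec$contaminated, cfg))
  ev <- evaluate_run(rec, run)
  expect_identical(sum(ev$counts), length(ev$evaluated))
  expect_true(ev$accuracy >= 0 && ev$accuracy <= 1)
  # untouched windows have identical SNR before and after
  untouched <- !run$modified[ev$evaluated]
  expect_identical(ev$snr_before[untouched], ev$snr_after[untouched])
  if (ev$counts[["TN"]] > 0) expect_identical(ev$js_by_category[["TN"]], 0)
  # empty categories are reported as absent, not zero
  if (ev$counts[["FN"]] == 0) expect_true(is.na(ev$js_by_category[["FN"]]))
})
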