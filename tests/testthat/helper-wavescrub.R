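# Small instantiation used by most unit tests: 64-sample windows (1 s at
# 64 Hz), 4 decomposition levels (sym4 default depth rule), 4-window buffer.
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(window_ms = 1000, sampling_rate = 64, buffer_capacity = 4,
                   if_subsample = 32, if_trees = 25, expansion_step = 2,
                   seed = 1)
  do.call(pipeline_config, utils::modifyList(defaults, args))
}

# Decompose the first `n_windows` windows of `signal` and push their columns
# into a fresh buffer; returns the buffer plus the windows for further use.
fill_buffer <- function(signal, config, n_windows) {
  wins <- suppressMessages(slide_windows(signal, config))
  stopifnot(length(wins) >= n_windows)
  buf <- sliding_buffer(config$buffer_capacity)
  prev <- NULL
  for (i in seq_len(n_windows)) {
    co <- dwt_decompose(wins[[i]], prev, config)
    sc <- replicate_coefficients(co)
    scn <- normalize_scaleogram(sc)
    buffer_push(buf, i - 1L, t(sc$matrix), t(scn$matrix))
    prev <- wins[[i]]
  }
  list(buffer = buf, windows = wins)
}

# A raw scaleogram of a random window, with reconstruction context.
random_scaleogram <- function(config, seed = 1, previous = TRUE) {
  set.seed(seed)
  n <- config$samples_per_window
  prev <- if (previous) rnorm(n) else NULL
  replicate_coefficients(dwt_decompose(rnorm(n), prev, config))
}
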