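test_that("timestamp expansion unions clipped neighbourhoods", {
  expect_identical(expand_timestamps(100, 5, 512), 95:105)
  expect_identical(expand_timestamps(3, 5, 512), 1:8) # clipped at the left
  expect_identical(expand_timestamps(c(510, 512), 5, 512), 505:512)
  expect_identical(expand_timestamps(c(10, 12), 3, 512), 7:15) # merged
  expect_identical(expand_timestamps(c(5, 9), 0, 512), c(5L, 9L))
  expect_identical(expand_timestamps(integer(0), 5, 512), integer(0))
  expect_error(expand_timestamps(600, 5, 512), "must lie in")
})

test_that("expansion is monotone in the expansion step", {
  set.seed(2)
  for (rep in 1:10) {
    at <- sort(sample(512, 5))
    prev <- expand_timestamps(at, 0, 512)
    for (es in c(2, 10, 35)) {
      cur <- expand_timestamps(at, es, 512)
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("the mitigator is 1 at the medoid, 0 at the farthest member, clamped beyond", {
  buf <- sliding_buffer(3)
  # three 1-column windows along a line: 0, 1, 10 per row
  for (w in 0:2) {
    pos <- c(0, 1, 10)[w + 1]
    buffer_push(buf, w, matrix(rep(pos, 4), 1, 4), matrix(rep(pos, 4), 1, 4))
  }
  med <- compute_medoid(buf) # the vector of 1s; maxdist = 9 per row
  expect_equal(mitigator_vector(med$values, med, buf), rep(1, 4))
  expect_equal(mitigator_vector(rep(10, 4), med, buf), rep(0, 4))
  # twice the maximum distance clamps to 0 rather than going negative
  expect_equal(mitigator_vector(rep(19, 4), med, buf), rep(0, 4))
  # zero-spread rows attenuate nothing
  buf2 <- sliding_buffer(2)
  for (w in 0:1) buffer_push(buf2, w, matrix(5, 1, 3), matrix(5, 1, 3))
  expect_equal(mitigator_vector(c(99, 99, 99), NULL, buf2), rep(1, 3))
})

test_that("mitigation touches only the expanded columns and never grows magnitudes", {
  cfg <- tiny_config()
  set.seed(6)
  fb <- fill_buffer(rnorm(6 * 64, sd = 5), cfg, 4)
  sc <- random_scaleogram(cfg, seed = 30)
  expect_identical(apply_mitigation(sc, integer(0), fb$buffer)$matrix,
                   sc$matrix)
  at_exp <- expand_timestamps(c(5, 20), cfg$expansion_step,
                              cfg$columns_per_window)
  out <- apply_mitigation(sc, at_exp, fb$buffer)
  untouched <- setdiff(seq_len(ncol(sc$matrix)), at_exp)
  expect_identical(out$matrix[, untouched], sc$matrix[, untouched])
  expect_true(all(abs(out$matrix[, at_exp]) <= abs(sc$matrix[, at_exp])))
  expect_error(apply_mitigation(normalize_scaleogram(sc), at_exp, fb$buffer),
               "non-normalised")
})

test_that("cold-start windows pass through bit-identical while filling the buffer", {
  cfg <- tiny_config()
  set.seed(41)
  x <- rnorm(6 * 64, sd = 10)
  wins <- slide_windows(x, cfg)
  buf <- sliding_buffer(cfg$buffer_capacity)
  prev <- NULL
  for (i in 1:cfg$buffer_capacity) {
    res <- denoise_window(wins[[i]], prev, buf, cfg)
    expect_false(res$window$modified)
    expect_identical(res$window$samples, wins[[i]]$samples)
    expect_true(res$report$cold)
    prev <- wins[[i]]
  }
  expect_true(buffer_full(buf))
})

test_that("windows with an empty anomaly list are returned bit-identical", {
  cfg <- tiny_config(anomaly_threshold = 1 - 1e-9, seed = 3)
  set.seed(17)
  x <- rnorm(8 * 64, sd = 10)
  run <- suppressWarnings(denoise_stream(x, cfg))
  for (i in seq_len(run$n_windows)) {
    expect_length(run$reports[[i]]$at, 0)
    expect_false(run$modified[i])
  }
  expect_identical(run$denoised, run$original)
})

test_that("an injected gross artefact is flagged and attenuated in place", {
  cfg <- tiny_config(buffer_capacity = 6, if_subsample = 64,
                     anomaly_threshold = 0.55)
  set.seed(12)
  x <- rnorm(9 * 64, sd = 2)
  # large smooth bump in the 8th window
  centre <- 7 * 64 + 32
  idx <- (centre - 10):(centre + 10)
  x[idx] <- x[idx] + 40 * cos(pi * (idx - centre) / 21)^2
  run <- suppressWarnings(denoise_stream(x, cfg))
  rep8 <- run$reports[[8]]
  expect_gt(length(rep8$at), 0)
  # flags concentrate around the bump's column neighbourhood
  bump_col <- 32 %/% 2
  expect_true(any(abs(rep8$at - bump_col) <= cfg$expansion_step + 8))
  expect_true(run$modified[8])
  # attenuated towards the background in the bump region
  seg <- (7 * 64 + 1):(8 * 64)
  expect_lt(max(abs(run$denoised[seg])), max(abs(run$original[seg])))
})
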