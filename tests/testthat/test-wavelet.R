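test_that("decomposition yields dyadic per-level coefficient counts", {
  cfg <- pipeline_config(max_level = 10) # full pyramid, 1024 samples
  co <- dwt_decompose(rnorm(1024), NULL, cfg)
  expect_identical(lengths(co$detail), as.integer(1024 / 2^(1:10)))
  expect_length(co$approximation, 1)

  cfg8 <- pipeline_config() # default depth for sym4
  co8 <- dwt_decompose(rnorm(1024), rnorm(1024), cfg8)
  expect_identical(lengths(co8$detail), as.integer(1024 / 2^(1:cfg8$levels)))
})

test_that("a constant window has vanishing detail coefficients", {
  cfg <- tiny_config()
  co <- dwt_decompose(rep(3.7, 64), NULL, cfg)
  for (d in co$detail) expect_lt(max(abs(d)), 1e-10)
  expect_gt(sum(co$approximation^2), 0)
})

test_that("reconstruction inverts decomposition to near machine precision", {
  for (cfg in list(tiny_config(), tiny_config(mother_wavelet = "haar"),
                   tiny_config(mother_wavelet = "db4"),
                   tiny_config(boundary_mode = "smooth"))) {
    set.seed(11)
    for (rep in 1:5) {
      w <- rnorm(cfg$samples_per_window, sd = 20)
      p <- rnorm(cfg$samples_per_window, sd = 20)
      expect_lt(max(abs(dwt_reconstruct(dwt_decompose(w, NULL, cfg)) - w)),
                1e-8 * max(abs(w)))
      expect_lt(max(abs(dwt_reconstruct(dwt_decompose(w, p, cfg)) - w)),
                1e-8 * max(abs(w)))
    }
  }
})

test_that("an impulse localises in the scaleogram near its own column", {
  cfg <- tiny_config()
  n <- cfg$samples_per_window
  w <- numeric(n); w[n / 2] <- 1
  co <- dwt_decompose(w, numeric(n), cfg)
  sc <- replicate_coefficients(co)
  # energy-weighted column centre of the level-1 row sits near column n/4
  row1 <- sc$matrix[1, ]^2
  centre <- sum(seq_along(row1) * row1) / sum(row1)
  expect_lt(abs(centre - n / 4), 4)
})

test_that("level bands halve per level from Nyquist downwards", {
  cfg <- pipeline_config()
  co <- dwt_decompose(rnorm(1024), NULL, cfg)
  expect_equal(unname(co$level_bands[1, ]), c(256, 512))
  expect_equal(unname(co$level_bands[2, ]), c(128, 256))
  M <- cfg$levels
  expect_equal(unname(co$level_bands[M, ]), 1024 / 2^c(M + 1, M))
  expect_equal(unname(co$level_bands[M + 1, ]), c(0, 1024 / 2^(M + 1)))
})

test_that("interior coefficients agree with a longer decomposition (trim correctness)", {
  cfg <- tiny_config(sampling_rate = 256) # 256-sample windows, 5 levels
  filt <- wavescrub:::wavelet_filters(cfg$mother_wavelet)
  L <- filt$length
  n <- cfg$samples_per_window
  set.seed(3)
  long <- rnorm(4 * n)
  wins <- slide_windows(long, cfg)
  co <- dwt_decompose(wins[[3]], wins[[2]], cfg)
  fullL <- wavescrub:::.wavedec(long, filt, cfg$levels)
  offset <- 2L * n # window 3 starts here in the long signal
  for (m in 1:min(3, cfg$levels)) {
    want <- n %/% 2L^m
    s <- round((offset + 2^(m - 1) - 0.5 + (L - 3) / 2 * (2^m - 1)) / 2^m)
    ref <- fullL$details[[m]][(s + 1):(s + want)]
    margin <- 2L * L
    idx <- (margin + 1):(want - margin)
    expect_equal(co$detail[[m]][idx], ref[idx], tolerance = 1e-10)
  }
})

test_that("constructed dyadic coefficient sets invert linearly", {
  cfg <- tiny_config()
  n <- cfg$samples_per_window
  M <- cfg$levels
  make <- function(fill) {
    structure(
      list(detail = lapply(1:M, function(m) fill(n / 2^m)),
           approximation = fill(n / 2^M),
           wavelet = cfg$mother_wavelet, n = n, levels = M,
           level_bands = wavescrub:::.level_bands(M, cfg$sampling_rate),
           window_index = NA_integer_),
      class = "dwt_coefficients")
  }
  zeros <- make(function(k) numeric(k))
  expect_identical(dwt_reconstruct(zeros), numeric(n))

  set.seed(5)
  a <- make(function(k) rnorm(k))
  b <- make(function(k) rnorm(k))
  ab <- a
  for (m in 1:M) ab$detail[[m]] <- a$detail[[m]] + b$detail[[m]]
  ab$approximation <- a$approximation + b$approximation
  expect_equal(dwt_reconstruct(ab),
               dwt_reconstruct(a) + dwt_reconstruct(b), tolerance = 1e-12)

  # zeroing one detail level removes exactly that band's contribution
  a0 <- a
  a0$detail[[2]] <- numeric(n / 4)
  band <- make(function(k) numeric(k))
  band$detail[[2]] <- a$detail[[2]]
  expect_equal(dwt_reconstruct(a) - dwt_reconstruct(a0),
               dwt_reconstruct(band), tolerance = 1e-12)
})

test_that("replication repeats level-m coefficients 2^(m-1) times", {
  cfg <- tiny_config()
  sc <- random_scaleogram(cfg, seed = 2)
  co <- attr(sc, "coeffs")
  n_cols <- ncol(sc$matrix)
  expect_identical(n_cols, cfg$columns_per_window)
  # level 1: no repetition
  expect_identical(unname(sc$matrix[1, ]), co$detail[[1]])
  # level 3: coefficient k occupies a block of 4 columns
  for (k in seq_along(co$detail[[3]])) {
    block <- sc$matrix[3, ((k - 1) * 4 + 1):(k * 4)]
    expect_true(all(block == co$detail[[3]][k]))
  }
  # full-depth pyramid: the deepest detail coefficient fills every column
  cfg10 <- pipeline_config(max_level = 10)
  sc10 <- replicate_coefficients(dwt_decompose(rnorm(1024), NULL, cfg10))
  expect_identical(length(unique(sc10$matrix[10, ])), 1L)
})

test_that("dereplication is the exact inverse of replication", {
  cfg <- tiny_config()
  for (seed in 1:5) {
    sc <- random_scaleogram(cfg, seed = seed)
    co <- attr(sc, "coeffs")
    back <- dereplicate_scaleogram(sc)
    expect_identical(back$detail, co$detail)
    expect_identical(back$approximation, co$approximation)
  }
})

test_that("dereplication rejects normalised or malformed scaleograms", {
  cfg <- tiny_config()
  sc <- random_scaleogram(cfg)
  expect_error(dereplicate_scaleogram(normalize_scaleogram(sc)), "normalis")
  bad <- sc
  bad$matrix <- sc$matrix[, 1:6] # 6 columns not divisible by 2^(m-1) at m=3
  expect_error(dereplicate_scaleogram(bad), "not divisible")
})
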