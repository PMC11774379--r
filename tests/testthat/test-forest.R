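test_that("the path-length normaliser matches its closed form", {
  expect_identical(avg_path_length(1), 0)
  expect_identical(avg_path_length(0), 0)
  expect_identical(avg_path_length(2), 1)
  # c(4) = 2 (ln 3 + gamma) - 2*3/4, computed from the closed form
  expect_equal(avg_path_length(4), 1.8516559071, tolerance = 1e-9)
  expect_error(avg_path_length(-1), "non-negative")
})

test_that("forests have the requested size and are reproducible from a seed", {
  set.seed(99)
  X <- matrix(rnorm(200 * 3), ncol = 3)
  f1 <- isolation_forest(X, n_trees = 40, subsample = 64, seed = 7)
  f2 <- isolation_forest(X, n_trees = 40, subsample = 64, seed = 7)
  expect_length(f1$trees, 40)
  probe <- matrix(rnorm(30), ncol = 3)
  expect_identical(anomaly_score(f1, probe), anomaly_score(f2, probe))
  f3 <- isolation_forest(X, n_trees = 40, subsample = 64, seed = 8)
  expect_false(identical(anomaly_score(f1, probe), anomaly_score(f3, probe)))
  expect_error(isolation_forest(X[1:10, ], subsample = 64), "at least")
})

test_that("extension level zero produces axis-parallel splits", {
  X <- matrix(rnorm(300 * 4), ncol = 4)
  f <- isolation_forest(X, n_trees = 10, subsample = 64,
                        extension_level = 0, seed = 3)
  for (tr in f$trees) {
    internal <- tr$leaf == 0
    if (any(internal))
      expect_true(all(rowSums(tr$normal[internal, , drop = FALSE] != 0) == 1))
  }
  # fully extended: all dimensions participate
  fe <- isolation_forest(X, n_trees = 5, subsample = 64, seed = 3)
  tr <- fe$trees[[1]]
  internal <- tr$leaf == 0
  expect_true(all(rowSums(tr$normal[internal, , drop = FALSE] != 0) == 4))
})

test_that("path lengths follow the edge count plus leaf correction", {
  d <- 2
  leaf_only <- list(normal = matrix(0, 1, d), pvec = matrix(0, 1, d),
                    left = 0L, right = 0L, size = 1L, leaf = 1L)
  expect_identical(path_length(leaf_only, c(5, 5)), 0)

  # root split sending the probe to a size-2 leaf at depth 1: 1 + c(2) = 2
  two_pt <- list(
    normal = rbind(c(1, 0), 0, 0),
    pvec = rbind(c(0, 0), 0, 0),
    left = c(2L, 0L, 0L), right = c(3L, 0L, 0L),
    size = c(4L, 2L, 2L), leaf = c(0L, 1L, 1L))
  expect_identical(path_length(two_pt, c(-1, 0)), 2) # goes left
  expect_identical(path_length(two_pt, c(1, 0)), 2)  # goes right
  expect_error(path_length(two_pt, c(1, 2, 3)), "dimension")
})

test_that("R traversal and compiled scoring agree", {
  set.seed(21)
  X <- matrix(rnorm(400 * 3), ncol = 3)
  f <- isolation_forest(X, n_trees = 20, subsample = 128, seed = 2)
  probe <- X[7, ]
  manual <- mean(vapply(f$trees, path_length, numeric(1), v = probe))
  expect_equal(unname(anomaly_score(f, probe)),
               2^(-manual / avg_path_length(f$subsample)), tolerance = 1e-12)
})

test_that("scores lie in (0,1) with the documented landmarks", {
  # mean path length equal to c(n) maps to exactly 0.5
  expect_equal(wavescrub:::score_from_mean_path(avg_path_length(256), 256), 0.5)
  # shorter paths push the score towards 1
  expect_gt(wavescrub:::score_from_mean_path(1, 256), 0.5)
  set.seed(4)
  X <- matrix(rnorm(300 * 2), ncol = 2)
  f <- isolation_forest(X, n_trees = 50, subsample = 128, seed = 1)
  s <- anomaly_score(f, X)
  expect_true(all(s > 0 & s < 1))
})

test_that("a gross outlier outscores every member of a tight cluster", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- rbind(matrix(rnorm(256 * 2, sd = 0.5), ncol = 2), c(100, 100))
    f <- isolation_forest(X, n_trees = 50, subsample = 128, seed = seed)
    s <- anomaly_score(f, X)
    expect_gt(s[257], max(s[1:256]))
  }
})

test_that("axis-parallel scores rank like distance from the median in 1-D", {
  rho <- vapply(1:10, function(seed) {
    set.seed(seed)
    x <- matrix(rnorm(64), ncol = 1)
    f <- isolation_forest(x, n_trees = 100, subsample = 64,
                          extension_level = 0, seed = seed)
    cor(anomaly_score(f, x), abs(x - median(x)), method = "spearman")
  }, numeric(1))
  # the oracle itself is imperfect at n = 64 (interior density dips raise
  # isolation scores legitimately), so require strong agreement on the whole
  # and positive agreement everywhere
  expect_gt(median(rho), 0.8)
  expect_true(all(rho > 0.3))
})

test_that("detection flags exactly the columns above the threshold", {
  cfg <- tiny_config()
  fb <- fill_buffer(rnorm(6 * 64, sd = 10), cfg, 4)
  f <- build_forest(buffer_vectors(fb$buffer, "norm"), cfg, seed = 1)
  sc <- random_scaleogram(cfg, seed = 9)
  scn <- normalize_scaleogram(sc)
  rep1 <- detect_anomalies(f, scn, 0.5)
  expect_identical(rep1$at, which(rep1$scores > 0.5))
  expect_length(rep1$scores, cfg$columns_per_window)
  # a threshold of (almost) 1 can never be exceeded
  rep2 <- detect_anomalies(f, scn, 1 - 1e-12)
  expect_length(rep2$at, 0)
})
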