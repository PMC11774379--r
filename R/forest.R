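#' Average unsuccessful-search path length
#'
#' The normaliser `c(n)` of the isolation-forest anomaly score: the expected
#' path length of an unsuccessful binary-search-tree lookup among `n` points,
#' `2 H(n-1) - 2 (n-1)/n` with `H(i) = ln(i) + gamma` (Euler-Mascheroni
#' constant), with `c(1) = 0` and `c(2) = 1`.
#'
#' @param n Number of points (vectorised, non-negative).
#' @return `c(n)`.
#' @export
avg_path_length <- function(n) {
  if (any(n < 0)) stop("`n` must be non-negative")
  gamma_e <- 0.5772156649
  out <- ifelse(n <= 1, 0,
         ifelse(n == 2, 1,
                2 * (log(n - 1) + gamma_e) - 2 * (n - 1) / n))
  as.numeric(out)
}

#' Grow an extended isolation forest
#'
#' Builds `n_trees` isolation trees, each on `subsample` observations drawn
#' uniformly without replacement. At every internal node the data are split by
#' a random hyperplane: a normal with standard-normal entries (with
#' `d - extension_level - 1` coordinates zeroed at random) and an intercept
#' drawn uniformly within the node's bounding box; points with
#' `(x - intercept) . normal <= 0` go left. Recursion stops at a single
#' point, identical points, or depth `ceiling(log2(subsample))`.
#'
#' @param x Numeric matrix, one observation per row.
#' @param n_trees Number of trees.
#' @param subsample Observations per tree (without replacement).
#' @param extension_level Number in `[0, ncol(x) - 1]`; 0 reproduces the
#'   original axis-parallel isolation forest, `ncol(x) - 1` (default) is fully
#'   extended.
#' @param seed Optional seed; when given, the forest is reproducible and the
#'   caller's RNG state is untouched.
#' @return An `isolation_forest` object.
#' @export
isolation_forest <- function(x, n_trees = 100,
                             subsample = min(256L, nrow(x)),
                             extension_level = NULL, seed = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  N <- nrow(x)
  d <- ncol(x)
  if (N < subsample)
    stop("need at least `subsample` (", subsample, ") observations, got ", N)
  if (subsample < 2) stop("`subsample` must be >= 2")
  if (is.null(extension_level)) extension_level <- d - 1L
  if (extension_level < 0 || extension_level > d - 1)
    stop("`extension_level` must lie in [0, ", d - 1, "]")
  depth_limit <- as.integer(ceiling(log2(subsample)))

  with_local_seed(seed, {
    samp <- vapply(seq_len(n_trees), function(t) sample.int(N, subsample),
                   integer(subsample))
    trees <- .eif_build(x, samp, as.integer(extension_level), depth_limit)
    structure(
      list(trees = trees,
           n_trees = as.integer(n_trees),
           subsample = as.integer(subsample),
           extension_level = as.integer(extension_level),
           dim = d,
           c_norm = avg_path_length(subsample)),
      class = "isolation_forest")
  })
}

#' Train the pipeline's anomaly forest from buffered coefficient vectors
#'
#' Convenience wrapper around [isolation_forest()] using the forest
#' parameters of a pipeline configuration (`if_trees`, `if_subsample`,
#' `extension_level`).
#'
#' @param vectors Numeric matrix of normalised coefficient vectors, one per
#'   row (e.g. `buffer_vectors(buffer, "norm")`).
#' @param config An [pipeline_config()] object.
#' @param seed Optional seed forwarded to [isolation_forest()].
#' @return An `isolation_forest`.
#' @export
build_forest <- function(vectors, config, seed = NULL) {
  stopifnot(inherits(config, "eeg_pipeline_config"))
  isolation_forest(vectors,
                   n_trees = config$if_trees,
                   subsample = config$if_subsample,
                   extension_level = config$extension_level,
                   seed = seed)
}

#' Path length of one vector through one isolation tree
#'
#' Number of edges from the root to the terminating leaf, plus the
#' unsuccessful-search correction [avg_path_length()] of the leaf size.
#'
#' @param tree One element of `forest$trees`.
#' @param v Numeric vector of the tree's dimension.
#' @return The path length.
#' @export
path_length <- function(tree, v) {
  v <- if (inherits(v, "coefficient_vector")) v$values else as.numeric(v)
  if (length(v) != ncol(tree$normal))
    stop("vector dimension ", length(v), " does not match the tree (",
         ncol(tree$normal), ")")
  node <- 1L
  depth <- 0L
  while (!tree$leaf[node]) {
    s <- sum((v - tree$pvec[node, ]) * tree$normal[node, ])
    node <- if (s <= 0) tree$left[node] else tree$right[node]
    depth <- depth + 1L
  }
  depth + avg_path_length(tree$size[node])
}

# Score from a mean path length: s = 2^(-E(h) / c(subsample)).
score_from_mean_path <- function(mean_path, subsample) {
  2^(-mean_path / avg_path_length(subsample))
}

#' Anomaly score of vectors under an isolation forest
#'
#' `s = 2^(-E(h(x)) / c(subsample))` with `E(h(x))` the mean path length over
#' the ensemble: scores close to 1 indicate easily isolated (anomalous)
#' vectors, scores below 0.5 typical ones.
#'
#' @param forest An [isolation_forest()].
#' @param x A numeric vector, a matrix with one observation per row, or a
#'   `coefficient_vector`.
#' @return Numeric vector of scores in (0, 1).
#' @export
anomaly_score <- function(forest, x) {
  stopifnot(inherits(forest, "isolation_forest"))
  if (inherits(x, "coefficient_vector")) x <- x$values
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != forest$dim)
    stop("vector dimension ", ncol(x), " does not match the forest (",
         forest$dim, ")")
  paths <- .eif_paths(forest$trees, x)
  score_from_mean_path(rowMeans(paths), forest$subsample)
}

#' Flag the anomalous columns of the current window
#'
#' Scores every coefficient column of the normalised scaleogram under the
#' forest and collects the columns whose score strictly exceeds the anomaly
#' threshold into the list `at` of anomalous timestamps.
#'
#' @param forest An [isolation_forest()] trained on the sliding buffer.
#' @param scaleogram The current window's normalised `scaleogram` (or a
#'   matrix with one coefficient vector per row).
#' @param threshold Anomaly threshold `t_a`.
#' @return An `anomaly_report`: `window_index`, `scores` (one per column),
#'   `at` (1-based flagged column indices, ascending), `at_exp` (filled by the
#'   mitigation stage), `cold = FALSE`.
#' @export
detect_anomalies <- function(forest, scaleogram, threshold) {
  if (inherits(scaleogram, "scaleogram")) {
    if (!scaleogram$normalized)
      warning("scoring a raw (non-normalised) scaleogram")
    x <- t(scaleogram$matrix)
    wi <- scaleogram$window_index
  } else {
    x <- as.matrix(scaleogram)
    wi <- NA_integer_
  }
  scores <- anomaly_score(forest, x)
  structure(
    list(window_index = wi,
         scores = unname(scores),
         at = which(scores > threshold),
         at_exp = integer(0),
         cold = FALSE),
    class = "anomaly_report")
}

.empty_report <- function(window_index) {
  structure(
    list(window_index = window_index, scores = NULL,
         at = integer(0), at_exp = integer(0), cold = TRUE),
    class = "anomaly_report")
}
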