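#' Sliding buffer of recent coefficient vectors
#'
#' FIFO store of the raw and normalised scaleogram columns of the most recent
#' windows. The normalised vectors train the anomaly forest; the raw vectors
#' supply the medoid and the mitigation distances. Only original
#' (pre-denoising) vectors enter the buffer, so mitigation never feeds back
#' into its own reference.
#'
#' @param capacity Number of windows retained.
#' @return A `sliding_buffer` (an environment; push/evict mutate in place).
#' @export
sliding_buffer <- function(capacity) {
  if (capacity < 1) stop("`capacity` must be >= 1")
  buf <- new.env(parent = emptyenv())
  buf$capacity <- as.integer(capacity)
  buf$windows <- list()
  buf$cache <- NULL
  class(buf) <- "sliding_buffer"
  buf
}

#' Insert one window's coefficient columns into the buffer
#'
#' Appends the window's original vectors and evicts the oldest window when the
#' buffer is over capacity. Any cached medoid is invalidated.
#'
#' @param buffer A [sliding_buffer()].
#' @param window_index Index of the pushed window.
#' @param raw Matrix of raw coefficient vectors, one per row
#'   (`columns_per_window` rows).
#' @param norm Matrix of normalised vectors, same shape as `raw`.
#' @return The buffer, invisibly.
#' @export
buffer_push <- function(buffer, window_index, raw, norm) {
  stopifnot(inherits(buffer, "sliding_buffer"))
  raw <- as.matrix(raw)
  norm <- as.matrix(norm)
  if (!all(dim(raw) == dim(norm)))
    stop("`raw` and `norm` must have identical dimensions")
  if (length(buffer$windows) > 0) {
    ref <- dim(buffer$windows[[1]]$raw)
    if (!all(dim(raw) == ref))
      stop("incomplete column set: expected ", ref[1], " x ", ref[2],
           ", got ", nrow(raw), " x ", ncol(raw))
  }

  # Once medoid distance sums exist, maintain them exactly across the
  # FIFO turnover (subtract the evicted window's contributions, add the
  # incoming window's) instead of recomputing the full O(N^2) sums.
  if (!is.null(buffer$dsums) &&
      length(buffer$windows) == buffer$capacity) {
    out <- buffer$windows[[1L]]$raw
    if (buffer$capacity > 1L) {
      surv <- do.call(rbind, lapply(buffer$windows[-1L], `[[`, "raw"))
      s_out <- .cross_distance_sums(t(surv), t(out))
      s_in <- .cross_distance_sums(t(surv), t(raw))
      sums_surv <- buffer$dsums[-seq_len(nrow(out))] - s_out + s_in
      sums_new <- .cross_distance_sums(t(raw), t(rbind(surv, raw)))
      buffer$dsums <- c(sums_surv, sums_new)
    } else {
      buffer$dsums <- as.numeric(.cross_distance_sums(t(raw), t(raw)))
    }
  } else {
    buffer$dsums <- NULL
  }

  buffer$windows[[length(buffer$windows) + 1L]] <-
    list(window_index = window_index, raw = raw, norm = norm)
  if (length(buffer$windows) > buffer$capacity)
    buffer$windows <- buffer$windows[-1L]
  buffer$cache <- NULL
  invisible(buffer)
}

#' @rdname sliding_buffer
#' @param buffer A `sliding_buffer`.
#' @export
buffer_full <- function(buffer) {
  length(buffer$windows) >= buffer$capacity
}

#' @rdname sliding_buffer
#' @export
buffer_size <- function(buffer) {
  length(buffer$windows)
}

#' Stack all buffered vectors into one matrix
#'
#' @param buffer A [sliding_buffer()].
#' @param type `"norm"` (forest training) or `"raw"` (medoid/mitigation).
#' @return Matrix with one vector per row, oldest window first.
#' @export
buffer_vectors <- function(buffer, type = c("norm", "raw")) {
  stopifnot(inherits(buffer, "sliding_buffer"))
  type <- match.arg(type)
  if (length(buffer$windows) == 0) stop("buffer is empty (cold start)")
  do.call(rbind, lapply(buffer$windows, function(w) w[[type]]))
}

#' Medoid of the buffered raw coefficient vectors
#'
#' The buffer member whose summed Euclidean distance to every other member is
#' minimal: the most representative recent coefficient vector, standing in
#' for prototypical clean signal. Ties resolve to the earliest
#' (window, column). Requires a full buffer; the result (together with the
#' per-row maximum distances used by the mitigator) is cached until the buffer
#' changes.
#'
#' @param buffer A full [sliding_buffer()].
#' @return A list: `values` (raw coefficient vector), `window_index`,
#'   `column_index`, `index` (row in [buffer_vectors()]), `maxdist`
#'   (per-row maximum absolute deviation of any buffer member from the
#'   medoid).
#' @export
compute_medoid <- function(buffer) {
  stopifnot(inherits(buffer, "sliding_buffer"))
  if (!buffer_full(buffer))
    stop("buffer holds ", buffer_size(buffer), " of ", buffer$capacity,
         " windows; the medoid needs a full buffer")
  if (!is.null(buffer$cache)) return(buffer$cache)
  raw <- buffer_vectors(buffer, "raw")
  if (is.null(buffer$dsums))
    buffer$dsums <- as.numeric(.medoid_distance_sums(t(raw)))
  sums <- buffer$dsums
  idx <- which.min(sums) # first minimum = earliest (window, column)
  values <- raw[idx, ]
  cols <- nrow(buffer$windows[[1]]$raw)
  w <- (idx - 1L) %/% cols + 1L
  res <- list(values = unname(values),
              window_index = buffer$windows[[w]]$window_index,
              column_index = as.integer((idx - 1L) %% cols + 1L),
              index = as.integer(idx),
              maxdist = apply(abs(sweep(raw, 2L, values)), 2L, max))
  buffer$cache <- res
  res
}
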