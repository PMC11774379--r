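#' Normalise a scaleogram across decomposition levels
#'
#' Wavelet coefficients at coarser levels (lower frequencies) are generally
#' larger in magnitude than those at finer levels, so they would dominate any
#' computation treating a scaleogram column as a point in coefficient space.
#' Normalisation divides row `m` by `2^m` (and the approximation row by
#' `2^M`, mirroring its replication factor), giving the scales comparable
#' weight before anomaly detection.
#'
#' @param scaleogram A raw `scaleogram`.
#' @return A new `scaleogram` with the `normalized` flag set; the input is
#'   left untouched.
#' @seealso [denormalize_scaleogram()]
#' @export
normalize_scaleogram <- function(scaleogram) {
  stopifnot(inherits(scaleogram, "scaleogram"))
  if (scaleogram$normalized) stop("scaleogram is already normalised")
  out <- scaleogram
  out$matrix <- scaleogram$matrix / .row_scale(scaleogram)
  out$normalized <- TRUE
  attr(out, "coeffs") <- attr(scaleogram, "coeffs")
  out
}

#' Undo scaleogram normalisation
#'
#' Multiplies row `m` by `2^m` (approximation row by `2^M`); exact inverse of
#' [normalize_scaleogram()]. Mitigation operates on the raw coefficient scale,
#' so a normalised scaleogram must pass through here before
#' [dereplicate_scaleogram()] and reconstruction.
#'
#' @param scaleogram A normalised `scaleogram`.
#' @return The raw-scale `scaleogram`.
#' @export
denormalize_scaleogram <- function(scaleogram) {
  stopifnot(inherits(scaleogram, "scaleogram"))
  if (!scaleogram$normalized) stop("scaleogram is not normalised")
  out <- scaleogram
  out$matrix <- scaleogram$matrix * .row_scale(scaleogram)
  out$normalized <- FALSE
  attr(out, "coeffs") <- attr(scaleogram, "coeffs")
  out
}

.row_scale <- function(scaleogram) {
  M <- scaleogram$levels
  2^c(seq_len(M), M)
}

#' Extract the per-time coefficient vectors of a scaleogram
#'
#' Each column of the scaleogram is one point in coefficient space: the
#' signal's representation across all scales at one coefficient-time index.
#' These vectors are the unit of anomaly detection.
#'
#' @param scaleogram A `scaleogram`.
#' @return A list of `coefficient_vector` objects (fields `values`,
#'   `column_index` starting at 1, `window_index`, `normalized`), one per
#'   column, in time order.
#' @export
scaleogram_columns <- function(scaleogram) {
  stopifnot(inherits(scaleogram, "scaleogram"))
  mat <- scaleogram$matrix
  lapply(seq_len(ncol(mat)), function(j) {
    structure(
      list(values = unname(mat[, j]),
           column_index = j,
           window_index = scaleogram$window_index,
           normalized = scaleogram$normalized),
      class = "coefficient_vector")
  })
}

#' @export
print.scaleogram <- function(x, ...) {
  cat(sprintf("scaleogram: %d rows (levels 1..%d + approximation) x %d columns, %s scale\n",
              nrow(x$matrix), x$levels, ncol(x$matrix),
              if (x$normalized) "normalised" else "raw"))
  invisible(x)
}
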