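# Orthogonal wavelet filter banks: decomposition low-pass coefficients of the
# Daubechies family (haar/dbN) and their least-asymmetric variants (symN).
# The remaining three filters follow from the quadrature-mirror relations.
.wavelet_dec_lo <- list(
  haar = c(0.70710678118654757, 0.70710678118654757),
  db2 = c(-0.12940952255126037, 0.22414386804201339, 0.83651630373780794,
          0.48296291314453416),
  db4 = c(-0.010597401785069032, 0.032883011666885197, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.63088076792985892,
          0.71484657055291567, 0.23037781330889651),
  sym4 = c(-0.075765714789273325, -0.02963552764599851, 0.49761866763201545,
           0.80373875180591614, 0.29785779560527736, -0.099219543576847216,
           -0.012603967262037833, 0.032223100604042702),
  sym8 = c(-0.0033824159510061256, -0.00054213233179114812,
           0.031695087811492981, 0.0076074873249176054, -0.14329423835080971,
           -0.061273359067658524, 0.48135965125837221, 0.77718575170052351,
           0.3644418948353314, -0.051945838107709037, -0.027219029917056003,
           0.049137179673607506, 0.0038087520138906151, -0.014952258337048231,
           -0.0003029205147213668, 0.0018899503327594609)
)

#' Filter bank of an orthogonal mother wavelet
#'
#' @param name Wavelet name: `"haar"` (alias `"db1"`), `"db2"`, `"db4"`,
#'   `"sym4"` or `"sym8"`.
#' @return List with the four filters (`dec_lo`, `dec_hi`, `rec_lo`,
#'   `rec_hi`), the filter `length` and the canonical `name`.
#' @export
wavelet_filters <- function(name) {
  nm <- tolower(name)
  if (nm == "db1") nm <- "haar"
  lo <- .wavelet_dec_lo[[nm]]
  if (is.null(lo))
    stop("unknown wavelet '", name, "'; available: ",
         paste(c(names(.wavelet_dec_lo), "db1"), collapse = ", "))
  L <- length(lo)
  hi <- rev(lo) * (-1)^seq_len(L)
  list(name = nm, length = L, dec_lo = lo, dec_hi = hi,
       rec_lo = rev(lo), rec_hi = rev(hi))
}

# Full linear convolution, exact tap-by-tap accumulation.
.conv_full <- function(x, f) {
  n <- length(x)
  out <- numeric(n + length(f) - 1L)
  for (j in seq_along(f)) {
    rng <- j:(j + n - 1L)
    out[rng] <- out[rng] + f[j] * x
  }
  out
}

# Boundary extensions, p samples on each side.
#
# "symmetric" (default): half-point mirror reflection. Bounded by the data
# range at every pyramid level, so boundary-influenced coefficients stay on
# the scale of the signal even at coarse scales.
#
# "smooth": straight-line continuation of the edge slope. At coarse levels
# the extension extrapolates over the equivalent of seconds of signal and the
# extrapolated values compound level over level, inflating edge coefficients
# far beyond the signal's energy; offered for comparison, not as the default.
.dwt_ext <- function(x, p, mode = "symmetric") {
  n <- length(x)
  if (mode == "smooth") {
    dl <- if (n > 1) x[2] - x[1] else 0
    dr <- if (n > 1) x[n] - x[n - 1] else 0
    return(c(x[1] - (p:1) * dl, x, x[n] + (1:p) * dr))
  }
  fold <- function(k) {
    m <- k %% (2L * n)
    ifelse(m >= n, 2L * n - 1L - m, m)
  }
  c(x[fold((-p):(-1)) + 1L], x, x[fold(n:(n + p - 1L)) + 1L])
}

# One analysis step with smooth boundary extension. Output length
# floor((n + L - 1) / 2); boundary-influenced coefficients are retained so the
# synthesis step is an exact inverse.
.dwt_step <- function(x, filt, mode = "symmetric") {
  n <- length(x)
  L <- filt$length
  if (n < 2) stop("signal too short to decompose")
  ext <- .dwt_ext(x, L - 1L, mode)
  la <- (n + L - 1L) %/% 2L
  idx <- seq.int(L + 1L, by = 2L, length.out = la)
  list(cA = .conv_full(ext, filt$dec_lo)[idx],
       cD = .conv_full(ext, filt$dec_hi)[idx])
}

# Exact inverse of .dwt_step, cropped to out_len samples.
.idwt_step <- function(cA, cD, filt, out_len) {
  la <- length(cA)
  L <- filt$length
  avail <- 2L * la - L + 2L
  if (out_len > avail)
    stop("inconsistent coefficient lengths for inverse transform")
  up <- function(v) {
    u <- numeric(2L * la)
    u[seq.int(1L, by = 2L, length.out = la)] <- v
    u
  }
  full <- .conv_full(up(cA), filt$rec_lo) + .conv_full(up(cD), filt$rec_hi)
  full[(L - 1L):(L - 2L + out_len)]
}

.wavedec <- function(x, filt, levels, mode = "symmetric") {
  details <- vector("list", levels)
  lengths <- integer(levels + 1L)
  lengths[1L] <- length(x)
  a <- x
  for (m in seq_len(levels)) {
    st <- .dwt_step(a, filt, mode)
    details[[m]] <- st$cD
    a <- st$cA
    lengths[m + 1L] <- length(a)
  }
  list(details = details, approx = a, lengths = lengths)
}

.waverec <- function(details, approx, filt, lengths) {
  a <- approx
  for (m in rev(seq_along(details)))
    a <- .idwt_step(a, details[[m]], filt, lengths[m])
  a
}

# Periodised (circular) analysis/synthesis: exactly n/2 coefficients per band
# and an orthogonal transform, used for coefficient sets constructed directly
# at dyadic lengths.
.dwt_step_per <- function(x, filt) {
  n <- length(x)
  if (n %% 2L != 0L) stop("periodised step needs an even length")
  L <- filt$length
  half <- L %/% 2L
  la <- n %/% 2L
  i2 <- 2L * (seq_len(la) - 1L)
  cA <- numeric(la)
  cD <- numeric(la)
  for (j in 0:(L - 1L)) {
    idx <- ((i2 + half - j) %% n) + 1L
    cA <- cA + filt$dec_lo[j + 1L] * x[idx]
    cD <- cD + filt$dec_hi[j + 1L] * x[idx]
  }
  list(cA = cA, cD = cD)
}

.idwt_step_per <- function(cA, cD, filt) {
  la <- length(cA)
  n <- 2L * la
  L <- filt$length
  half <- L %/% 2L
  x <- numeric(n)
  i2 <- 2L * (seq_len(la) - 1L)
  for (j in 0:(L - 1L)) {
    idx <- ((i2 + half - j) %% n) + 1L
    x[idx] <- x[idx] + filt$dec_lo[j + 1L] * cA + filt$dec_hi[j + 1L] * cD
  }
  x
}

# Frequency band (Hz) covered by each scaleogram row: detail level m spans
# [fs / 2^(m+1), fs / 2^m]; the approximation row spans [0, fs / 2^(M+1)].
.level_bands <- function(levels, sampling_rate) {
  m <- seq_len(levels)
  bands <- cbind(low = sampling_rate / 2^(m + 1), high = sampling_rate / 2^m)
  bands <- rbind(bands, c(0, sampling_rate / 2^(levels + 1)))
  rownames(bands) <- c(paste0("d", m), paste0("a", levels))
  bands
}

.window_samples <- function(w) {
  if (inherits(w, "eeg_window")) w$samples else as.numeric(w)
}

#' Multi-level wavelet decomposition of one streaming window
#'
#' Decomposes the current window with the pyramidal sub-band scheme. To keep
#' the left edge of the window away from boundary effects (the cone of
#' influence), the transform runs on the concatenation of the previous and the
#' current window whenever a predecessor exists; the right edge (and, for a
#' first window, the left edge) is extended at every pyramid level according
#' to `config$boundary_mode` - symmetric mirror reflection by default, or
#' straight-line continuation of the edge slope (`"smooth"`). The returned
#' detail vectors are trimmed to exactly the coefficients attributable to the
#' current window - `n / 2^m` at level `m` - while the boundary-influenced
#' extras are retained internally so that [dwt_reconstruct()] is an exact
#' inverse.
#'
#' @param current The current window (`eeg_window` or numeric vector of
#'   `config$samples_per_window` samples).
#' @param previous The immediately preceding window, or `NULL` for the first
#'   window of a stream.
#' @param config An [pipeline_config()] object.
#' @return A `dwt_coefficients` object: `detail` (list of trimmed detail
#'   vectors, level 1 first), `approximation`, `wavelet`, `n`, `levels`,
#'   `level_bands`, `window_index`.
#' @export
dwt_decompose <- function(current, previous = NULL, config) {
  stopifnot(inherits(config, "eeg_pipeline_config"))
  cur <- .window_samples(current)
  n <- config$samples_per_window
  if (length(cur) != n)
    stop("current window has ", length(cur), " samples; expected ", n)
  if (!is.null(previous)) {
    if (inherits(current, "eeg_window") && inherits(previous, "eeg_window") &&
        previous$window_index != current$window_index - 1L)
      stop("`previous` is not the immediately preceding window")
    prev <- .window_samples(previous)
    if (length(prev) != n)
      stop("previous window has ", length(prev), " samples; expected ", n)
  } else {
    prev <- numeric(0)
  }

  filt <- wavelet_filters(config$mother_wavelet)
  M <- config$levels
  L <- filt$length
  sig <- c(prev, cur)
  offset <- length(prev)

  mode <- if (is.null(config$boundary_mode)) "symmetric" else config$boundary_mode
  full <- .wavedec(sig, filt, M, mode)

  # 0-based start of the current window's coefficients in each full array.
  # Level-m coefficient j is centred on signal sample 2^m j - (L-3)/2 (2^m - 1)
  # (support-centre recursion of the analysis step), so the coefficient whose
  # centre is nearest the middle of the window's first dyadic block is
  # round((offset + 2^(m-1) - 1/2 + (L-3)/2 (2^m - 1)) / 2^m). This centred
  # trim keeps the kept coefficients maximally clear of the padding-influenced
  # edges of the full arrays.
  starts <- integer(M)
  for (m in seq_len(M)) {
    want <- n %/% 2L^m
    s <- round((offset + 2^(m - 1) - 0.5 + (L - 3) / 2 * (2^m - 1)) / 2^m)
    s <- max(0L, min(as.integer(s), full$lengths[m + 1L] - want))
    starts[m] <- s
    if (s < 0 || s + want > full$lengths[m + 1L])
      stop("window too short for decomposition depth ", M,
           " with wavelet '", filt$name, "'")
  }

  detail <- lapply(seq_len(M), function(m) {
    full$details[[m]][(starts[m] + 1L):(starts[m] + n %/% 2L^m)]
  })
  approx <- full$approx[(starts[M] + 1L):(starts[M] + n %/% 2L^M)]

  structure(
    list(detail = detail,
         approximation = approx,
         wavelet = filt$name,
         n = n,
         levels = M,
         level_bands = .level_bands(M, config$sampling_rate),
         window_index = if (inherits(current, "eeg_window"))
           current$window_index else NA_integer_),
    class = "dwt_coefficients",
    full = full, starts = starts, offset = offset)
}

#' Inverse wavelet transform back to the time domain
#'
#' Reconstructs the time-domain window from a `dwt_coefficients` object. For
#' coefficients produced by [dwt_decompose()], the (possibly modified) trimmed
#' coefficients are written back over the retained full arrays and the exact
#' synthesis chain is applied, so an untouched decomposition reproduces the
#' window to machine precision. Coefficient sets constructed directly at
#' dyadic lengths (without decomposition context) are inverted with the
#' periodised synthesis filters.
#'
#' @param coeffs A `dwt_coefficients` object.
#' @param config Optional config; only used to cross-check the wavelet name.
#' @return Numeric vector of `coeffs$n` samples.
#' @export
dwt_reconstruct <- function(coeffs, config = NULL) {
  stopifnot(inherits(coeffs, "dwt_coefficients"))
  if (!is.null(config) && config$mother_wavelet != coeffs$wavelet)
    stop("config wavelet does not match the coefficients")
  filt <- wavelet_filters(coeffs$wavelet)
  n <- coeffs$n
  M <- coeffs$levels
  for (m in seq_len(M)) {
    if (length(coeffs$detail[[m]]) != n %/% 2L^m)
      stop("detail level ", m, " has inconsistent length")
  }
  if (length(coeffs$approximation) != n %/% 2L^M)
    stop("approximation has inconsistent length")

  full <- attr(coeffs, "full")
  if (!is.null(full)) {
    starts <- attr(coeffs, "starts")
    offset <- attr(coeffs, "offset")
    for (m in seq_len(M)) {
      idx <- (starts[m] + 1L):(starts[m] + n %/% 2L^m)
      full$details[[m]][idx] <- coeffs$detail[[m]]
    }
    idx <- (starts[M] + 1L):(starts[M] + n %/% 2L^M)
    full$approx[idx] <- coeffs$approximation
    sig <- .waverec(full$details, full$approx, filt, full$lengths)
    sig[(offset + 1L):(offset + n)]
  } else {
    a <- coeffs$approximation
    for (m in rev(seq_len(M)))
      a <- .idwt_step_per(a, coeffs$detail[[m]], filt)
    a
  }
}

#' Arrange wavelet coefficients as a scaleogram matrix
#'
#' Builds the time-by-scale matrix: row `m` holds the level-`m` detail
#' coefficients, each repeated `2^(m-1)` times so that every row has
#' `n / 2` columns; the final row holds the approximation coefficients
#' repeated `2^(M-1)` times. Column `j` of the matrix corresponds to samples
#' `[2(j-1), 2j)` of the window.
#'
#' @param coeffs A `dwt_coefficients` object.
#' @param window_index Optional window index stored on the scaleogram
#'   (defaults to the one recorded in `coeffs`).
#' @return A `scaleogram` object: `matrix` (`levels + 1` rows, `n / 2`
#'   columns), `normalized` flag, `window_index`, `levels`, `n`, `wavelet`,
#'   `level_bands`.
#' @export
replicate_coefficients <- function(coeffs, window_index = NULL) {
  stopifnot(inherits(coeffs, "dwt_coefficients"))
  M <- coeffs$levels
  cols <- coeffs$n %/% 2L
  rows <- lapply(seq_len(M), function(m) rep(coeffs$detail[[m]], each = 2L^(m - 1L)))
  rows[[M + 1L]] <- rep(coeffs$approximation, each = 2L^(M - 1L))
  mat <- do.call(rbind, rows)
  rownames(mat) <- rownames(coeffs$level_bands)
  structure(
    list(matrix = mat,
         normalized = FALSE,
         window_index = if (is.null(window_index)) coeffs$window_index
                        else window_index,
         levels = M,
         n = coeffs$n,
         wavelet = coeffs$wavelet,
         level_bands = coeffs$level_bands),
    class = "scaleogram",
    coeffs = coeffs)
}

#' Collapse a scaleogram back to per-level wavelet coefficients
#'
#' Removes the per-level replication by keeping the first coefficient of every
#' run of `2^(m-1)` repeated entries in row `m` (and `2^(M-1)` in the
#' approximation row). Exact inverse of [replicate_coefficients()]; when the
#' scaleogram descends from a decomposition, the reconstruction context is
#' carried over so [dwt_reconstruct()] stays exact.
#'
#' @param scaleogram A raw (non-normalised) `scaleogram`.
#' @return A `dwt_coefficients` object.
#' @export
dereplicate_scaleogram <- function(scaleogram) {
  stopifnot(inherits(scaleogram, "scaleogram"))
  if (scaleogram$normalized)
    stop("scaleogram is normalised; denormalise before dereplicating")
  mat <- scaleogram$matrix
  M <- scaleogram$levels
  cols <- ncol(mat)
  detail <- vector("list", M)
  for (m in seq_len(M)) {
    step <- 2L^(m - 1L)
    if (cols %% step != 0L)
      stop("column count ", cols, " is not divisible by 2^(m-1) at level ", m)
    detail[[m]] <- unname(mat[m, seq.int(1L, cols, by = step)])
  }
  stepA <- 2L^(M - 1L)
  approx <- unname(mat[M + 1L, seq.int(1L, cols, by = stepA)])

  src <- attr(scaleogram, "coeffs")
  out <- structure(
    list(detail = detail,
         approximation = approx,
         wavelet = scaleogram$wavelet,
         n = scaleogram$n,
         levels = M,
         level_bands = scaleogram$level_bands,
         window_index = scaleogram$window_index),
    class = "dwt_coefficients")
  if (!is.null(src)) {
    attr(out, "full") <- attr(src, "full")
    attr(out, "starts") <- attr(src, "starts")
    attr(out, "offset") <- attr(src, "offset")
  }
  out
}
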