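#' @include AllClasses.R utils.R
NULL

#' Sliding boxcar (multilook) average
#'
#' Mean over an odd square window with mirror padding; the realization of the
#' ensemble average used when forming second-order matrices. Accepts a plain
#' real/complex matrix or a \linkS4class{HermitianField} (averaged entry-wise,
#' which preserves Hermitian positive semidefiniteness by convexity).
#'
#' @param field matrix or \linkS4class{HermitianField}.
#' @param window odd window side length in pixels.
#' @return object of the same type as the input.
#' @export
boxcarFilter <- function(field, window) {
  stopifnotOddWindow(window)
  if (is(field, "HermitianField")) {
    d <- dim(field@entries)[3]
    entries <- field@entries
    for (i in seq_len(d)) for (j in seq_len(d))
      entries[, , i, j] <- boxcarMean(field@entries[, , i, j], window)
    return(new("HermitianField", entries = entries,
               window = as.integer(window) * field@window, kind = field@kind))
  }
  boxcarMean(field, window)
}

#' Local-statistics (MMSE) Lee speckle filter
#'
#' Classic Lee filter for multiplicative speckle on an intensity-like raster:
#' out = mean + k (x - mean) with adaptive gain
#' k = max(0, var - mean^2 / enl) / var, both moments over the sliding
#' window. Homogeneous regions collapse to the local mean (k -> 0),
#' heterogeneous structure is retained (k -> 1), so means are preserved and
#' edges are not displaced.
#'
#' @param x nonnegative numeric matrix (intensity or covariance diagonal).
#' @param window odd window side length (default 7, >= 3).
#' @param enl equivalent number of looks of the input (default 1,
#'   single-look).
#' @return filtered matrix.
#' @export
leeFilter <- function(x, window = 7L, enl = 1) {
  stopifnotOddWindow(window)
  if (window < 3L) stop("Lee filter window must be >= 3", call. = FALSE)
  if (!is.numeric(enl) || length(enl) != 1L || enl <= 0)
    stop("enl must be a positive scalar", call. = FALSE)
  if (any(x < 0)) stop("Lee filter expects a nonnegative raster", call. = FALSE)
  k <- leeGain(x, window, enl)
  mu <- boxcarMean(x, window)
  mu + k * (x - mu)
}

# Adaptive Lee gain from local statistics of an intensity raster.
leeGain <- function(x, window, enl) {
  mu <- boxcarMean(x, window)
  m2 <- boxcarMean(x^2, window)
  v <- pmax(m2 - mu^2, 0)
  k <- pmax(0, v - mu^2 / enl) / v
  k[v <= 0] <- 0
  k
}

#' Lee filter on a Hermitian matrix field via the span gain
#'
#' Computes the adaptive gain from the span (trace) raster and applies the
#' same per-pixel gain to every matrix entry, so the filtered field stays
#' Hermitian positive semidefinite (a convex combination of the local mean
#' field and the original).
#'
#' @param field a \linkS4class{HermitianField}.
#' @param window odd window side length (default 7).
#' @param enl equivalent number of looks of the span (default 1).
#' @return a filtered \linkS4class{HermitianField}.
#' @export
leeFilterHermitian <- function(field, window = 7L, enl = 1) {
  stopifnotOddWindow(window)
  if (enl <= 0) stop("enl must be a positive scalar", call. = FALSE)
  d <- dim(field@entries)[3]
  span <- Reduce(`+`, lapply(seq_len(d), function(i)
    Re(field@entries[, , i, i])))
  k <- leeGain(span, window, enl)
  entries <- field@entries
  for (i in seq_len(d)) for (j in seq_len(d)) {
    mu <- boxcarMean(field@entries[, , i, j], window)
    entries[, , i, j] <- mu + k * (field@entries[, , i, j] - mu)
  }
  new("HermitianField", entries = entries, window = field@window,
      kind = field@kind)
}

#' Estimate the equivalent number of looks
#'
#' ENL = mean^2 / variance of intensities over a statistically homogeneous
#' region: 1 for single-look fully developed speckle, L after an L-look
#' average.
#'
#' @param x intensity raster.
#' @param mask logical matrix selecting the homogeneous region (default all).
#' @return scalar ENL estimate.
#' @export
estimateENL <- function(x, mask = NULL) {
  v <- if (is.null(mask)) as.numeric(x) else as.numeric(x[mask])
  if (length(v) < 100)
    stop("ENL estimation needs at least 100 pixels", call. = FALSE)
  s2 <- stats::var(v)
  if (s2 <= 0) stop("degenerate (zero-variance) region", call. = FALSE)
  mean(v)^2 / s2
}
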