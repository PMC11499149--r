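# Internal numeric helpers shared across modules.

DEG <- 180 / pi

# Mirror-padded index vector for a sliding window of half-width `pad`.
mirrorIndex <- function(n, pad) {
  if (pad == 0) return(seq_len(n))
  if (pad > n) stop("window larger than raster extent", call. = FALSE)
  c(pad:1, seq_len(n), n:(n - pad + 1))
}

# Sliding boxcar mean of odd side length via a summed-area table.
# Works on real and complex matrices; mirror padding at edges.
boxcarMean <- function(m, window) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be odd and >= 1", call. = FALSE)
  if (window == 1L) return(m)
  pad <- (window - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  if (window > nr || window > nc)
    stop("window larger than raster extent", call. = FALSE)
  mp <- m[mirrorIndex(nr, pad), mirrorIndex(nc, pad), drop = FALSE]
  # summed-area table with a leading zero row/column
  cs <- apply(mp, 2L, cumsum)
  cs <- t(apply(cs, 1L, cumsum))
  z <- if (is.complex(m)) 0 + 0i else 0
  sat <- matrix(z, nrow(mp) + 1L, ncol(mp) + 1L)
  sat[-1L, -1L] <- cs
  i1 <- seq_len(nr); i2 <- i1 + window
  j1 <- seq_len(nc); j2 <- j1 + window
  out <- sat[i2, j2, drop = FALSE] - sat[i1, j2, drop = FALSE] -
    sat[i2, j1, drop = FALSE] + sat[i1, j1, drop = FALSE]
  out / window^2
}

# arctan(num/den) in degrees with the x/0 -> 90 convention; 0/0 -> NaN.
arctanRatioDeg <- function(num, den, tol = 0) {
  out <- atan2(num, den) * DEG
  out[num <= tol & den <= tol] <- NaN
  out
}

paramRaster <- function(values, name, units = "degrees",
                        validMask = is.finite(values)) {
  new("ParamRaster", values = values, name = name, units = units,
      validMask = validMask)
}

stopifnotOddWindow <- function(window) {
  if (length(window) != 1L || window < 1 || window %% 2 == 0)
    stop("window must be a single odd integer >= 1", call. = FALSE)
}
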