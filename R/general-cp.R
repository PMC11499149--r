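#' @include AllClasses.R utils.R
NULL

# Jones amplitudes of the transmit ellipse:
# a = cos(theta)cos(chi) - j sin(theta)sin(chi)
# b = sin(theta)cos(chi) + j cos(theta)sin(chi)
jonesAmplitudes <- function(theta, chi) {
  list(a = complex(real = cos(theta) * cos(chi),
                   imaginary = -sin(theta) * sin(chi)),
       b = complex(real = sin(theta) * cos(chi),
                   imaginary = cos(theta) * sin(chi)))
}

#' Construct a transmit polarization ellipse
#'
#' Builds the fully polarized transmit wave for orientation angle
#' \code{theta} and ellipticity angle \code{chi}, deriving the unit-norm
#' complex Jones amplitudes (a, b). The linear pi/4 mode is (pi/4, 0),
#' horizontal transmit is (0, 0) and right-circular transmit is
#' (theta, -pi/4) for any theta.
#'
#' @param theta orientation angle in radians, in [-pi/2, pi/2].
#' @param chi ellipticity angle in radians, in [-pi/4, pi/4].
#' @return A \linkS4class{TransmitWave}.
#' @examples
#' w <- transmitWave(pi / 4, 0)
#' waveAmplitudes(w)  # a = b = 1/sqrt(2)
#' @export
transmitWave <- function(theta, chi) {
  if (!is.numeric(theta) || length(theta) != 1L || abs(theta) > pi / 2 + 1e-12)
    stop("theta must be a scalar in [-pi/2, pi/2]", call. = FALSE)
  if (!is.numeric(chi) || length(chi) != 1L || abs(chi) > pi / 4 + 1e-12)
    stop("chi must be a scalar in [-pi/4, pi/4]", call. = FALSE)
  ab <- jonesAmplitudes(theta, chi)
  new("TransmitWave", theta = theta, chi = chi, a = ab$a, b = ab$b)
}

#' Transmit-wave amplitudes
#' @param wave a \linkS4class{TransmitWave}.
#' @return named list with complex elements \code{a} and \code{b}.
#' @export
waveAmplitudes <- function(wave) list(a = wave@a, b = wave@b)

#' Transmit-wave ellipse angles (radians)
#' @param wave a \linkS4class{TransmitWave}.
#' @return named numeric vector c(theta, chi).
#' @export
waveAngles <- function(wave) c(theta = wave@theta, chi = wave@chi)

#' Full-pol Pauli target vector
#'
#' Per-pixel three-component Pauli vector
#' k = (1/sqrt(2)) (S_HH + S_VV, S_HH - S_VV, 2 S_HV),
#' using the reciprocal cross-pol channel.
#'
#' @param img a \linkS4class{ScatteringImage}.
#' @return list of three complex matrices \code{k1}, \code{k2}, \code{k3}.
#' @export
fpTargetVector <- function(img) {
  s2 <- sqrt(2)
  hv <- (img@shv + img@svh) / 2  # reciprocity: average the cross channels
  list(k1 = (img@shh + img@svv) / s2,
       k2 = (img@shh - img@svv) / s2,
       k3 = 2 * hv / s2)
}

hermitianFromChannels <- function(chans, window, kind) {
  d <- length(chans)
  nr <- nrow(chans[[1]]); nc <- ncol(chans[[1]])
  entries <- array(0 + 0i, c(nr, nc, d, d))
  for (i in seq_len(d)) for (j in i:d) {
    v <- boxcarMean(chans[[i]] * Conj(chans[[j]]), window)
    if (i == j) v <- complex(real = pmax(Re(v), 0), imaginary = 0)
    entries[, , i, j] <- v
    if (i != j) entries[, , j, i] <- Conj(v)
  }
  new("HermitianField", entries = entries, window = as.integer(window),
      kind = kind)
}

#' Full-pol coherency matrix field (T3)
#'
#' Ensemble-averaged outer product of the Pauli target vector over a sliding
#' boxcar window (mirror padding at edges). Hermitian positive semidefinite
#' by construction.
#'
#' @param img a \linkS4class{ScatteringImage}.
#' @param window odd averaging window side length in pixels (default 7).
#' @return a \linkS4class{HermitianField} of kind \code{"T3"}.
#' @export
fpCoherency <- function(img, window = 7L) {
  stopifnotOddWindow(window)
  hermitianFromChannels(fpTargetVector(img), window, "T3")
}

#' Classic compact-pol scattering vectors (pi/4 and CTLR modes)
#'
#' Dedicated two-channel CP vectors:
#' pi/4 mode (45-degree linear transmit, H/V receive)
#' k = (1/sqrt(2)) (S_HH + S_HV, S_VV + S_HV);
#' CTLR mode (right-circular transmit, H/V receive)
#' k = (1/sqrt(2)) (S_HH - i S_HV, S_HV - i S_VV).
#'
#' @param img a \linkS4class{ScatteringImage}.
#' @param mode \code{"pi4"} or \code{"ctlr"}.
#' @return list of two complex matrices \code{v1}, \code{v2}.
#' @export
classicCPVector <- function(img, mode = c("pi4", "ctlr")) {
  mode <- match.arg(mode)
  hv <- (img@shv + img@svh) / 2
  s2 <- sqrt(2)
  if (mode == "pi4")
    list(v1 = (img@shh + hv) / s2, v2 = (img@svv + hv) / s2)
  else
    list(v1 = (img@shh - 1i * hv) / s2, v2 = (hv - 1i * img@svv) / s2)
}

#' Normalize a classic CP vector into the general CP channel field
#'
#' Applies the per-channel normalization by (1/a, 1/b) of the corresponding
#' transmit wave, mapping the dedicated pi/4 or CTLR vector onto the general
#' CP channels (E1, E2) so that both routes produce identical decomposition
#' parameters.
#'
#' @param vec list \code{(v1, v2)} from \code{\link{classicCPVector}}.
#' @param mode \code{"pi4"} or \code{"ctlr"}.
#' @return a \linkS4class{CPField}.
#' @export
cpFieldFromClassic <- function(vec, mode = c("pi4", "ctlr")) {
  mode <- match.arg(mode)
  wave <- if (mode == "pi4") transmitWave(pi / 4, 0)
          else transmitWave(0, -pi / 4)
  # classic vectors are E_r (theta, chi) itself times a fixed layout; undo the
  # (a, b) weights channel-wise
  new("CPField", e1 = vec$v1 / wave@a, e2 = vec$v2 / wave@b, wave = wave)
}

#' General compact-pol channel field for an arbitrary transmit ellipse
#'
#' Synthesizes the normalized CP backscatter channels from a quad-pol image:
#' E1 = S_HH + (b/a) S_HV, E2 = S_VV + (a/b) S_HV (reciprocity assumed).
#' The pure-H and pure-V transmit states (a = 0 or b = 0) are outside the
#' normalization's domain and are rejected.
#'
#' @param img a \linkS4class{ScatteringImage}.
#' @param wave a \linkS4class{TransmitWave} with both amplitudes nonzero.
#' @param eps singularity guard on |a| and |b| (default 1e-8).
#' @return a \linkS4class{CPField}.
#' @export
generalCPField <- function(img, wave, eps = 1e-8) {
  if (Mod(wave@a) <= eps || Mod(wave@b) <= eps)
    stop("unsupported CP mode: the general normalization requires a != 0 and ",
         "b != 0 (pure H or V transmit is singular)", call. = FALSE)
  hv <- (img@shv + img@svh) / 2
  new("CPField",
      e1 = img@shh + (wave@b / wave@a) * hv,
      e2 = img@svv + (wave@a / wave@b) * hv,
      wave = wave)
}

#' Second-order CP statistics (C2 and T2)
#'
#' Sliding-window ensemble averages of the general CP channels:
#' C2 from k1 = (E1, E2) and T2 from k2 = (E1 + E2, E1 - E2)/sqrt(2).
#' Their traces agree to rounding.
#'
#' @param cp a \linkS4class{CPField}.
#' @param window odd averaging window (default 7).
#' @return named list with \code{c2} and \code{t2}
#'   (\linkS4class{HermitianField}s).
#' @export
cpSecondOrder <- function(cp, window = 7L) {
  stopifnotOddWindow(window)
  s2 <- sqrt(2)
  c2 <- hermitianFromChannels(list(cp@e1, cp@e2), window, "C2")
  t2 <- hermitianFromChannels(list((cp@e1 + cp@e2) / s2,
                                   (cp@e1 - cp@e2) / s2), window, "T2")
  list(c2 = c2, t2 = t2)
}

#' Extract one entry of a Hermitian field as a matrix
#' @param field a \linkS4class{HermitianField}.
#' @param i,j entry indices (1-based).
#' @return complex matrix of the (i, j) entry per pixel.
#' @export
fieldEntry <- function(field, i, j) {
  m <- field@entries[, , i, j]
  dim(m) <- dim(field@entries)[1:2]
  m
}

#' Whole-raster ensemble average of a Hermitian field
#'
#' Averages the per-pixel matrices over the full raster, giving the global
#' d x d second-order matrix (the large-sample ensemble estimate when the
#' raster is one homogeneous region).
#'
#' @param field a \linkS4class{HermitianField}.
#' @return complex d x d Hermitian matrix.
#' @export
globalCoherency <- function(field) {
  d <- dim(field@entries)[3]
  M <- matrix(0 + 0i, d, d)
  for (i in seq_len(d)) for (j in seq_len(d))
    M[i, j] <- mean(field@entries[, , i, j])
  M
}
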