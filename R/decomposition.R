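#' @include AllClasses.R utils.R general-cp.R
NULL

#' Average scattering-mechanism angle from a full-pol coherency field
#'
#' alpha_B = arctan((T22 + T33) / T11) in degrees, range [0, 90]. Rotation
#' invariant about the radar line of sight: the Pauli rotation mixes only the
#' second and third coherency channels, leaving T22 + T33 and T11 unchanged.
#' T11 = 0 with a positive numerator maps to 90 degrees; 0/0 pixels are
#' masked invalid.
#'
#' @param t3 a \linkS4class{HermitianField} of kind \code{"T3"}.
#' @return a \linkS4class{ParamRaster} named \code{"alpha_B"} in degrees.
#' @export
alphaBFP <- function(t3) {
  if (t3@kind != "T3") stop("alphaBFP requires a T3 field", call. = FALSE)
  t11 <- Re(fieldEntry(t3, 1, 1))
  t22 <- Re(fieldEntry(t3, 2, 2))
  t33 <- Re(fieldEntry(t3, 3, 3))
  sc <- max(t11 + t22 + t33, .Machine$double.eps)
  if (min(t11, t22, t33) < -1e-10 * sc)
    stop("negative coherency diagonal beyond tolerance", call. = FALSE)
  vals <- arctanRatioDeg(pmax(t22 + t33, 0), pmax(t11, 0))
  paramRaster(vals, "alpha_B")
}

#' Full-pol co-polar channel statistics
#'
#' Windowed second-order co-pol statistics of a quad-pol image:
#' \itemize{
#'   \item \code{rho}: modulus sqrt(<|S_VV|^2>/<|S_HH|^2>) (amplitude ratio)
#'     with argument arg(<S_VV S_HH*>), the circular-mean co-pol phase
#'     difference (wrap-robust, unlike averaging per-pixel phases);
#'   \item \code{r}: normalized complex cross-correlation
#'     <S_VV S_HH*> / sqrt(<|S_HH|^2><|S_VV|^2>).
#' }
#' Pixels with zero HH power are masked invalid.
#'
#' @param img a \linkS4class{ScatteringImage}.
#' @param window odd averaging window (default 7).
#' @return a \linkS4class{CoPolStats}.
#' @export
copolStatsFP <- function(img, window = 7L) {
  stopifnotOddWindow(window)
  phh <- Re(boxcarMean(img@shh * Conj(img@shh), window))
  pvv <- Re(boxcarMean(img@svv * Conj(img@svv), window))
  cross <- boxcarMean(img@svv * Conj(img@shh), window)
  channelStats(phh, pvv, cross)
}

# Shared rho/r assembly for the FP and CP flavors; `cross` is <ch2 ch1*>.
channelStats <- function(p1, p2, cross) {
  valid <- p1 > 0
  p1s <- p1
  p1s[!valid] <- NA_real_
  modRho <- sqrt(p2 / p1s)
  phase <- Arg(cross)
  rho <- complex(modulus = modRho, argument = phase)
  denom <- sqrt(p1s * p2)
  r <- cross
  pos <- !is.na(denom) & denom > 0
  r[pos] <- cross[pos] / denom[pos]
  r[!pos] <- 0 + 0i
  big <- Mod(r) > 1
  r[big] <- r[big] / Mod(r[big])  # rounding guard
  rho[!valid] <- NaN + 0i
  r[!valid] <- NaN + 0i
  dim(rho) <- dim(p1)
  dim(r) <- dim(p1)
  vm <- valid & is.finite(modRho)
  vm[is.na(vm)] <- FALSE
  new("CoPolStats", rho = rho, r = r, validMask = vm)
}

#' Ideal scattering-mechanism angle from the channel ratio
#'
#' alpha_0 = arctan(|rho - 1|^2 / |rho + 1|^2) in degrees. rho = 1 gives 0
#' (ideal surface), rho = -1 gives 90 (ideal double bounce). Applies to both
#' the full-pol ratio rho_r and the CP ratio rho_CP.
#'
#' @param stats a \linkS4class{CoPolStats}.
#' @return a \linkS4class{ParamRaster} named \code{"alpha_0"} in degrees.
#' @export
alphaZero <- function(stats) {
  num <- Mod(stats@rho - 1)^2
  den <- Mod(stats@rho + 1)^2
  vals <- atan2(num, den) * DEG
  vals[!stats@validMask] <- NaN
  paramRaster(vals, "alpha_0")
}

#' Scattering-randomness angle
#'
#' delta-alpha = alpha - alpha_0, element-wise in degrees. Positive for
#' randomness with co-pol phase near 0 (surface/volume), negative near pi
#' (double bounce).
#'
#' @param alpha,alpha0 co-registered \linkS4class{ParamRaster}s in degrees.
#' @return a \linkS4class{ParamRaster} named \code{"delta_alpha"}.
#' @export
deltaAlpha <- function(alpha, alpha0) {
  if (!identical(dim(alpha@values), dim(alpha0@values)))
    stop("alpha and alpha0 rasters are not co-registered", call. = FALSE)
  vals <- alpha@values - alpha0@values
  paramRaster(vals, "delta_alpha",
              validMask = alpha@validMask & alpha0@validMask)
}

#' Average scattering-mechanism angle from a CP coherency field
#'
#' alpha_BCP = arctan(<|E1 - E2|^2> / <|E1 + E2|^2>) in degrees, [0, 90].
#' Ideal surface (E1 = E2) gives 0, ideal double bounce (E1 = -E2) gives 90,
#' fully decorrelated equal-power channels give 45. Zero-power pixels
#' (0/0) are masked invalid.
#'
#' @param t2 a \linkS4class{HermitianField} of kind \code{"T2"} from
#'   \code{\link{cpSecondOrder}}.
#' @return a \linkS4class{ParamRaster} named \code{"alpha_BCP"} in degrees.
#' @export
alphaBCP <- function(t2) {
  if (t2@kind != "T2") stop("alphaBCP requires a T2 field", call. = FALSE)
  num <- pmax(Re(fieldEntry(t2, 2, 2)), 0)  # <|E1-E2|^2>/2
  den <- pmax(Re(fieldEntry(t2, 1, 1)), 0)  # <|E1+E2|^2>/2
  paramRaster(arctanRatioDeg(num, den), "alpha_BCP")
}

#' CP channel statistics (rho_CP, r_CP, phi_CP)
#'
#' Windowed channel ratio, correlation coefficient and phase difference of
#' the general CP channels:
#' |rho_CP| = sqrt(<|E2|^2>/<|E1|^2>), phi_CP = arg(<E2 E1*>),
#' r_CP = <E1 E2*> / sqrt(<|E1|^2><|E2|^2>). Zero-power pixels are masked.
#'
#' @param cp a \linkS4class{CPField}.
#' @param window odd averaging window (default 7).
#' @return a \linkS4class{CoPolStats}; \code{rho} holds rho_CP (modulus and
#'   phase), \code{r} holds the conjugate-symmetric correlation with
#'   \code{Mod(r)} = |r_CP|.
#' @export
cpChannelStats <- function(cp, window = 7L) {
  stopifnotOddWindow(window)
  p1 <- Re(boxcarMean(cp@e1 * Conj(cp@e1), window))
  p2 <- Re(boxcarMean(cp@e2 * Conj(cp@e2), window))
  cross <- boxcarMean(cp@e2 * Conj(cp@e1), window)
  channelStats(p1, p2, cross)
}

#' Consistency of the expanded alpha_BCP closed form
#'
#' Diagnostic comparison between the direct channel-power definition of
#' alpha_BCP and its expansion in terms of the channel ratio, correlation
#' coefficient and phase difference, evaluated under the reading that the
#' decorrelation factor is (1 - |r_CP|):
#' arctan((|1 - rho|^2 + 2 |rho| cos(phi) (1 - |r|)) /
#'        (|1 + rho|^2 - 2 |rho| cos(phi) (1 - |r|))).
#' The expansion's parenthetical factor is typeset ambiguously in the
#' literature ((1 - |rho|) is the alternative); the direct form is
#' authoritative and this function only reports deviations.
#'
#' @param t2 a \linkS4class{HermitianField} of kind \code{"T2"}.
#' @param stats \linkS4class{CoPolStats} from the same field and window.
#' @param factor \code{"r"} (default) or \code{"rho"}: which modulus enters
#'   the (1 - |.|) decorrelation factor.
#' @return list with \code{maxAbsDev} and \code{meanAbsDev} (degrees) and the
#'   per-pixel \code{deviation} \linkS4class{ParamRaster}.
#' @export
expansionConsistency <- function(t2, stats, factor = c("r", "rho")) {
  factor <- match.arg(factor)
  direct <- alphaBCP(t2)
  modRho <- Mod(stats@rho)
  phi <- Arg(stats@rho)
  decor <- 1 - (if (factor == "r") Mod(stats@r) else modRho)
  term <- 2 * modRho * cos(phi) * decor
  num <- Mod(stats@rho - 1)^2 + term
  den <- Mod(stats@rho + 1)^2 - term
  expanded <- atan2(num, den) * DEG
  dev <- abs(expanded - direct@values)
  ok <- stats@validMask & direct@validMask & is.finite(dev)
  dev[!ok] <- NaN
  list(maxAbsDev = if (any(ok)) max(dev[ok]) else NaN,
       meanAbsDev = if (any(ok)) mean(dev[ok]) else NaN,
       deviation = paramRaster(dev, "alpha_BCP_expansion_dev",
                               validMask = ok))
}

#' Full-pol delta-alpha/alpha decomposition
#'
#' Computes alpha_B from the windowed T3 coherency, alpha_0 from the co-pol
#' channel ratio and delta-alpha_B = alpha_B - alpha_0.
#'
#' @param img a \linkS4class{ScatteringImage}.
#' @param window odd averaging window (default 7).
#' @return a \linkS4class{DecompResult} with flavor \code{"fp"}.
#' @export
decomposeFP <- function(img, window = 7L) {
  t3 <- fpCoherency(img, window)
  alpha <- alphaBFP(t3)
  stats <- copolStatsFP(img, window)
  a0 <- alphaZero(stats)
  new("DecompResult", alpha = alpha, alpha0 = a0,
      deltaAlpha = deltaAlpha(alpha, a0), stats = stats, flavor = "fp")
}

#' Compact-pol delta-alpha/alpha decomposition
#'
#' Synthesizes the general CP channels for a transmit ellipse (or a classic
#' pi/4 / CTLR mode), forms the windowed T2 coherency and computes
#' alpha_BCP, alpha_0CP and delta-alpha_BCP.
#'
#' @param img a \linkS4class{ScatteringImage}.
#' @param wave a \linkS4class{TransmitWave}; ignored when \code{mode} given.
#' @param mode optional \code{"pi4"} or \code{"ctlr"} shortcut routed through
#'   the dedicated classic vectors plus the general normalization.
#' @param window odd averaging window (default 7).
#' @return a \linkS4class{DecompResult} with flavor \code{"cp"}.
#' @export
decomposeCP <- function(img, wave = NULL, mode = NULL, window = 7L) {
  cp <- if (!is.null(mode)) cpFieldFromClassic(classicCPVector(img, mode), mode)
        else {
          if (is.null(wave)) stop("either wave or mode required", call. = FALSE)
          generalCPField(img, wave)
        }
  so <- cpSecondOrder(cp, window)
  alpha <- alphaBCP(so$t2)
  alpha@name <- "alpha_BCP"
  stats <- cpChannelStats(cp, window)
  a0 <- alphaZero(stats)
  a0@name <- "alpha_0CP"
  da <- deltaAlpha(alpha, a0)
  da@name <- "delta_alpha_BCP"
  new("DecompResult", alpha = alpha, alpha0 = a0, deltaAlpha = da,
      stats = stats, flavor = "cp")
}

#' Accessors for decomposition rasters
#' @param x a \linkS4class{DecompResult}.
#' @return the requested \linkS4class{ParamRaster}.
#' @name decomp-accessors
NULL

#' @rdname decomp-accessors
#' @export
alphaRaster <- function(x) x@alpha

#' @rdname decomp-accessors
#' @export
alphaZeroRaster <- function(x) x@alpha0

#' @rdname decomp-accessors
#' @export
deltaAlphaRaster <- function(x) x@deltaAlpha

#' Values of a parameter raster
#' @param x a \linkS4class{ParamRaster}.
#' @return numeric matrix (NaN on invalid pixels).
#' @export
paramValues <- function(x) x@values

#' Scattering-mechanism angle of a single coherency matrix
#'
#' Evaluates the decomposition angle on one Hermitian matrix (e.g. from
#' \code{\link{globalCoherency}}): arctan((T22 + T33)/T11) for a 3x3 T3,
#' arctan(T22/T11) = arctan(<|E1 - E2|^2>/<|E1 + E2|^2>) for a 2x2 T2.
#' The x/0 convention maps a positive numerator over zero to 90 degrees.
#'
#' @param M complex Hermitian matrix, 2x2 (T2) or 3x3 (T3).
#' @return angle in degrees, [0, 90].
#' @export
alphaFromMatrix <- function(M) {
  d <- nrow(M)
  if (d == 3L)
    atan2(Re(M[2, 2] + M[3, 3]), Re(M[1, 1])) * DEG
  else if (d == 2L)
    atan2(Re(M[2, 2]), Re(M[1, 1])) * DEG
  else stop("expected a 2x2 or 3x3 matrix", call. = FALSE)
}
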