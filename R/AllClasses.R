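#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Quad-pol scattering-matrix raster
#'
#' Per-pixel 2x2 complex Sinclair matrix, stored as four co-registered complex
#' rasters (linear amplitude, dimensionless). Monostatic backscatter is
#' assumed, so simulator-built images satisfy \code{svh == shv} element-wise;
#' images read from files keep both channels as stored.
#'
#' @slot shh,shv,svh,svv complex matrices, identical dimensions.
#' @slot dateTag free-text acquisition tag, e.g. \code{"2015-06-12"}.
#' @slot pixelSpacing optional azimuth x range spacing in metres.
#' @exportClass ScatteringImage
setClass("ScatteringImage",
  representation(shh = "matrix", shv = "matrix", svh = "matrix",
                 svv = "matrix", dateTag = "character",
                 pixelSpacing = "numericOrNULL"),
  prototype(dateTag = "", pixelSpacing = NULL))

setValidity("ScatteringImage", function(object) {
  d <- dim(object@shh)
  for (ch in c("shv", "svh", "svv"))
    if (!identical(dim(slot(object, ch)), d))
      return(sprintf("channel '%s' dimensions differ from shh", ch))
  for (ch in c("shh", "shv", "svh", "svv"))
    if (!is.complex(slot(object, ch)))
      return(sprintf("channel '%s' must be a complex matrix", ch))
  for (ch in c("shh", "shv", "svh", "svv"))
    if (any(!is.finite(Re(slot(object, ch))) | !is.finite(Im(slot(object, ch)))))
      return(sprintf("channel '%s' contains non-finite values", ch))
  TRUE
})

#' Transmit polarization ellipse
#'
#' Fully polarized transmit state parameterized by the ellipse orientation
#' angle theta (radians, [-pi/2, pi/2]) and ellipticity angle chi (radians,
#' [-pi/4, pi/4]). The complex Jones amplitudes (a, b) are derived from the
#' angles and satisfy |a|^2 + |b|^2 = 1.
#'
#' @slot theta,chi ellipse angles in radians.
#' @slot a,b derived complex transmit amplitudes.
#' @exportClass TransmitWave
setClass("TransmitWave",
  representation(theta = "numeric", chi = "numeric",
                 a = "complex", b = "complex"))

setValidity("TransmitWave", function(object) {
  if (abs(object@theta) > pi / 2 + 1e-12) return("theta outside [-pi/2, pi/2]")
  if (abs(object@chi) > pi / 4 + 1e-12) return("chi outside [-pi/4, pi/4]")
  ab <- jonesAmplitudes(object@theta, object@chi)
  if (abs(Mod(object@a)^2 + Mod(object@b)^2 - 1) > 1e-12)
    return("|a|^2 + |b|^2 must equal 1")
  if (Mod(object@a - ab$a) > 1e-12 || Mod(object@b - ab$b) > 1e-12)
    return("(a, b) do not regenerate from (theta, chi)")
  TRUE
})

#' Compact-polarimetric channel field
#'
#' Normalized CP backscatter channels E1 and E2 synthesized from a quad-pol
#' image for a given transmit ellipse: E1 = S_HH + (b/a) S_HV and
#' E2 = S_VV + (a/b) S_HV under reciprocity.
#'
#' @slot e1,e2 complex rasters of the normalized channels.
#' @slot wave the \linkS4class{TransmitWave} used for synthesis.
#' @exportClass CPField
setClass("CPField",
  representation(e1 = "matrix", e2 = "matrix", wave = "TransmitWave"))

setValidity("CPField", function(object) {
  if (!identical(dim(object@e1), dim(object@e2)))
    return("e1 and e2 dimensions differ")
  TRUE
})

#' Per-pixel Hermitian second-order matrix field
#'
#' Ensemble-averaged coherency/covariance matrices: 2x2 (C2/T2, compact pol)
#' or 3x3 (T3, full pol). Entries are stored as an array with dimensions
#' (rows, cols, d, d).
#'
#' @slot entries complex array (rows, cols, d, d).
#' @slot window odd ensemble-averaging window side length in pixels.
#' @slot kind one of \code{"C2"}, \code{"T2"}, \code{"T3"}.
#' @exportClass HermitianField
setClass("HermitianField",
  representation(entries = "array", window = "integer", kind = "character"))

setValidity("HermitianField", function(object) {
  dm <- dim(object@entries)
  if (length(dm) != 4L || dm[3] != dm[4])
    return("entries must be a (rows, cols, d, d) array")
  if (!object@kind %in% c("C2", "T2", "T3"))
    return("kind must be one of C2, T2, T3")
  if ((object@kind == "T3") != (dm[3] == 3L))
    return("matrix dimension inconsistent with kind")
  d <- dm[3]
  # Hermitian symmetry and a real, near-nonnegative diagonal; PSD is checked
  # on a deterministic pixel subsample to keep validation cheap.
  sc <- max(abs(object@entries))
  if (sc == 0) sc <- 1
  for (i in seq_len(d)) for (j in seq_len(d)) {
    dev <- max(abs(object@entries[, , i, j] - Conj(object@entries[, , j, i])))
    if (dev > 1e-10 * sc) return("entries are not Hermitian")
  }
  for (i in seq_len(d)) {
    di <- object@entries[, , i, i]
    if (max(abs(Im(di))) > 1e-10 * sc) return("diagonal not real")
    if (min(Re(di)) < -1e-10 * sc) return("diagonal negative beyond tolerance")
  }
  ri <- unique(round(seq(1, dm[1], length.out = min(5, dm[1]))))
  ci <- unique(round(seq(1, dm[2], length.out = min(5, dm[2]))))
  for (r in ri) for (cc in ci) {
    M <- matrix(object@entries[r, cc, , ], d, d)
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    tr <- sum(Re(diag(M)))
    if (min(ev) < -1e-8 * max(tr, .Machine$double.eps))
      return("sampled pixel matrix not positive semidefinite")
  }
  TRUE
})

#' Real-valued parameter raster with validity mask
#'
#' Decomposition outputs (alpha, alpha_0, delta-alpha) and other scalar
#' rasters. Invalid pixels carry NaN and are flagged in \code{validMask};
#' they are never silently zero.
#'
#' @slot values numeric matrix; NaN outside the valid mask.
#' @slot name short identifier, e.g. \code{"alpha_B"}.
#' @slot units \code{"degrees"} or \code{"dimensionless"}.
#' @slot validMask logical matrix of the same shape.
#' @exportClass ParamRaster
setClass("ParamRaster",
  representation(values = "matrix", name = "character", units = "character",
                 validMask = "matrix"))

setValidity("ParamRaster", function(object) {
  if (!identical(dim(object@values), dim(object@validMask)))
    return("values and validMask dimensions differ")
  if (!is.logical(object@validMask)) return("validMask must be logical")
  if (any(!is.finite(object@values[object@validMask])))
    return("non-finite values inside the valid mask")
  TRUE
})

#' Class-label raster with per-parcel train/verify split
#'
#' @slot labels integer matrix; 0 = unlabeled, 1..K = classes.
#' @slot classNames names of the K classes.
#' @slot parcels integer matrix of parcel ids (0 = background).
#' @slot parcelInfo data.frame with columns parcel, class, split
#'   (split in \code{"train"}/\code{"verify"}).
#' @exportClass LabelMask
setClass("LabelMask",
  representation(labels = "matrix", classNames = "character",
                 parcels = "matrix", parcelInfo = "data.frame"))

setValidity("LabelMask", function(object) {
  if (!identical(dim(object@labels), dim(object@parcels)))
    return("labels and parcels dimensions differ")
  K <- length(object@classNames)
  if (any(object@labels < 0) || any(object@labels > K))
    return("label exceeds class-table length")
  if (nrow(object@parcelInfo) &&
      !all(object@parcelInfo$split %in% c("train", "verify")))
    return("split entries must be 'train' or 'verify'")
  TRUE
})

#' Co-polar channel statistics
#'
#' Complex channel ratio rho (modulus = amplitude ratio, argument = circular
#' mean co-pol phase difference) and the normalized complex correlation
#' coefficient r, per pixel.
#'
#' @slot rho,r complex matrices.
#' @slot validMask logical matrix.
#' @exportClass CoPolStats
setClass("CoPolStats",
  representation(rho = "matrix", r = "matrix", validMask = "matrix"))

setValidity("CoPolStats", function(object) {
  if (!identical(dim(object@rho), dim(object@r)) ||
      !identical(dim(object@rho), dim(object@validMask)))
    return("rho, r and validMask dimensions differ")
  if (any(Mod(object@r[object@validMask]) > 1 + 1e-9))
    return("|r| exceeds 1 beyond tolerance")
  TRUE
})

#' Delta-alpha/alpha decomposition result
#'
#' Co-registered rasters of alpha (average scattering mechanism, degrees in
#' [0, 90]), alpha_0 (ideal mechanism implied by the channel ratio alone) and
#' delta-alpha = alpha - alpha_0 (scattering randomness, signed by the co-pol
#' phase difference), plus the channel statistics they derive from.
#'
#' @slot alpha,alpha0,deltaAlpha \linkS4class{ParamRaster}s in degrees.
#' @slot stats \linkS4class{CoPolStats}.
#' @slot flavor \code{"fp"} (full pol) or \code{"cp"} (compact pol).
#' @exportClass DecompResult
setClass("DecompResult",
  representation(alpha = "ParamRaster", alpha0 = "ParamRaster",
                 deltaAlpha = "ParamRaster", stats = "CoPolStats",
                 flavor = "character"))

setValidity("DecompResult", function(object) {
  if (!object@flavor %in% c("fp", "cp")) return("flavor must be 'fp' or 'cp'")
  ok <- object@alpha@validMask & object@alpha0@validMask &
    object@deltaAlpha@validMask
  dev <- object@deltaAlpha@values[ok] -
    (object@alpha@values[ok] - object@alpha0@values[ok])
  if (length(dev) && max(abs(dev)) > 0)
    return("deltaAlpha must equal alpha - alpha0 exactly on valid pixels")
  TRUE
})

#' Scattering-mechanism mixture specification
#'
#' Second-order scattering model of one land-cover class at one date: power
#' fractions of surface, double-bounce and volume mechanisms, the co-pol
#' power ratio and complex coherence of the polarized part, and the total
#' backscattered power.
#'
#' @slot fSurface,fDouble,fVolume nonnegative fractions summing to 1.
#' @slot copolRatio <|S_VV|^2>/<|S_HH|^2> of the coherent part, > 0.
#' @slot copolCoherence complex co-pol coherence magnitude factor, |.| <= 1.
#' @slot totalPower total power (trace of C3), linear units.
#' @exportClass MixtureSpec
setClass("MixtureSpec",
  representation(fSurface = "numeric", fDouble = "numeric",
                 fVolume = "numeric", copolRatio = "numeric",
                 copolCoherence = "complex", totalPower = "numeric"))

setValidity("MixtureSpec", function(object) {
  f <- c(object@fSurface, object@fDouble, object@fVolume)
  if (any(f < 0)) return("mixture fractions must be nonnegative")
  if (abs(sum(f) - 1) > 1e-9) return("mixture fractions must sum to 1")
  if (object@copolRatio <= 0) return("copolRatio must be positive")
  if (Mod(object@copolCoherence) > 1 + 1e-12)
    return("|copolCoherence| must not exceed 1")
  if (object@totalPower <= 0) return("totalPower must be positive")
  TRUE
})

#' Per-class, per-date phenology schedule
#'
#' Six acquisition dates with crop growth-stage labels and one
#' \linkS4class{MixtureSpec} per class per date, driving the scene simulator.
#'
#' @slot dates six date tags.
#' @slot stages six growth-stage labels.
#' @slot specs named list (one entry per class) of six-element MixtureSpec lists.
#' @exportClass PhenologySchedule
setClass("PhenologySchedule",
  representation(dates = "character", stages = "character", specs = "list"))

setValidity("PhenologySchedule", function(object) {
  if (length(object@dates) != 6L) return("exactly six dates are required")
  if (length(object@stages) != 6L) return("exactly six stage labels required")
  for (cl in names(object@specs)) {
    s <- object@specs[[cl]]
    if (length(s) != 6L)
      return(sprintf("class '%s' must have six date specs", cl))
    if (!all(vapply(s, is, TRUE, class2 = "MixtureSpec")))
      return(sprintf("class '%s' entries must be MixtureSpec", cl))
  }
  TRUE
})

#' Rectangular parcel layout of a simulated scene
#'
#' @slot rows,cols scene size in pixels.
#' @slot parcels data.frame with columns row, col, height, width, class
#'   (integer id), split ("train"/"verify").
#' @slot classNames class names indexed by class id.
#' @exportClass ParcelLayout
setClass("ParcelLayout",
  representation(rows = "integer", cols = "integer", parcels = "data.frame",
                 classNames = "character"))

setValidity("ParcelLayout", function(object) {
  p <- object@parcels
  need <- c("row", "col", "height", "width", "class", "split")
  if (!all(need %in% names(p))) return("parcels lacks required columns")
  if (any(p$row < 1 | p$col < 1 | p$row + p$height - 1 > object@rows |
          p$col + p$width - 1 > object@cols))
    return("parcel outside scene bounds")
  occ <- matrix(FALSE, object@rows, object@cols)
  for (i in seq_len(nrow(p))) {
    ri <- p$row[i]:(p$row[i] + p$height[i] - 1)
    ci <- p$col[i]:(p$col[i] + p$width[i] - 1)
    if (any(occ[ri, ci])) return("parcels overlap")
    occ[ri, ci] <- TRUE
  }
  for (k in seq_along(object@classNames))
    if (sum(p$class == k) < 2)
      return(sprintf("class '%s' needs at least 2 parcels for a split",
                     object@classNames[k]))
  TRUE
})

#' Named multi-date feature stack
#'
#' @slot features named list of co-registered numeric matrices; names encode
#'   parameter x date x mode (e.g. \code{"alpha_B_1103_pi4"}).
#' @slot dates date tags covered by the stack.
#' @slot mode \code{"fp"}, \code{"pi4"}, \code{"ctlr"} or \code{"general"}.
#' @exportClass FeatureStack
setClass("FeatureStack",
  representation(features = "list", dates = "character", mode = "character"))

setValidity("FeatureStack", function(object) {
  if (is.null(names(object@features)) || anyDuplicated(names(object@features)))
    return("features must have unique names")
  d <- dim(object@features[[1]])
  for (f in object@features)
    if (!identical(dim(f), d)) return("feature rasters not co-registered")
  TRUE
})

#' Classification accuracy report
#'
#' Confusion matrix over verification pixels (rows = predicted,
#' columns = reference) with producer's/user's accuracy, their mean, overall
#' accuracy and the kappa coefficient.
#'
#' @slot confusion integer matrix, predicted x reference.
#' @slot pa,ua,averageAccuracy per-class percentages (NA when undefined).
#' @slot oa overall accuracy, percent.
#' @slot kappa chance-corrected agreement in [-1, 1].
#' @slot classNames class names.
#' @exportClass AccuracyReport
setClass("AccuracyReport",
  representation(confusion = "matrix", pa = "numeric", ua = "numeric",
                 averageAccuracy = "numeric", oa = "numeric", kappa = "numeric",
                 classNames = "character"))

setValidity("AccuracyReport", function(object) {
  if (!isTRUE(all.equal(sum(object@confusion),
                        sum(diag(object@confusion)) +
                          sum(object@confusion) - sum(diag(object@confusion)))))
    return("confusion matrix inconsistent")
  if (object@oa < 0 || object@oa > 100) return("OA outside [0, 100]")
  if (!is.na(object@kappa) &&
      (object@kappa < -1 - 1e-12 || object@kappa > 1 + 1e-12))
    return("kappa outside [-1, 1]")
  TRUE
})

#' Transmit-ellipse sweep result
#'
#' Per-grid-point, per-class statistics of the CP decomposition parameters.
#'
#' @slot table data.frame with columns theta, chi (radians), class,
#'   alphaMean, alphaSD, dalphaMean, dalphaSD (degrees), n.
#' @slot axis \code{"chi_at_fixed_theta"} or \code{"theta_at_fixed_chi"}.
#' @slot excluded data.frame of grid points skipped by the a,b != 0 guard.
#' @exportClass SweepResult
setClass("SweepResult",
  representation(table = "data.frame", axis = "character",
                 excluded = "data.frame"))
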