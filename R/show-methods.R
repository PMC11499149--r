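#' @include AllClasses.R
NULL

setMethod("show", "ScatteringImage", function(object) {
  d <- dim(object@shh)
  cat(sprintf("ScatteringImage: %d x %d quad-pol pixels%s\n", d[1], d[2],
              if (nzchar(object@dateTag))
                sprintf(" [%s]", object@dateTag) else ""))
  cat(sprintf("  mean span: %.4g\n",
              mean(Mod(object@shh)^2 + 2 * Mod(object@shv)^2 +
                     Mod(object@svv)^2)))
})

setMethod("dim", "ScatteringImage", function(x) dim(x@shh))

setMethod("show", "TransmitWave", function(object) {
  cat(sprintf(
    "TransmitWave: theta = %.2f deg, chi = %.2f deg\n  a = %.5f%+.5fi, b = %.5f%+.5fi\n",
    object@theta * 180 / pi, object@chi * 180 / pi,
    Re(object@a), Im(object@a), Re(object@b), Im(object@b)))
})

setMethod("show", "CPField", function(object) {
  d <- dim(object@e1)
  cat(sprintf("CPField: %d x %d pixels, transmit (theta, chi) = (%.2f, %.2f) deg\n",
              d[1], d[2], object@wave@theta * 180 / pi,
              object@wave@chi * 180 / pi))
})

setMethod("show", "HermitianField", function(object) {
  d <- dim(object@entries)
  cat(sprintf("HermitianField (%s): %d x %d pixels of %dx%d matrices, window %d\n",
              object@kind, d[1], d[2], d[3], d[4], object@window))
})

setMethod("show", "ParamRaster", function(object) {
  v <- object@values[object@validMask]
  cat(sprintf("ParamRaster '%s' (%s): %d x %d, %d valid pixels\n",
              object@name, object@units, nrow(object@values),
              ncol(object@values), sum(object@validMask)))
  if (length(v))
    cat(sprintf("  range [%.3f, %.3f], mean %.3f\n", min(v), max(v), mean(v)))
})

setMethod("show", "LabelMask", function(object) {
  cat(sprintf("LabelMask: %d x %d, %d classes, %d parcels\n",
              nrow(object@labels), ncol(object@labels),
              length(object@classNames), nrow(object@parcelInfo)))
  counts <- table(factor(object@labels[object@labels > 0],
                         levels = seq_along(object@classNames),
                         labels = object@classNames))
  cat("  ", paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
      "\n")
})

setMethod("show", "DecompResult", function(object) {
  cat(sprintf("DecompResult (%s flavor)\n", object@flavor))
  show(object@alpha)
  show(object@deltaAlpha)
})

setMethod("show", "AccuracyReport", function(object) {
  cat("AccuracyReport\n")
  tab <- data.frame(class = object@classNames,
                    PA = round(object@pa, 2), UA = round(object@ua, 2),
                    average = round(object@averageAccuracy, 2))
  print(tab, row.names = FALSE)
  cat(sprintf("  OA = %.2f%%, kappa = %.3f\n", object@oa, object@kappa))
})

setMethod("show", "MixtureSpec", function(object) {
  cat(sprintf(
    "MixtureSpec: surface %.2f / double %.2f / volume %.2f, ratio %.2f, |coh| %.2f, power %.2f\n",
    object@fSurface, object@fDouble, object@fVolume, object@copolRatio,
    Mod(object@copolCoherence), object@totalPower))
})

setMethod("show", "PhenologySchedule", function(object) {
  cat("PhenologySchedule:", length(object@specs), "classes x 6 dates\n")
  cat("  dates:", paste(object@dates, collapse = ", "), "\n")
  cat("  stages:", paste(object@stages, collapse = "; "), "\n")
})
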