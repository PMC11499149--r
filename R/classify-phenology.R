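#' @include AllClasses.R utils.R decomposition.R
NULL

dateToken <- function(tag) {
  # "2015-11-03" -> "1103"; anything unparseable is used verbatim
  m <- regmatches(tag, regexec("^\\d{4}-(\\d{2})-(\\d{2})$", tag))[[1]]
  if (length(m) == 3L) paste0(m[2], m[3]) else tag
}

#' Multi-date alpha/delta-alpha feature stack
#'
#' Runs the decomposition on each date of an image stack and collects the
#' alpha and delta-alpha rasters as named features
#' (\code{"alpha_B_<MMDD>_<mode>"} / \code{"dalpha_B_<MMDD>_<mode>"}).
#'
#' @param images list of co-registered \linkS4class{ScatteringImage}s.
#' @param mode \code{"fp"}, \code{"pi4"}, \code{"ctlr"} or
#'   \code{"general"}.
#' @param wave \linkS4class{TransmitWave}, required for
#'   \code{mode = "general"}.
#' @param window odd averaging window (default 7).
#' @return a \linkS4class{FeatureStack}.
#' @export
extractFeatureStack <- function(images, mode = c("fp", "pi4", "ctlr",
                                                 "general"),
                                wave = NULL, window = 7L) {
  mode <- match.arg(mode)
  feats <- list()
  dates <- character(length(images))
  for (i in seq_along(images)) {
    img <- images[[i]]
    dates[i] <- img@dateTag
    dec <- switch(mode,
      fp = decomposeFP(img, window),
      pi4 = decomposeCP(img, mode = "pi4", window = window),
      ctlr = decomposeCP(img, mode = "ctlr", window = window),
      general = decomposeCP(img, wave = wave, window = window))
    tok <- dateToken(img@dateTag)
    feats[[sprintf("alpha_B_%s_%s", tok, mode)]] <- dec@alpha@values
    feats[[sprintf("dalpha_B_%s_%s", tok, mode)]] <- dec@deltaAlpha@values
  }
  new("FeatureStack", features = feats, dates = dates, mode = mode)
}

trainValues <- function(feature, mask, classId, split = "train") {
  pid <- mask@parcelInfo
  sel <- pid$parcel[pid$class == classId & pid$split == split]
  feature[mask@parcels %in% sel]
}

classIdOf <- function(mask, class) {
  if (is.character(class)) {
    id <- match(class, mask@classNames)
    if (is.na(id)) stop("unknown class: ", class, call. = FALSE)
    id
  } else as.integer(class)
}

#' Two-class difference degree of one feature
#'
#' Standardized mean difference over training pixels:
#' |mean_a - mean_b| / sqrt(var_a + var_b). Zero for identical
#' distributions; invariant to affine rescaling of the feature.
#'
#' @param feature numeric matrix.
#' @param mask a \linkS4class{LabelMask}.
#' @param classA,classB class names or ids.
#' @return nonnegative scalar.
#' @export
differenceDegree <- function(feature, mask, classA, classB) {
  va <- trainValues(feature, mask, classIdOf(mask, classA))
  vb <- trainValues(feature, mask, classIdOf(mask, classB))
  va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
  if (length(va) < 30)
    stop("class '", classA, "' has fewer than 30 training pixels",
         call. = FALSE)
  if (length(vb) < 30)
    stop("class '", classB, "' has fewer than 30 training pixels",
         call. = FALSE)
  denom <- sqrt(stats::var(va) + stats::var(vb))
  num <- abs(mean(va) - mean(vb))
  if (denom == 0) return(if (num == 0) 0 else Inf)
  num / denom
}

#' Rank features by difference degree and keep the top k
#'
#' @param stack a \linkS4class{FeatureStack}.
#' @param mask a \linkS4class{LabelMask}.
#' @param classA,classB the two classes to separate.
#' @param k number of features to keep (default 8).
#' @return character vector of feature names, best first; ties broken by
#'   lexicographic name order.
#' @export
selectOptimalFeatures <- function(stack, mask, classA = "T-H",
                                  classB = "D-J", k = 8L) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (k > length(stack@features))
    stop("k exceeds the number of features", call. = FALSE)
  nm <- names(stack@features)
  scores <- vapply(nm, function(f)
    differenceDegree(stack@features[[f]], mask, classA, classB), numeric(1))
  ord <- order(-scores, nm)
  nm[ord][seq_len(k)]
}

#' SVM classifier configuration
#'
#' RBF kernel with penalty C (default 100) and gamma defaulting to the
#' reciprocal of the number of input features; classification at native
#' pixel resolution with probability threshold 0 (every pixel receives the
#' maximum-margin label).
#'
#' @param C penalty parameter (> 0).
#' @param gamma RBF width; \code{NULL} = 1 / number of features.
#' @param probabilityThreshold kept at 0.
#' @return list configuration.
#' @export
classifierConfig <- function(C = 100, gamma = NULL,
                             probabilityThreshold = 0) {
  if (C <= 0) stop("C must be positive", call. = FALSE)
  if (!is.null(gamma) && gamma <= 0) stop("gamma must be positive",
                                          call. = FALSE)
  list(C = C, gamma = gamma, probabilityThreshold = probabilityThreshold)
}

#' Train an RBF SVM on the training parcels and classify the raster
#'
#' Features are z-scored with the training-set statistics, the SVM (RBF
#' kernel, penalty and gamma from the configuration) is fitted on all
#' training-parcel pixels, and every labeled-or-not pixel of the scene is
#' classified at native resolution.
#'
#' @param stack a \linkS4class{FeatureStack}, typically restricted to
#'   \code{\link{selectOptimalFeatures}} output via \code{features}.
#' @param mask a \linkS4class{LabelMask}.
#' @param cfg \code{\link{classifierConfig}} list.
#' @param seed integer seed (libsvm shrinking/caching is deterministic for
#'   fixed data; the seed pins R-side reproducibility).
#' @param features optional character vector restricting/ordering the
#'   feature set.
#' @return list: \code{prediction} (integer matrix of class ids),
#'   \code{model} (the fitted svm), \code{scaling} (training means/sds),
#'   \code{features}.
#' @export
trainAndClassify <- function(stack, mask, cfg = classifierConfig(),
                             seed = 1L, features = NULL) {
  if (is.null(features)) features <- names(stack@features)
  feats <- stack@features[features]
  train <- mask@parcelInfo$parcel[mask@parcelInfo$split == "train"]
  trainPix <- which(mask@parcels %in% train & mask@labels > 0)
  if (!length(trainPix)) stop("empty training set", call. = FALSE)
  y <- factor(mask@labels[trainPix], levels = seq_along(mask@classNames))
  y <- droplevels(y)
  if (nlevels(y) < 2)
    stop("training set contains a single class", call. = FALSE)
  X <- vapply(feats, function(f) f[trainPix], numeric(length(trainPix)))
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sd, "/")
  gamma <- if (is.null(cfg$gamma)) 1 / length(feats) else cfg$gamma
  set.seed(as.integer(seed))
  model <- e1071::svm(Xs, y, kernel = "radial", cost = cfg$C, gamma = gamma,
                      scale = FALSE)
  all <- vapply(feats, function(f) as.numeric(f), numeric(length(feats[[1]])))
  allS <- sweep(sweep(all, 2, mu), 2, sd, "/")
  ok <- rowSums(!is.finite(allS)) == 0
  pred <- rep(NA_integer_, nrow(allS))
  pred[ok] <- as.integer(as.character(predict(model, allS[ok, , drop = FALSE])))
  prediction <- matrix(pred, nrow(feats[[1]]), ncol(feats[[1]]))
  list(prediction = prediction, model = model,
       scaling = list(mean = mu, sd = sd), features = features)
}

#' Accuracy assessment on the verification parcels
#'
#' Confusion matrix over verification pixels (rows = predicted, columns =
#' reference) with producer's accuracy (reference-conditioned), user's
#' accuracy (prediction-conditioned), their mean, overall accuracy and the
#' kappa coefficient. Classes absent from the verification set are reported
#' as NA, never dropped.
#'
#' @param prediction integer matrix of predicted class ids.
#' @param mask a \linkS4class{LabelMask}.
#' @return an \linkS4class{AccuracyReport}.
#' @export
accuracyReport <- function(prediction, mask) {
  verify <- mask@parcelInfo$parcel[mask@parcelInfo$split == "verify"]
  idx <- which(mask@parcels %in% verify & mask@labels > 0 &
                 !is.na(prediction))
  if (!length(idx)) stop("no verification pixels", call. = FALSE)
  K <- length(mask@classNames)
  ref <- factor(mask@labels[idx], levels = seq_len(K))
  prd <- factor(prediction[idx], levels = seq_len(K))
  conf <- table(predicted = prd, reference = ref)
  accuracyFromConfusion(unclass(conf), mask@classNames)
}

#' Accuracy metrics from a confusion matrix
#'
#' @param confusion square count matrix, predicted rows x reference columns.
#' @param classNames optional class names.
#' @return an \linkS4class{AccuracyReport}.
#' @export
accuracyFromConfusion <- function(confusion,
                                  classNames = rownames(confusion)) {
  confusion <- as.matrix(confusion)
  if (is.null(classNames))
    classNames <- paste0("class", seq_len(nrow(confusion)))
  n <- sum(confusion)
  diagc <- diag(confusion)
  refTot <- colSums(confusion)
  prdTot <- rowSums(confusion)
  pa <- ifelse(refTot > 0, 100 * diagc / refTot, NA_real_)
  ua <- ifelse(prdTot > 0, 100 * diagc / prdTot, NA_real_)
  oa <- 100 * sum(diagc) / n
  pe <- sum(as.numeric(refTot) * as.numeric(prdTot)) / n^2
  # kappa is undefined when chance agreement is total (single occupied cell)
  kappa <- if (pe >= 1) NaN else (sum(diagc) / n - pe) / (1 - pe)
  new("AccuracyReport", confusion = confusion, pa = as.numeric(pa),
      ua = as.numeric(ua), averageAccuracy = as.numeric((pa + ua) / 2),
      oa = oa, kappa = kappa, classNames = classNames)
}

#' Mean of producer's and user's accuracy for one class
#'
#' The per-class "average accuracy" summary: (PA + UA) / 2, in percent.
#'
#' @param pa,ua producer's and user's accuracy in percent.
#' @return scalar percentage.
#' @export
averageAccuracy <- function(pa, ua) (pa + ua) / 2

#' Transmit-ellipse separability sweep
#'
#' Varies one ellipse angle over its admissible range with the other fixed,
#' runs the CP decomposition at every grid point and reports per-class mean
#' and spread of alpha_BCP and delta-alpha_BCP over the labeled pixels.
#' Grid points violating the a,b != 0 guard are excluded and recorded.
#'
#' @param img a \linkS4class{ScatteringImage}.
#' @param mask a \linkS4class{LabelMask}.
#' @param axis \code{"chi_at_fixed_theta"} or \code{"theta_at_fixed_chi"}.
#' @param fixed the fixed angle, radians (default pi/4 for fixed theta,
#'   0 for fixed chi).
#' @param step grid step in radians (default 1 degree).
#' @param window odd averaging window (default 7).
#' @param eps singularity guard on |a|, |b| (default 1e-8).
#' @return a \linkS4class{SweepResult}.
#' @export
parameterSweep <- function(img, mask,
                           axis = c("chi_at_fixed_theta",
                                    "theta_at_fixed_chi"),
                           fixed = NULL, step = pi / 180, window = 7L,
                           eps = 1e-8) {
  axis <- match.arg(axis)
  if (is.null(fixed)) fixed <- if (axis == "chi_at_fixed_theta") pi / 4 else 0
  grid <- if (axis == "chi_at_fixed_theta")
    seq(-pi / 4, pi / 4, by = step) else seq(-pi / 2, pi / 2, by = step)
  rows <- list(); excl <- list()
  lab <- mask@labels
  for (g in grid) {
    theta <- if (axis == "chi_at_fixed_theta") fixed else g
    chi <- if (axis == "chi_at_fixed_theta") g else fixed
    w <- transmitWave(theta, chi)
    if (Mod(w@a) <= eps || Mod(w@b) <= eps) {
      excl[[length(excl) + 1L]] <- data.frame(theta = theta, chi = chi)
      next
    }
    dec <- decomposeCP(img, wave = w, window = window)
    for (k in seq_along(mask@classNames)) {
      sel <- lab == k
      av <- dec@alpha@values[sel]; dv <- dec@deltaAlpha@values[sel]
      av <- av[is.finite(av)]; dv <- dv[is.finite(dv)]
      if (!length(av)) next
      rows[[length(rows) + 1L]] <- data.frame(
        theta = theta, chi = chi, class = mask@classNames[k],
        alphaMean = mean(av), alphaSD = stats::sd(av),
        dalphaMean = mean(dv), dalphaSD = stats::sd(dv),
        n = length(av), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("empty admissible grid", call. = FALSE)
  new("SweepResult", table = do.call(rbind, rows), axis = axis,
      excluded = if (length(excl)) do.call(rbind, excl)
                 else data.frame(theta = numeric(), chi = numeric()))
}

#' Per-class phenological trajectories of alpha and delta-alpha
#'
#' For each transmit mode and each date, computes the CP decomposition and
#' the parcel-mean alpha/delta-alpha per class, then flags the consecutive
#' trends (rise/dip/plateau/drop).
#'
#' @param images list of six co-registered \linkS4class{ScatteringImage}s.
#' @param mask a \linkS4class{LabelMask}.
#' @param modes named list of \linkS4class{TransmitWave}s; default the four
#'   canonical modes: right circular, linear pi/4 and the two intermediate
#'   ellipses (theta = pi/4, chi = +/- pi/8).
#' @param window odd averaging window (default 7).
#' @param plateauTol absolute consecutive change (degrees) treated as a
#'   plateau (default 3).
#' @return list: \code{table} (date x mode x class means and spreads) and
#'   \code{trends} (per class/mode character vectors of
#'   rise/dip/plateau/drop flags between consecutive dates).
#' @export
temporalCurves <- function(images, mask, modes = NULL, window = 7L,
                           plateauTol = 3) {
  if (length(images) != 6L) stop("six dates are required", call. = FALSE)
  if (is.null(modes))
    modes <- list(circular = transmitWave(0, -pi / 4),
                  pi4 = transmitWave(pi / 4, 0),
                  ellipse_pos = transmitWave(pi / 4, pi / 8),
                  ellipse_neg = transmitWave(pi / 4, -pi / 8))
  rows <- list()
  for (m in names(modes)) for (d in seq_along(images)) {
    dec <- decomposeCP(images[[d]], wave = modes[[m]], window = window)
    for (k in seq_along(mask@classNames)) {
      sel <- mask@labels == k
      av <- dec@alpha@values[sel]; dv <- dec@deltaAlpha@values[sel]
      av <- av[is.finite(av)]; dv <- dv[is.finite(dv)]
      if (!length(av)) next
      rows[[length(rows) + 1L]] <- data.frame(
        mode = m, date = images[[d]]@dateTag, dateIndex = d,
        class = mask@classNames[k],
        alphaMean = mean(av), alphaSD = stats::sd(av),
        dalphaMean = mean(dv), dalphaSD = stats::sd(dv),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  trends <- list()
  for (m in names(modes)) for (cl in unique(tab$class)) {
    sub <- tab[tab$mode == m & tab$class == cl, ]
    sub <- sub[order(sub$dateIndex), ]
    dif <- diff(sub$alphaMean)
    trends[[paste(m, cl, sep = ".")]] <-
      ifelse(abs(dif) <= plateauTol, "plateau",
             ifelse(dif > 0, "rise",
                    ifelse(dif > -3 * plateauTol, "dip", "drop")))
  }
  list(table = tab, trends = trends)
}
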