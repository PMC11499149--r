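# Small two-class mask helper: two parcels per class on a 20x40 scene.
twoClassMask <- function() {
  labels <- matrix(0L, 20, 40)
  parcels <- matrix(0L, 20, 40)
  lay <- list(list(1:10, 1:10, 1L), list(11:20, 1:10, 1L),
              list(1:10, 21:30, 2L), list(11:20, 21:30, 2L))
  for (i in seq_along(lay)) {
    labels[lay[[i]][[1]], lay[[i]][[2]]] <- lay[[i]][[3]]
    parcels[lay[[i]][[1]], lay[[i]][[2]]] <- i
  }
  new("LabelMask", labels = labels, classNames = c("A", "B"),
      parcels = parcels,
      parcelInfo = data.frame(parcel = 1:4, class = c(1L, 1L, 2L, 2L),
                              split = c("train", "verify", "train",
                                        "verify")))
}

test_that("difference degree follows the standardized mean difference", {
  mask <- twoClassMask()
  # identical distributions -> 0
  f <- matrix(rep(c(1, 2), 10), 20, 40)
  expect_equal(differenceDegree(f, mask, "A", "B"), 0)
  # means 0 and 1, variances ~0.5 each -> score ~1.0
  s <- sqrt(0.5)
  f <- matrix(0, 20, 40)
  f[, 1:10] <- rep_len(c(-s, s), 200)   # sample mean 0, sample var ~0.5
  f[, 21:30] <- 1 + rep_len(c(-s, s), 200)
  va <- f[mask@parcels == 1]
  vb <- f[mask@parcels == 3]
  manual <- abs(mean(va) - mean(vb)) / sqrt(var(va) + var(vb))
  expect_equal(differenceDegree(f, mask, "A", "B"), manual)
  expect_equal(manual, 1, tolerance = 0.02)
  # affine invariance
  expect_equal(differenceDegree(3 * f + 7, mask, "A", "B"),
               differenceDegree(f, mask, "A", "B"), tolerance = 1e-12)
  expect_error(differenceDegree(f, mask, "A", "C"), "unknown class")
})

test_that("feature selection ranks by separability with lexicographic ties", {
  mask <- twoClassMask()
  set.seed(11)
  noise1 <- matrix(rnorm(800), 20, 40)
  noise2 <- matrix(rnorm(800), 20, 40)
  sep <- matrix(0, 20, 40)
  sep[, 21:30] <- 10  # only this feature separates A from B
  stack <- new("FeatureStack",
               features = list(zz_noise = noise1, sep_feature = sep,
                               aa_noise = noise2),
               dates = "d", mode = "fp")
  expect_equal(selectOptimalFeatures(stack, mask, "A", "B", k = 1),
               "sep_feature")
  all3 <- selectOptimalFeatures(stack, mask, "A", "B", k = 3)
  expect_setequal(all3, names(stack@features))
  # invariant to feature ordering in the stack
  stack2 <- new("FeatureStack",
                features = stack@features[c(3, 1, 2)], dates = "d",
                mode = "fp")
  expect_equal(selectOptimalFeatures(stack2, mask, "A", "B", k = 3), all3)
  expect_error(selectOptimalFeatures(stack, mask, "A", "B", k = 0),
               "positive")
  expect_error(selectOptimalFeatures(stack, mask, "A", "B", k = 9),
               "exceeds")
})

test_that("the SVM separates well-separated classes and is seed-stable", {
  mask <- twoClassMask()
  set.seed(12)
  f1 <- matrix(rnorm(800, 0, 0.3), 20, 40)
  f1[, 21:30] <- rnorm(200, 4, 0.3)
  f2 <- matrix(rnorm(800, 0, 0.3), 20, 40)
  f2[, 21:30] <- rnorm(200, -4, 0.3)
  stack <- new("FeatureStack", features = list(f1 = f1, f2 = f2),
               dates = "d", mode = "fp")
  fit <- trainAndClassify(stack, mask, classifierConfig(), seed = 1L)
  rep <- accuracyReport(fit$prediction, mask)
  expect_equal(rep@oa, 100)
  expect_equal(rep@kappa, 1)
  fit2 <- trainAndClassify(stack, mask, classifierConfig(), seed = 1L)
  expect_identical(fit$prediction, fit2$prediction)
})

test_that("label-free features with permuted training labels give chance accuracy", {
  mask <- twoClassMask()
  set.seed(13)
  # features carry no class information at all
  stack <- new("FeatureStack",
               features = list(f1 = matrix(rnorm(800), 20, 40),
                               f2 = matrix(rnorm(800), 20, 40)),
               dates = "d", mode = "fp")
  scrambled <- mask
  # permute labels inside the training parcels only
  tr <- scrambled@parcels %in% c(1L, 3L)
  set.seed(14)
  scrambled@labels[tr] <- sample(scrambled@labels[tr])
  fit <- trainAndClassify(stack, scrambled, classifierConfig(), seed = 2L)
  rep <- accuracyReport(fit$prediction, mask)
  expect_lt(rep@oa, 65)
  expect_gt(rep@oa, 35)
})

test_that("single-class training sets are rejected", {
  mask <- twoClassMask()
  mask@labels[mask@labels == 2L] <- 1L
  mask@parcelInfo$class <- 1L
  stack <- new("FeatureStack",
               features = list(f = matrix(rnorm(800), 20, 40)),
               dates = "d", mode = "fp")
  expect_error(trainAndClassify(stack, mask, classifierConfig(), seed = 1L),
               "single class")
})

test_that("accuracy metrics match a hand-computed confusion matrix", {
  conf <- matrix(c(50, 10, 10, 30), 2, 2, byrow = TRUE)
  rep <- accuracyFromConfusion(conf, c("A", "B"))
  expect_equal(rep@oa, 80)
  # brute-force chance agreement: pe = (60*60 + 40*40)/100^2 = 0.52
  expect_equal(rep@kappa, (0.8 - 0.52) / (1 - 0.52))
  # PA is reference-conditioned (columns), UA prediction-conditioned (rows)
  expect_equal(rep@pa, c(100 * 50 / 60, 100 * 30 / 40))
  expect_equal(rep@ua, c(100 * 50 / 60, 100 * 30 / 40))
  # the published worked example: PA 91.07, UA 88.92 -> average 90.0 (1 d.p.)
  expect_equal(round(averageAccuracy(91.07, 88.92), 1), 90.0)
})

test_that("accuracy identities hold on random confusion matrices", {
  set.seed(15)
  for (i in 1:20) {
    K <- sample(2:5, 1)
    conf <- matrix(rpois(K * K, 20), K, K)
    rep <- accuracyFromConfusion(conf)
    refTot <- colSums(conf)
    # OA equals the reference-count-weighted mean of per-class PA
    expect_equal(rep@oa, sum(rep@pa * refTot, na.rm = TRUE) / sum(refTot))
    # kappa = 1 iff the confusion matrix is diagonal
    expect_lt(rep@kappa, 1)
  }
  diagRep <- accuracyFromConfusion(diag(c(5, 9, 13)))
  expect_equal(diagRep@kappa, 1)
  expect_equal(diagRep@oa, 100)
})

test_that("classes absent from the verification set are NA, not dropped", {
  mask <- twoClassMask()
  # remove class B's verify parcel labels
  mask@labels[mask@parcels == 4L] <- 0L
  pred <- mask@labels
  rep <- accuracyReport(pred, mask)
  expect_true(is.na(rep@pa[2]))
  expect_length(rep@pa, 2)
})

test_that("transmit-ellipse sweeps behave physically", {
  # surface-only scene: alpha_BCP near zero across the whole admissible grid
  surf <- sampleSpeckle(
    mixtureCovariance(mixtureSpec(1, 0, 0, copolCoherence = 0.98 + 0i)),
    20, 40, seed = 16)
  mask <- twoClassMask()
  sw <- parameterSweep(surf, mask, "chi_at_fixed_theta", fixed = pi / 4,
                       step = 5 * pi / 180, window = 5L)
  expect_lt(max(sw@table$alphaMean), 6)
  # continuity of the class-mean curve on a mixed scene (1-degree grid)
  mix <- sampleSpeckle(
    mixtureCovariance(mixtureSpec(0.5, 0, 0.5, copolCoherence = 0.8 + 0i)),
    20, 40, seed = 17)
  sw1 <- parameterSweep(mix, mask, "chi_at_fixed_theta", fixed = pi / 4,
                        step = pi / 180, window = 5L)
  curveA <- sw1@table[sw1@table$class == "A", ]
  curveA <- curveA[order(curveA$chi), ]
  expect_lt(max(abs(diff(curveA$alphaMean))), 5)
  # circular endpoints are theta-independent
  endA <- parameterSweep(mix, mask, "chi_at_fixed_theta", fixed = pi / 4,
                         step = pi / 4, window = 5L)
  endB <- parameterSweep(mix, mask, "chi_at_fixed_theta", fixed = -pi / 8,
                         step = pi / 4, window = 5L)
  for (ch in c(-pi / 4, pi / 4)) {
    a <- endA@table$alphaMean[endA@table$class == "A" &
                                abs(endA@table$chi - ch) < 1e-9]
    b <- endB@table$alphaMean[endB@table$class == "A" &
                                abs(endB@table$chi - ch) < 1e-9]
    expect_equal(a, b, tolerance = 1e-9)
  }
  # theta sweep at chi = 0 excludes the singular H/V transmit points
  swt <- parameterSweep(mix, mask, "theta_at_fixed_chi", fixed = 0,
                        step = pi / 4, window = 5L)
  expect_true(all(abs(swt@excluded$theta) %in% c(0, pi / 2)))
  expect_false(any(abs(swt@table$theta) < 1e-9))
})

test_that("temporal curves recover the built-in phenological trends", {
  lay <- defaultParcelLayout(parcelSize = 8L, cell = 10L)
  stack <- buildSceneStack(lay, defaultPhenologySchedule(), seed = 19)
  tc <- temporalCurves(stack$images, stack$mask,
                       modes = list(pi4 = transmitWave(pi / 4, 0)),
                       window = 5L)
  curve <- function(cl) {
    s <- tc$table[tc$table$class == cl, ]
    s$alphaMean[order(s$dateIndex)]
  }
  for (cl in c("T-H", "D-J"))
    expect_lt(curve(cl)[1], curve(cl)[2])  # rise into elongation
  th <- curve("T-H"); dj <- curve("D-J")
  expect_lt(th[6], th[5] - 5)              # harvest drop of T-H
  expect_gt(dj[6], dj[5] - 5)              # no such drop for D-J
  # constant scene over time -> flat trajectories
  const <- rep(list(stack$images[[1]]), 6)
  tcc <- temporalCurves(const, stack$mask,
                        modes = list(pi4 = transmitWave(pi / 4, 0)),
                        window = 5L)
  flat <- tcc$table[tcc$table$class == "water", ]
  expect_lt(max(abs(diff(flat$alphaMean[order(flat$dateIndex)]))), 1e-12)
  expect_true(all(tcc$trends$pi4.water == "plateau"))
  expect_error(temporalCurves(stack$images[1:5], stack$mask), "six dates")
})
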