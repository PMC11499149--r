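test_that("alpha_B hits the canonical full-pol limits", {
  expect_equal(paramValues(alphaBFP(diagT3Field(c(2, 0, 0))))[1, 1], 0)
  expect_equal(paramValues(alphaBFP(diagT3Field(c(0, 2, 0))))[1, 1], 90)
  expect_equal(paramValues(alphaBFP(diagT3Field(c(1, 0.5, 0.5))))[1, 1], 45)
  # 0/0 is masked invalid, never silently zero
  r <- alphaBFP(diagT3Field(c(0, 0, 0)))
  expect_false(r@validMask[1, 1])
  expect_true(is.nan(paramValues(r)[1, 1]))
})

test_that("full-pol co-polar statistics capture ratio and phase", {
  st <- copolStatsFP(constantImage(canonicalTarget("trihedral"), 3, 3), 3L)
  expect_equal(st@rho[2, 2], 1 + 0i, tolerance = 1e-12)
  st <- copolStatsFP(constantImage(canonicalTarget("dihedral"), 3, 3), 3L)
  expect_equal(st@rho[2, 2], -1 + 0i, tolerance = 1e-12)
  # power ratio 4 with zero phase difference -> amplitude ratio 2
  s <- matrix(c(1, 0, 0, 2) + 0i, 2, 2)
  st <- copolStatsFP(constantImage(s, 3, 3), 3L)
  expect_equal(Mod(st@rho[2, 2]), 2, tolerance = 1e-12)
  expect_equal(Arg(st@rho[2, 2]), 0, tolerance = 1e-12)
  # zero HH power is masked
  s <- matrix(c(0, 0, 0, 1) + 0i, 2, 2)
  st <- copolStatsFP(constantImage(s, 3, 3), 3L)
  expect_false(st@validMask[2, 2])
})

test_that("alpha_0 depends only on the channel ratio", {
  expect_equal(paramValues(alphaZero(rhoStats(1 + 0i)))[1, 1], 0)
  expect_equal(paramValues(alphaZero(rhoStats(-1 + 0i)))[1, 1], 90)
  expect_equal(paramValues(alphaZero(rhoStats(1i)))[1, 1], 45)
})

test_that("delta-alpha sign follows the co-pol phase difference", {
  # partially coherent ensembles with zero cross-pol and equal co-pol powers
  neg <- analyticAlpha(copolMomentC3(-0.5 + 0i))  # phase pi (double bounce)
  expect_equal(neg$alphaB, atan(3) * 180 / pi, tolerance = 1e-12)
  expect_equal(neg$alphaZeroFP, 90)
  expect_equal(neg$deltaAlphaFP, atan(3) * 180 / pi - 90, tolerance = 1e-12)
  expect_lt(neg$deltaAlphaFP, 0)

  pos <- analyticAlpha(copolMomentC3(0.5 + 0i))  # phase 0 (surface)
  expect_equal(pos$deltaAlphaFP, 90 - atan(3) * 180 / pi, tolerance = 1e-12)
  expect_gt(pos$deltaAlphaFP, 0)

  expect_error(deltaAlpha(paramRasterFor(matrix(1, 2, 2)),
                          paramRasterFor(matrix(1, 3, 3))),
               "co-registered")
})

test_that("speckled ensembles with the stated moments reproduce the signed delta-alpha", {
  for (cc in c(-0.5, 0.5)) {
    c3 <- copolMomentC3(cc + 0i)
    img <- sampleSpeckle(c3, 100, 100, seed = 21)
    t3 <- globalCoherency(fpCoherency(img, 1L))
    alpha <- alphaFromMatrix(t3)
    truth <- analyticAlpha(c3)
    expect_equal(alpha, truth$alphaB, tolerance = 0.02)
    if (cc < 0) expect_lt(alpha - truth$alphaZeroFP, 0)
    else expect_gt(alpha - truth$alphaZeroFP, 0)
  }
})

test_that("alpha_BCP hits the canonical compact-pol limits", {
  w <- transmitWave(pi / 4, 0)
  surf <- decomposeCP(constantImage(canonicalTarget("trihedral"), 3, 3),
                      wave = w, window = 3L)
  expect_equal(paramValues(surf@alpha)[2, 2], 0)
  dih <- decomposeCP(constantImage(canonicalTarget("dihedral"), 3, 3),
                     wave = w, window = 3L)
  expect_equal(paramValues(dih@alpha)[2, 2], 90)
})

test_that("decorrelated equal-power channels give alpha_BCP near 45 degrees", {
  set.seed(271)
  n <- 100000L
  e1 <- matrix(complex(real = rnorm(n), imaginary = rnorm(n)) / sqrt(2),
               250, 400)
  e2 <- matrix(complex(real = rnorm(n), imaginary = rnorm(n)) / sqrt(2),
               250, 400)
  cp <- new("CPField", e1 = e1, e2 = e2, wave = transmitWave(pi / 4, 0))
  T2 <- globalCoherency(cpSecondOrder(cp, 1L)$t2)
  expect_equal(alphaFromMatrix(T2), 45, tolerance = 0.5)
  # and the channel correlation is near zero
  st <- cpSecondOrder(cp, 1L)$c2
  C2 <- globalCoherency(st)
  expect_lt(Mod(C2[1, 2]) / sqrt(Re(C2[1, 1]) * Re(C2[2, 2])), 0.05)
})

test_that("CP channel statistics follow their definitions", {
  w <- transmitWave(pi / 4, 0)
  e1 <- matrix(1 + 1i, 3, 3)
  cp <- new("CPField", e1 = e1, e2 = e1, wave = w)
  st <- cpChannelStats(cp, 3L)
  expect_equal(st@rho[2, 2], 1 + 0i, tolerance = 1e-12)
  expect_equal(Mod(st@r[2, 2]), 1, tolerance = 1e-12)

  cp <- new("CPField", e1 = e1, e2 = 1i * e1, wave = w)
  st <- cpChannelStats(cp, 3L)
  expect_equal(Arg(st@rho[2, 2]), pi / 2, tolerance = 1e-12)
  expect_equal(Mod(st@r[2, 2]), 1, tolerance = 1e-12)
})

test_that("coherent pixels are governed by the channel ratio alone", {
  # |r| = 1 at window 1: alpha_BCP equals arctan(|1-rho|^2/|1+rho|^2)
  set.seed(17)
  img <- randomImage(30, 30, seed = 17)
  w <- transmitWave(pi / 5, -pi / 9)
  dec <- decomposeCP(img, wave = w, window = 1L)
  cp <- generalCPField(img, w)
  st <- cpChannelStats(cp, 1L)
  expect_gt(min(Mod(st@r[st@validMask])), 1 - 1e-9)
  pred <- atan2(Mod(st@rho - 1)^2, Mod(st@rho + 1)^2) * 180 / pi
  ok <- st@validMask
  expect_lt(max(abs(pred[ok] - dec@alpha@values[ok])), 1e-6)
})

test_that("the expanded closed form agrees in its exact limits and is reported, not enforced", {
  img <- randomImage(20, 20, seed = 23)
  w <- transmitWave(pi / 4, 0)
  cp <- generalCPField(img, w)
  so <- cpSecondOrder(cp, 1L)
  st <- cpChannelStats(cp, 1L)
  # coherent single-look pixels: both factor readings coincide with Eq-17
  cons <- expansionConsistency(so$t2, st)
  expect_lt(cons$maxAbsDev, 1e-6)
  # incoherent equal-power: both routes approach 45 degrees
  set.seed(5)
  n <- 20000L
  e1 <- matrix(complex(real = rnorm(n), imaginary = rnorm(n)), 100, 200)
  e2 <- matrix(complex(real = rnorm(n), imaginary = rnorm(n)), 100, 200)
  cpv <- new("CPField", e1 = e1, e2 = e2, wave = w)
  T2 <- globalCoherency(cpSecondOrder(cpv, 1L)$t2)
  C2 <- globalCoherency(cpSecondOrder(cpv, 1L)$c2)
  rho <- complex(modulus = sqrt(Re(C2[2, 2]) / Re(C2[1, 1])),
                 argument = Arg(Conj(C2[1, 2])))
  rmod <- Mod(C2[1, 2]) / sqrt(Re(C2[1, 1]) * Re(C2[2, 2]))
  term <- 2 * Mod(rho) * cos(Arg(rho)) * (1 - rmod)
  expanded <- atan2(Mod(rho - 1)^2 + term, Mod(rho + 1)^2 - term) * 180 / pi
  expect_equal(alphaFromMatrix(T2), 45, tolerance = 1)
  expect_equal(expanded, 45, tolerance = 1)
  # windowed speckle: deviations are summarized, finite, and modest
  spk <- sampleSpeckle(mixtureCovariance(mixtureSpec(0.4, 0.2, 0.4)),
                       40, 40, seed = 31)
  cps <- generalCPField(spk, w)
  sos <- cpSecondOrder(cps, 7L)
  sts <- cpChannelStats(cps, 7L)
  rep7 <- expansionConsistency(sos$t2, sts)
  expect_true(is.finite(rep7$maxAbsDev))
  expect_true(rep7$meanAbsDev <= rep7$maxAbsDev)
})

test_that("angle ranges hold on random speckle scenes", {
  set.seed(404)
  for (seed in 1:3) {
    f <- c(runif(3))
    f <- f / sum(f)
    c3 <- mixtureCovariance(mixtureSpec(f[1], f[2], f[3],
                                        copolCoherence = 0.6 + 0i))
    img <- sampleSpeckle(c3, 25, 25, seed = seed)
    fp <- decomposeFP(img, 3L)
    cpw <- decomposeCP(img, wave = transmitWave(pi / 4, -pi / 8), window = 3L)
    for (d in list(fp, cpw)) {
      a <- d@alpha@values[d@alpha@validMask]
      a0 <- d@alpha0@values[d@alpha0@validMask]
      da <- d@deltaAlpha@values[d@deltaAlpha@validMask]
      expect_true(all(a >= 0 & a <= 90))
      expect_true(all(a0 >= 0 & a0 <= 90))
      expect_true(all(da >= -90 & da <= 90))
      # exact identity on valid pixels
      ok <- d@alpha@validMask & d@alpha0@validMask
      expect_identical(d@deltaAlpha@values[ok],
                       d@alpha@values[ok] - d@alpha0@values[ok])
    }
  }
})

test_that("alpha_B is rotation invariant about the line of sight", {
  set.seed(101)
  drift <- 0
  for (i in 1:100) {
    s <- randomSinclair()
    base <- paramValues(alphaBFP(fpCoherency(constantImage(s), 1L)))[1, 1]
    for (phi in seq(-pi / 2, pi / 2, length.out = 19)) {
      rot <- rotateSinclair(s, phi)
      a <- paramValues(alphaBFP(fpCoherency(constantImage(rot), 1L)))[1, 1]
      drift <- max(drift, abs(a - base))
    }
  }
  expect_lt(drift, 1e-6)
})

test_that("windowless alpha_B matches a brute-force outer-product recomputation", {
  set.seed(202)
  worst <- 0
  for (i in 1:1000) {
    s <- randomSinclair()
    pkg <- paramValues(alphaBFP(fpCoherency(constantImage(s), 1L)))[1, 1]
    # independent route: explicit Pauli vector, explicit outer product
    k <- c(s[1, 1] + s[2, 2], s[1, 1] - s[2, 2], 2 * s[1, 2]) / sqrt(2)
    T3 <- k %*% Conj(t(k))
    ref <- atan(Re(T3[2, 2] + T3[3, 3]) / Re(T3[1, 1])) * 180 / pi
    worst <- max(worst, abs(pkg - ref))
  }
  expect_lt(worst, 1e-9)
})
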