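#' @include AllClasses.R utils.R general-cp.R decomposition.R
NULL

#' Canonical deterministic scatterers
#'
#' Single-pixel 2x2 Sinclair matrices of the textbook limits: trihedral
#' (odd-bounce surface, diag(1, 1)), dihedral (even-bounce, diag(1, -1)) and
#' a pure cross-pol pair (off-diagonal units).
#'
#' @param kind \code{"trihedral"}, \code{"dihedral"} or \code{"hv_pair"}.
#' @return complex 2x2 matrix (rows: H/V receive, cols: H/V transmit).
#' @export
canonicalTarget <- function(kind = c("trihedral", "dihedral", "hv_pair")) {
  kind <- match.arg(kind)
  switch(kind,
    trihedral = matrix(c(1 + 0i, 0, 0, 1), 2, 2),
    dihedral  = matrix(c(1 + 0i, 0, 0, -1), 2, 2),
    hv_pair   = matrix(c(0 + 0i, 1, 1, 0), 2, 2))
}

#' Constant scattering image from a 2x2 Sinclair matrix
#'
#' @param s complex 2x2 matrix (e.g. from \code{\link{canonicalTarget}}).
#' @param rows,cols raster size.
#' @param dateTag optional date tag.
#' @return a \linkS4class{ScatteringImage} with every pixel equal to
#'   \code{s}.
#' @export
constantImage <- function(s, rows = 1L, cols = 1L, dateTag = "") {
  mk <- function(v) matrix(as.complex(v), rows, cols)
  new("ScatteringImage", shh = mk(s[1, 1]), shv = mk(s[1, 2]),
      svh = mk(s[2, 1]), svv = mk(s[2, 2]), dateTag = dateTag)
}

# Unit-trace surface/double-bounce covariance in the lexicographic
# (S_HH, sqrt(2) S_HV, S_VV) basis: zero cross-pol, co-pol power ratio g and
# complex co-pol coherence c (sign encodes the 0 / pi phase difference).
copolCovariance <- function(g, c) {
  off <- c * sqrt(g)
  matrix(c(1, 0, Conj(off),
           0, 0, 0,
           off, 0, g), 3, 3) / (1 + g)
}

# Azimuthally symmetric random-volume covariance, unit trace: equal co-pol
# powers, zero co-pol correlation, cross-pol power ratio
# <|S_HV|^2>/<|S_HH|^2> = 1/3 (the conventional random-dipole value).
volumeCovariance <- function() {
  diag(c(3, 2, 3)) / 8 + 0i
}

#' Scattering-mixture covariance (C3, lexicographic basis)
#'
#' Second-order model of a land-cover class as an incoherent power-weighted
#' sum of surface, double-bounce and volume mechanisms:
#' C3 = P (f_s C_surf(g, +c) + f_d C_dbl(g, -c) + f_v C_vol), each component
#' unit trace. The surface and double-bounce parts share the co-pol ratio g
#' and coherence magnitude |c| but carry co-pol phase differences of 0 and
#' pi respectively; the volume part is azimuthally symmetric with
#' decorrelated co-pols and the conventional 1/3 cross-pol power ratio.
#'
#' @param spec a \linkS4class{MixtureSpec}.
#' @return 3x3 complex Hermitian PSD matrix.
#' @export
mixtureCovariance <- function(spec) {
  validObject(spec)
  c3 <- spec@totalPower *
    (spec@fSurface * copolCovariance(spec@copolRatio, spec@copolCoherence) +
     spec@fDouble * copolCovariance(spec@copolRatio, -spec@copolCoherence) +
     spec@fVolume * volumeCovariance())
  ev <- eigen(c3, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * sum(Re(diag(c3))))
    stop("internal error: mixture covariance not PSD", call. = FALSE)
  c3
}

#' Construct a mixture specification
#'
#' @param fSurface,fDouble,fVolume nonnegative power fractions summing to 1.
#' @param copolRatio co-pol power ratio of the coherent part (> 0).
#' @param copolCoherence co-pol coherence magnitude/phase factor, |.| <= 1.
#' @param totalPower total backscattered power (linear).
#' @return a \linkS4class{MixtureSpec}.
#' @export
mixtureSpec <- function(fSurface, fDouble, fVolume, copolRatio = 1,
                        copolCoherence = 0.7 + 0i, totalPower = 1) {
  new("MixtureSpec", fSurface = fSurface, fDouble = fDouble,
      fVolume = fVolume, copolRatio = copolRatio,
      copolCoherence = as.complex(copolCoherence), totalPower = totalPower)
}

#' Lexicographic-to-Pauli change of basis (T3 from C3)
#'
#' @param c3 3x3 Hermitian covariance in the (S_HH, sqrt(2) S_HV, S_VV)
#'   basis.
#' @return 3x3 Hermitian coherency matrix in the Pauli basis.
#' @export
c3ToT3 <- function(c3) {
  U <- matrix(c(1, 0, 1,
                1, 0, -1,
                0, sqrt(2), 0), 3, 3, byrow = TRUE) / sqrt(2) + 0i
  U %*% c3 %*% Conj(t(U))
}

#' Closed-form decomposition angles of a covariance model
#'
#' Analytic alpha_B (full pol) and alpha_BCP (compact pol, for a given
#' transmit ellipse) of an ensemble whose second-order statistics equal
#' \code{c3} exactly; the large-sample limits the speckled estimates
#' converge to.
#'
#' @param c3 3x3 Hermitian covariance (lexicographic basis).
#' @param wave optional \linkS4class{TransmitWave} for the CP angles.
#' @return named list: \code{alphaB}, \code{alphaZeroFP},
#'   \code{deltaAlphaFP} (degrees); when \code{wave} is given also
#'   \code{alphaBCP}, \code{alphaZeroCP} and \code{deltaAlphaBCP}.
#' @export
analyticAlpha <- function(c3, wave = NULL) {
  t3 <- c3ToT3(c3)
  out <- list(alphaB = atan2(Re(t3[2, 2] + t3[3, 3]), Re(t3[1, 1])) * DEG)
  # FP co-pol ratio: |rho| = sqrt(<|S_VV|^2>/<|S_HH|^2>), phase of <S_VV S_HH*>
  rhoFP <- complex(modulus = sqrt(Re(c3[3, 3]) / Re(c3[1, 1])),
                   argument = Arg(c3[3, 1]))
  out$alphaZeroFP <- atan2(Mod(rhoFP - 1)^2, Mod(rhoFP + 1)^2) * DEG
  out$deltaAlphaFP <- out$alphaB - out$alphaZeroFP
  if (!is.null(wave)) {
    cpm <- cpMomentsFromC3(c3, wave)
    num <- cpm$p1 + cpm$p2 - 2 * Re(cpm$cross12)
    den <- cpm$p1 + cpm$p2 + 2 * Re(cpm$cross12)
    out$alphaBCP <- atan2(pmax(num, 0), pmax(den, 0)) * DEG
    rho <- complex(modulus = sqrt(cpm$p2 / cpm$p1),
                   argument = Arg(Conj(cpm$cross12)))
    out$alphaZeroCP <- atan2(Mod(rho - 1)^2, Mod(rho + 1)^2) * DEG
    out$deltaAlphaBCP <- out$alphaBCP - out$alphaZeroCP
  }
  out
}

# Second-order moments of the general CP channels implied by a C3 model:
# p1 = <|E1|^2>, p2 = <|E2|^2>, cross12 = <E1 E2*>.
cpMomentsFromC3 <- function(c3, wave) {
  w1 <- wave@b / wave@a
  w2 <- wave@a / wave@b
  s <- sqrt(2)  # lexicographic channel 2 is sqrt(2) S_HV
  # E1 = S_HH + w1 S_HV = u1 . k_L with u1 = (1, w1/sqrt(2), 0)
  u1 <- c(1, w1 / s, 0)
  u2 <- c(0, w2 / s, 1)
  # E = u^T k_L with C3 = <k k^H>, so <E_m E_n*> = t(u_m) C3 Conj(u_n)
  p1 <- Re((t(u1) %*% c3 %*% Conj(u1))[1])
  p2 <- Re((t(u2) %*% c3 %*% Conj(u2))[1])
  cross12 <- (t(u1) %*% c3 %*% Conj(u2))[1]
  list(p1 = p1, p2 = p2, cross12 = cross12)
}

#' Sample fully developed speckle from a covariance model
#'
#' Draws i.i.d. zero-mean circular complex Gaussian scattering vectors with
#' covariance \code{c3} (single look), unpacked to Sinclair channels with
#' S_VH = S_HV. Rank-deficient (coherent) covariances are handled through
#' the eigen factorization.
#'
#' @param c3 3x3 Hermitian PSD covariance (lexicographic basis).
#' @param rows,cols raster size.
#' @param seed integer RNG seed (Mersenne-Twister); required for
#'   reproducibility.
#' @param dateTag optional date tag.
#' @return a \linkS4class{ScatteringImage}.
#' @export
sampleSpeckle <- function(c3, rows, cols, seed, dateTag = "") {
  set.seed(as.integer(seed))
  drawSpeckle(c3, rows, cols, dateTag)
}

# Speckle draw using the current RNG state (no re-seeding); internal so that
# scene builders can draw several parcels under one seed.
drawSpeckle <- function(c3, rows, cols, dateTag = "") {
  eg <- eigen(c3, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  if (min(eg$values) < -1e-8 * max(sum(ev), .Machine$double.eps))
    stop("covariance is not positive semidefinite", call. = FALSE)
  B <- eg$vectors %*% diag(sqrt(ev))
  n <- rows * cols
  W <- matrix(complex(real = stats::rnorm(3 * n), imaginary = stats::rnorm(3 * n)),
              3, n) / sqrt(2)
  K <- B %*% W
  shv <- matrix(K[2, ] / sqrt(2), rows, cols)
  new("ScatteringImage",
      shh = matrix(K[1, ], rows, cols),
      shv = shv, svh = shv,
      svv = matrix(K[3, ], rows, cols),
      dateTag = dateTag)
}

#' Default six-date phenology schedule
#'
#' Mixture specifications for the five land-cover classes (water, urban,
#' shoal naked land, transplanted hybrid rice T-H, direct-sown japonica rice
#' D-J) at the six acquisition dates of a rice season (day of year 163, 211,
#' 235, 259, 283, 307; Seedling through Harvest). The rice trajectories
#' encode the standard C-band narrative: surface-dominated seedling stage
#' over the underlying water/soil, a rise of volume and double-bounce power
#' to elongation, a slight dip at booting, a plateau through maturity, and a
#' bare-soil reversion of T-H at harvest while the longer-cycle D-J remains
#' vegetated.
#'
#' @return a \linkS4class{PhenologySchedule}.
#' @export
defaultPhenologySchedule <- function() {
  ms <- mixtureSpec
  specs <- list(
    water = rep(list(ms(1, 0, 0, copolRatio = 1.0,
                        copolCoherence = 0.95 + 0i, totalPower = 0.25)), 6),
    urban = rep(list(ms(0.08, 0.84, 0.08, copolRatio = 1.0,
                        copolCoherence = 0.9 + 0i, totalPower = 2.0)), 6),
    SNL = rep(list(ms(0.80, 0.05, 0.15, copolRatio = 1.1,
                      copolCoherence = 0.7 + 0i, totalPower = 0.8)), 6),
    `T-H` = list(
      ms(0.88, 0.04, 0.08, 1.00, 0.90 + 0i, 0.45),   # seedling over water
      ms(0.30, 0.22, 0.48, 1.05, 0.55 + 0i, 1.00),   # elongation rise
      ms(0.36, 0.18, 0.46, 1.05, 0.60 + 0i, 1.00),   # booting dip
      ms(0.34, 0.19, 0.47, 1.05, 0.60 + 0i, 1.00),   # heading-flowering
      ms(0.33, 0.20, 0.47, 1.05, 0.60 + 0i, 1.00),   # dough-mature plateau
      ms(0.82, 0.05, 0.13, 1.10, 0.70 + 0i, 0.70)),  # harvested: bare soil
    `D-J` = list(
      ms(0.78, 0.06, 0.16, 1.05, 0.75 + 0i, 0.55),   # seedling over moist soil
      ms(0.28, 0.24, 0.48, 1.05, 0.50 + 0i, 1.00),
      ms(0.34, 0.20, 0.46, 1.05, 0.55 + 0i, 1.00),
      ms(0.26, 0.22, 0.52, 1.05, 0.50 + 0i, 1.00),
      ms(0.32, 0.21, 0.47, 1.05, 0.55 + 0i, 1.00),
      ms(0.30, 0.22, 0.48, 1.05, 0.55 + 0i, 1.00)))  # still vegetated
  new("PhenologySchedule",
      dates = c("2015-06-12", "2015-07-30", "2015-08-23",
                "2015-09-16", "2015-10-10", "2015-11-03"),
      stages = c("Seedling", "Seedling-Elongation", "Booting-Heading",
                 "Heading-Flowering", "Dough-Mature", "Harvest"),
      specs = specs)
}

#' Default parcel layout
#'
#' Rectangular parcels on a regular grid emulating the study-area structure:
#' 28 T-H and 14 D-J rice parcels plus 8 parcels each of water, urban and
#' shoal naked land, each parcel 12x12 pixels, alternately assigned to the
#' train and verify splits (50/50 per class, disjoint by construction).
#'
#' @param parcelSize parcel side length in pixels (default 12).
#' @param cell grid cell side length in pixels (default 16).
#' @return a \linkS4class{ParcelLayout}.
#' @export
defaultParcelLayout <- function(parcelSize = 12L, cell = 16L) {
  classNames <- c("water", "urban", "SNL", "T-H", "D-J")
  counts <- c(water = 8L, urban = 8L, SNL = 8L, `T-H` = 28L, `D-J` = 14L)
  classIds <- rep(seq_along(classNames), counts)
  ncells <- length(classIds)
  gcols <- 8L
  grows <- ceiling(ncells / gcols)
  # interleave classes across the grid so no class is spatially clustered
  ord <- order(rep_len(seq_len(gcols), ncells), seq_len(ncells))
  classIds <- classIds[ord]
  split <- character(ncells)
  for (k in seq_along(classNames)) {
    idx <- which(classIds == k)
    split[idx] <- rep_len(c("train", "verify"), length(idx))
  }
  cellRow <- (seq_len(ncells) - 1L) %/% gcols
  cellCol <- (seq_len(ncells) - 1L) %% gcols
  off <- (cell - parcelSize) %/% 2L
  parcels <- data.frame(
    row = cellRow * cell + off + 1L,
    col = cellCol * cell + off + 1L,
    height = parcelSize, width = parcelSize,
    class = classIds, split = split,
    stringsAsFactors = FALSE)
  new("ParcelLayout", rows = as.integer(grows * cell),
      cols = as.integer(gcols * cell),
      parcels = parcels, classNames = classNames)
}

#' Build a speckled multi-class scene for one date
#'
#' Samples fully developed speckle parcel-by-parcel from the class-date
#' mixture covariances of the schedule; background pixels carry an
#' unlabeled low-power surface texture. The RNG is seeded once, so a fixed
#' seed reproduces the scene bit-for-bit.
#'
#' @param layout a \linkS4class{ParcelLayout}.
#' @param schedule a \linkS4class{PhenologySchedule} covering the layout's
#'   classes.
#' @param dateIndex date index 1..6.
#' @param seed integer RNG seed.
#' @return list with \code{image} (\linkS4class{ScatteringImage}) and
#'   \code{mask} (\linkS4class{LabelMask}).
#' @export
buildScene <- function(layout, schedule, dateIndex, seed) {
  if (dateIndex < 1 || dateIndex > length(schedule@dates))
    stop("date index out of range", call. = FALSE)
  missing <- setdiff(layout@classNames, names(schedule@specs))
  if (length(missing))
    stop("schedule lacks classes: ", paste(missing, collapse = ", "),
         call. = FALSE)
  set.seed(as.integer(seed))
  tag <- schedule@dates[dateIndex]
  bgSpec <- mixtureSpec(0.9, 0.02, 0.08, copolRatio = 1.05,
                        copolCoherence = 0.5 + 0i, totalPower = 0.35)
  img <- drawSpeckle(mixtureCovariance(bgSpec), layout@rows, layout@cols, tag)
  labels <- matrix(0L, layout@rows, layout@cols)
  parcelIds <- matrix(0L, layout@rows, layout@cols)
  p <- layout@parcels
  for (i in seq_len(nrow(p))) {
    cls <- layout@classNames[p$class[i]]
    c3 <- mixtureCovariance(schedule@specs[[cls]][[dateIndex]])
    tile <- drawSpeckle(c3, p$height[i], p$width[i])
    ri <- p$row[i]:(p$row[i] + p$height[i] - 1L)
    ci <- p$col[i]:(p$col[i] + p$width[i] - 1L)
    img@shh[ri, ci] <- tile@shh
    img@shv[ri, ci] <- tile@shv
    img@svh[ri, ci] <- tile@svh
    img@svv[ri, ci] <- tile@svv
    labels[ri, ci] <- p$class[i]
    parcelIds[ri, ci] <- i
  }
  mask <- new("LabelMask", labels = labels, classNames = layout@classNames,
              parcels = parcelIds,
              parcelInfo = data.frame(parcel = seq_len(nrow(p)),
                                      class = p$class, split = p$split,
                                      stringsAsFactors = FALSE))
  list(image = img, mask = mask)
}

#' Build the full six-date scene stack
#'
#' @param layout a \linkS4class{ParcelLayout}.
#' @param schedule a \linkS4class{PhenologySchedule}.
#' @param seed integer base seed; date d uses seed + d - 1.
#' @return list with \code{images} (list of six
#'   \linkS4class{ScatteringImage}s) and \code{mask}.
#' @export
buildSceneStack <- function(layout = defaultParcelLayout(),
                            schedule = defaultPhenologySchedule(),
                            seed = 1L) {
  scenes <- lapply(seq_along(schedule@dates), function(d)
    buildScene(layout, schedule, d, seed = as.integer(seed) + d - 1L))
  list(images = lapply(scenes, `[[`, "image"), mask = scenes[[1]]$mask)
}
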