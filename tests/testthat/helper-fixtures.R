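# Shared fixtures: all synthetic, built in code at test time.

# Random quad-pol image with reciprocity (svh == shv), CN(0,1)-ish channels.
randomImage <- function(rows, cols, seed = 42L) {
  set.seed(seed)
  rc <- function() matrix(complex(real = rnorm(rows * cols),
                                  imaginary = rnorm(rows * cols)),
                          rows, cols) / sqrt(2)
  hv <- rc()
  new("ScatteringImage", shh = rc(), shv = hv, svh = hv, svv = rc())
}

# Random single-pixel 2x2 Sinclair matrix (reciprocal).
randomSinclair <- function() {
  z <- complex(real = rnorm(3), imaginary = rnorm(3))
  matrix(c(z[1], z[2], z[2], z[3]), 2, 2)
}

# Single-pixel Hermitian T3 field with the given diagonal.
diagT3Field <- function(d) {
  entries <- array(0 + 0i, c(1, 1, 3, 3))
  for (i in 1:3) entries[1, 1, i, i] <- d[i]
  new("HermitianField", entries = entries, window = 1L, kind = "T3")
}

# Single-pixel CoPolStats with the given complex rho (|r| = 1).
rhoStats <- function(rho) {
  new("CoPolStats", rho = matrix(as.complex(rho), 1, 1),
      r = matrix(complex(modulus = 1, argument = Arg(rho)), 1, 1),
      validMask = matrix(TRUE, 1, 1))
}

# Closed-form C3 of equal-power co-pol channels with cross-correlation `cc`
# and zero cross-pol (lexicographic basis).
copolMomentC3 <- function(cc) {
  matrix(c(1, 0, Conj(cc),
           0, 0, 0,
           cc, 0, 1), 3, 3)
}

paramRasterFor <- function(m)
  new("ParamRaster", values = m, name = "x", units = "degrees",
      validMask = is.finite(m))

# Rotate a Sinclair matrix about the radar line of sight by angle phi.
rotateSinclair <- function(s, phi) {
  R <- matrix(c(cos(phi), -sin(phi), sin(phi), cos(phi)), 2, 2)
  t(R) %*% s %*% R
}
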