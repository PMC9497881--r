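randImage <- function(n = 64L) {
  matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
}
randKspace <- function(n = 64L, nc = 4L) {
  array(complex(real = rnorm(n * n * nc), imaginary = rnorm(n * n * nc)),
        c(n, n, nc))
}

test_that("forward operator reduces to the unitary FFT for one uniform coil", {
  c1 <- simulateCoils(c(64L, 64L), 1L)
  op <- systemOperator(c1, buildFullMask(64L))
  set.seed(1)
  x <- randImage()
  expect_lt(max(abs(applyForward(op, x)[, , 1] - oUfft2(x))), 1e-10)
  expect_lt(max(abs(applyAdjoint(op, applyForward(op, x)) - x)), 1e-10)
  expect_true(all(applyForward(op, matrix(0i, 64L, 64L)) == 0))
})

test_that("forward and adjoint pass the dot-product test for every mask kind", {
  set.seed(2)
  coils <- simulateCoils(c(64L, 64L), 4L, seed = 3L)
  masks <- list(buildFullMask(64L),
                buildVDMask(64L, 24L, seed = 5L),
                buildUniformMask(64L, 2L),
                buildPFMask(64L, 6 / 8))
  for (mk in masks) {
    op <- systemOperator(coils, mk)
    for (rep in 1:5) {
      x <- randImage(); y <- randKspace()
      lhs <- sum(applyForward(op, x) * Conj(y))
      rhs <- sum(x * Conj(applyAdjoint(op, y)))
      expect_lt(abs(lhs - rhs) / abs(lhs), 1e-8)
    }
    # against the independent plain-fft implementation
    x <- randImage()
    expect_lt(max(abs(applyForward(op, x) -
                        oForward(x, sensitivities(coils), sampledLines(mk)))),
              1e-10)
  }
})

test_that("A^H A is the identity under full sampling with normalized maps", {
  coils <- simulateCoils(c(64L, 64L), 8L, seed = 7L)
  op <- systemOperator(coils, buildFullMask(64L))
  x <- matrix(1 + 0i, 64L, 64L)
  expect_lt(max(abs(applyAdjoint(op, applyForward(op, x)) - x)), 1e-8)
  # operator norm of A is at most 1 (masking is a projection)
  opU <- systemOperator(coils, buildVDMask(64L, 24L, seed = 9L))
  expect_lte(operatorNorm2(opU), 1 + 1e-6)
})

test_that("coil maps estimated from the calibration scan match the truth", {
  ph <- makePhantom(c(128L, 128L), nLesions = 2L, seed = 7L)
  co <- simulateCoils(c(128L, 128L), 8L, seed = 8L)
  pr <- protocolParams(matrixRead = 128L, matrixPE = 128L, acceleration = 3,
                       nACS = 24L)
  ref <- acquireReference(ph, co, pr, noiseSigma = 0, decay = FALSE)
  est <- estimateMaps(ref)

  # RSS normalization invariant on the estimated support
  rss <- sqrt(apply(abs(sensitivities(est))^2, c(1, 2), sum))
  expect_lt(max(abs(rss[supportMask(est)] - 1)), 1e-6)
  expect_true(all(rss[!supportMask(est)] == 0))

  # per-coil normalized correlation with the generator's maps > 0.99
  sup <- supportMask(est)
  for (k in 1:8) {
    a <- sensitivities(est)[, , k][sup]
    b <- sensitivities(co)[, , k][sup]
    corr <- abs(sum(a * Conj(b))) / sqrt(sum(abs(a)^2) * sum(abs(b)^2))
    expect_gt(corr, 0.99)
  }
})

test_that("single uniform coil with a zero-phase object estimates to 1", {
  ph <- fixPhantom64(phaseAmplitude = 0)
  c1 <- simulateCoils(c(64L, 64L), 1L)
  ref <- acquireReference(ph, c1, fixProtocol(nACS = 24L), noiseSigma = 0,
                          decay = FALSE)
  est <- estimateMaps(ref)
  sup <- supportMask(est)
  expect_gt(sum(sup), 100)
  expect_lt(max(abs(sensitivities(est)[, , 1][sup] - 1)), 1e-8)
})

test_that("map estimation rejects unusable input", {
  ph <- fixPhantom64()
  c1 <- simulateCoils(c(64L, 64L), 1L)
  ks <- acquire(ph, c1, buildFullMask(64L), fixProtocol())
  expect_error(estimateMaps(ks), "reference")
  ref <- acquireReference(ph, c1, fixProtocol(nACS = 24L))
  ref@data[] <- 0i
  expect_error(estimateMaps(ref), "zero")
})
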