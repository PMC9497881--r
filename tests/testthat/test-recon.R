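test_that("unregularized full-sampling reconstruction is exact", {
  ph <- fixPhantom64(phaseAmplitude = 0.3)
  c1 <- simulateCoils(c(64L, 64L), 1L)
  ks <- acquire(ph, c1, buildFullMask(64L), fixProtocol(), noiseSigma = 0,
                decay = FALSE)
  gt <- groundTruthImage(ph, 99)
  res <- csReconstruct(ks, c1, reconConfig(lam = 0, nIter = 5L, tol = 0))
  relErr <- sqrt(sum(abs(reconImage(res) - gt)^2)) / sqrt(sum(abs(gt)^2))
  expect_lt(relErr, 1e-6)
})

test_that("objective trace is non-increasing for both solvers", {
  ph <- makePhantom(c(64L, 64L), nLesions = 1L, seed = 3L)
  co <- simulateCoils(c(64L, 64L), 4L, seed = 4L)
  mk <- buildVDMask(64L, 24L, seed = 5L)
  ks <- acquire(ph, co, mk, fixProtocol(accel = 3), noiseSigma = 0.01,
                seed = 6L)
  for (solver in c("ista", "fista_restart")) {
    res <- csReconstruct(ks, co, reconConfig(nIter = 40L, tol = 0,
                                             solver = solver))
    expect_true(all(diff(objectiveTrace(res)) <= 1e-10))
    expect_identical(res@nIterRun, 40L)
  }
})

test_that("wavelet-domain l1 norm of the solution decreases with lambda", {
  ph <- makePhantom(c(64L, 64L), nLesions = 1L, seed = 3L)
  co <- simulateCoils(c(64L, 64L), 4L, seed = 4L)
  mk <- buildVDMask(64L, 24L, seed = 5L)
  ks <- acquire(ph, co, mk, fixProtocol(accel = 3), noiseSigma = 0.01,
                seed = 6L)
  w <- waveletOperator()
  l1 <- vapply(c(1e-4, 1e-3, 1e-2, 0.05, 0.2), function(lam) {
    res <- csReconstruct(ks, co, reconConfig(lam = lam, nIter = 60L, tol = 0), w)
    sum(abs(waveletForward(w, reconImage(res))))
  }, numeric(1))
  expect_true(all(diff(l1) < 1e-8))
})

test_that("CS reconstruction beats the zero-filled adjoint at acceleration 3", {
  ph <- makePhantom(c(128L, 128L), nLesions = 2L, seed = 7L)
  co <- simulateCoils(c(128L, 128L), 8L, seed = 8L)
  pr <- protocolParams(matrixRead = 128L, matrixPE = 128L, acceleration = 3,
                       nACS = 24L)
  gt <- groundTruthImage(ph, pr@teMs)
  mk <- buildVDMask(128L, 43L, seed = 11L)
  ks <- acquire(ph, co, mk, pr, noiseSigma = 0.01, seed = 12L)
  ref <- acquireReference(ph, co, pr, noiseSigma = 0.01, seed = 13L)
  maps <- estimateMaps(ref)
  res <- csReconstruct(ks, maps, reconConfig(nIter = 60L))
  expect_lt(fixNRMSE(reconImage(res), gt), fixNRMSE(zeroFilledRecon(ks, maps), gt))
})

test_that("homodyne is exact on zero-phase objects with full data", {
  ph <- fixPhantom64(phaseAmplitude = 0)
  c1 <- simulateCoils(c(64L, 64L), 1L)
  ks <- acquire(ph, c1, buildPFMask(64L, 1), fixProtocol(), noiseSigma = 0,
                decay = FALSE)
  gt <- abs(groundTruthImage(ph, 99))
  expect_lt(max(abs(homodyneRecon(ks) - gt)), 1e-8)
  # multi-coil variant with the generator's maps
  co <- simulateCoils(c(64L, 64L), 8L, seed = 2L)
  ks8 <- acquire(ph, co, buildPFMask(64L, 1), fixProtocol(), noiseSigma = 0,
                 decay = FALSE)
  expect_lt(max(abs(homodyneRecon(ks8, co) - gt)), 1e-8)
})

test_that("homodyne beats the zero-filled adjoint on smooth-phase phantoms", {
  ph <- makePhantom(c(128L, 128L), nLesions = 2L, seed = 7L)  # smooth phase
  co <- simulateCoils(c(128L, 128L), 8L, seed = 8L)
  pr <- protocolParams(matrixRead = 128L, matrixPE = 128L, acceleration = 2,
                       partialFourier = 6 / 8, nACS = 24L)
  gt <- groundTruthImage(ph, pr@teMs)
  ks <- acquire(ph, co, buildPFMask(128L, 6 / 8), pr, noiseSigma = 0.01,
                seed = 14L)
  expect_lt(fixNRMSE(homodyneRecon(ks, co), gt),
            fixNRMSE(zeroFilledRecon(ks, co), gt))
  expect_true(all(homodyneRecon(ks, co) >= 0))
})

test_that("homodyne rejects insufficient coverage", {
  ph <- fixPhantom64()
  c1 <- simulateCoils(c(64L, 64L), 1L)
  ks <- acquire(ph, c1, buildUniformMask(64L, 2L), fixProtocol(accel = 2))
  expect_error(homodyneRecon(ks), "partial-Fourier")
})

test_that("solver input validation catches broken data", {
  ph <- fixPhantom64()
  c1 <- simulateCoils(c(64L, 64L), 1L)
  ks <- acquire(ph, c1, buildFullMask(64L), fixProtocol())
  ks@data[1, 1, 1] <- NaN * 1i
  expect_error(csReconstruct(ks, c1), "non-finite")
})
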