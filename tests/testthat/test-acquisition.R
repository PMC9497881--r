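test_that("echo-train length follows the floor(matrixPE / R) budget", {
  expect_identical(echoTrainLength(protocolParams(matrixPE = 253L,
                                                  acceleration = 3)), 84L)
  expect_identical(echoTrainLength(protocolParams(matrixPE = 250L,
                                                  acceleration = 2)), 125L)
  # no acceleration: the full matrix in one train
  for (n in c(64L, 100L, 253L))
    expect_identical(echoTrainLength(protocolParams(matrixPE = n,
                                                    acceleration = 1)), n)
  expect_error(echoTrainLength(protocolPreset("skyra_mtse")), "single-shot")
})

test_that("variable-density mask meets its budget with a denser center", {
  m <- buildVDMask(253L, 84L, seed = 1L)
  expect_identical(length(sampledLines(m)), 84L)
  expect_identical(maskKind(m), "variable_density")
  # fully sampled contiguous center block of round(centerFraction * budget)
  blk <- acsLines(m)
  expect_identical(length(blk), 24L)
  expect_true(all(diff(sort(blk)) == 1L))
  expect_true(127L %in% blk)  # DC line of a 253-line axis
  expect_true(all(blk %in% sampledLines(m)))

  # budget = nPE degenerates to the full mask
  expect_identical(maskKind(buildVDMask(64L, 64L)), "full")

  # windowed density: center 21-line window denser than outer windows
  ctr <- 127L
  winCount <- function(lines, at) sum(lines >= at - 10L & lines <= at + 10L)
  centerCounts <- outerCounts <- numeric(200)
  for (s in 1:200) {
    ln <- sampledLines(buildVDMask(253L, 84L, seed = s))
    centerCounts[s] <- winCount(ln, ctr)
    outerCounts[s] <- (winCount(ln, 21L) + winCount(ln, 233L)) / 2
  }
  expect_gt(mean(centerCounts), mean(outerCounts))

  # determinism and error cases
  expect_identical(sampledLines(buildVDMask(253L, 84L, seed = 4L)),
                   sampledLines(buildVDMask(253L, 84L, seed = 4L)))
  expect_error(buildVDMask(64L, 65L), "budget")
  expect_error(buildVDMask(64L, 10L, centerFraction = 0.01), ">= 1")
})

test_that("uniform mask is an arithmetic progression with the closed-form count", {
  m <- buildUniformMask(250L, 2L)
  expect_identical(length(sampledLines(m)), 125L)
  # 0-based offset 1, r = 3 on 16 lines: 0-based {1,4,7,10,13}
  m2 <- buildUniformMask(16L, 3L, offset = 1L)
  expect_identical(sampledLines(m2), c(2L, 5L, 8L, 11L, 14L))
  expect_identical(length(sampledLines(m2)),
                   as.integer(ceiling((16 - 1) / 3)))
  # r = 1 is the identity
  expect_identical(length(sampledLines(buildUniformMask(77L, 1L))), 77L)
  expect_error(buildUniformMask(64L, 0L), "r")
  expect_error(buildUniformMask(64L, 4L, offset = 4L), "offset")
})

test_that("partial-Fourier mask retains a contiguous block containing DC", {
  expect_identical(length(sampledLines(buildPFMask(256L, 6 / 8))), 192L)
  m <- buildPFMask(253L, 6 / 8)
  ln <- sampledLines(m)
  expect_identical(length(ln), as.integer(ceiling(0.75 * 253)))  # 190
  expect_true(all(diff(sort(ln)) == 1L))
  expect_true(127L %in% ln)  # 0-based center index 126
  expect_identical(maskKind(buildPFMask(64L, 1)), "full")
  expect_error(buildPFMask(64L, 0.5), "half")
})

test_that("slice ordering strides by the increment and is a permutation", {
  # 0-based (0,4,1,5,2,6,3,7) translated to 1-based
  expect_identical(sliceOrder(8L, 4L), c(1L, 5L, 2L, 6L, 3L, 7L, 4L, 8L))
  expect_identical(sliceOrder(5L, 1L), 1:5)
  for (n in c(7L, 12L, 32L)) for (inc in c(2L, 4L)) {
    o <- sliceOrder(n, inc)
    expect_identical(sort(o), seq_len(n))
    # within a pass, temporally adjacent slices differ by the increment
    d <- diff(o)
    expect_true(all(abs(d) == inc | d < 0))
  }
  expect_error(sliceOrder(4L, 8L), "increment")
})

test_that("acquisition reduces to the unitary FFT in the decay-free limit", {
  ph <- fixPhantom64(phaseAmplitude = 0.3)
  ph@t2Map <- matrix(1e15, 64L, 64L)  # T2 far beyond the train: no decay
  c1 <- simulateCoils(c(64L, 64L), 1L)
  pr <- fixProtocol()
  ks <- acquire(ph, c1, buildFullMask(64L), pr, noiseSigma = 0)
  img <- protonDensity(ph) * exp(1i * phaseMap(ph))
  expect_lt(max(abs(kspaceArray(ks)[, , 1] - oUfft2(img))), 1e-10)
})

test_that("T2 decay along the echo train broadens the phase-encode PSF", {
  n <- 64L
  fwhm <- function(decay) {
    ph <- makePhantom(c(n, n), nLesions = 0L, seed = 1L, textureSd = 0,
                      phaseAmplitude = 0)
    pd <- matrix(0, n, n); pd[33, 33] <- 1
    ph@protonDensity <- pd
    ph@t2Map <- matrix(80, n, n)
    c1 <- simulateCoils(c(n, n), 1L)
    ks <- acquire(ph, c1, buildFullMask(n), fixProtocol(), ordering = "linear",
                  decay = decay)
    prof <- abs(zeroFilledRecon(ks, c1))[, 33]
    pk <- which.max(prof)
    half <- prof[pk] / 2
    # linear interpolation of the half-max crossings on either side
    up <- pk; while (prof[up + 1] > half) up <- up + 1
    dn <- pk; while (prof[dn - 1] > half) dn <- dn - 1
    fu <- (prof[up] - half) / (prof[up] - prof[up + 1])
    fd <- (prof[dn] - half) / (prof[dn] - prof[dn - 1])
    (up + fu) - (dn - fd)
  }
  expect_gt(fwhm(TRUE), 1)
  expect_gt(fwhm(TRUE), fwhm(FALSE))
})

test_that("acquisition noise has the configured component-wise sigma", {
  n <- 64L
  ph <- fixPhantom64()
  ph@protonDensity <- matrix(0, n, n)   # zero object: pure noise out
  c1 <- simulateCoils(c(n, n), 1L)
  pr <- protocolParams(matrixRead = 160L, matrixPE = n, acceleration = 1,
                       nACS = 16L)
  # widen readout so the sample count exceeds 10^4
  ph2 <- makePhantom(c(n, 160L), nLesions = 0L, seed = 1L, textureSd = 0)
  ph2@protonDensity <- matrix(0, n, 160L)
  c2 <- simulateCoils(c(n, 160L), 1L)
  s <- 0.37
  ks <- acquire(ph2, c2, buildFullMask(n), pr, noiseSigma = s, seed = 21L)
  re <- Re(kspaceArray(ks)[, , 1])
  expect_gt(length(re), 1e4)
  expect_lt(abs(sd(as.vector(re)) - s) / s, 0.05)
  # determinism of the draw
  ks2 <- acquire(ph2, c2, buildFullMask(n), pr, noiseSigma = s, seed = 21L)
  expect_identical(kspaceArray(ks), kspaceArray(ks2))
})

test_that("reference scan is a contiguous center block matching full data", {
  ph <- fixPhantom64()
  c1 <- simulateCoils(c(64L, 64L), 1L)
  pr <- fixProtocol(nACS = 24L)
  ref <- acquireReference(ph, c1, pr, noiseSigma = 0, decay = FALSE)
  expect_true(ref@isReference)
  ln <- sort(sampledLines(samplingMask(ref)))
  expect_identical(length(ln), 24L)
  expect_true(all(diff(ln) == 1L))
  expect_true(33L %in% ln)  # DC line of a 64-line axis

  # center rows equal the corresponding rows of a full acquisition
  full <- acquire(ph, c1, buildFullMask(64L), pr, noiseSigma = 0,
                  decay = FALSE)
  expect_lt(max(abs(kspaceArray(ref)[ln, , 1] - kspaceArray(full)[ln, , 1])),
            1e-10)

  # degenerate full-ACS reference equals a full acquisition
  prFull <- fixProtocol(nACS = 64L)
  refFull <- acquireReference(ph, c1, prFull, noiseSigma = 0, decay = FALSE)
  expect_lt(max(abs(kspaceArray(refFull) - kspaceArray(full))), 1e-10)

  expect_error(acquireReference(ph, c1, fixProtocol(nACS = 0L)), "nACS")
})
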