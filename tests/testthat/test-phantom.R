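test_that("phantom generation respects labels, determinism and T2 classes", {
  # zero-lesion case: only background + organ classes
  ph0 <- makePhantom(c(64L, 64L), nLesions = 0L, seed = 1L)
  expect_true(all(tissueLabels(ph0) %in% 0:4))
  expect_identical(nrow(lesionList(ph0)), 0L)

  # seed determinism: bit-identical maps
  a <- makePhantom(c(128L, 128L), nLesions = 3L, seed = 7L)
  b <- makePhantom(c(128L, 128L), nLesions = 3L, seed = 7L)
  expect_identical(protonDensity(a), protonDensity(b))
  expect_identical(t2Map(a), t2Map(b))
  expect_identical(phaseMap(a), phaseMap(b))
  expect_identical(tissueLabels(a), tissueLabels(b))

  # fluid lesions: T2 contrast against parenchyma, by direct masking
  ph <- makePhantom(c(128L, 128L), nLesions = 2L, lesionClasses = "fluid",
                    seed = 3L)
  lm <- tissueLabels(ph) == 5L
  pm <- tissueLabels(ph) == 2L
  expect_gt(sum(lm), 0)
  expect_gt(mean(t2Map(ph)[lm]), 4 * mean(t2Map(ph)[pm]))

  # configured class ranges hold exactly on the masks
  phs <- makePhantom(c(96L, 96L), nLesions = 2L, lesionClasses = "solid",
                     seed = 11L)
  sm <- tissueLabels(phs) == 6L
  expect_true(all(t2Map(phs)[sm] >= 60 & t2Map(phs)[sm] <= 120))
  expect_true(all(t2Map(ph)[lm] >= 500))
  expect_true(all(t2Map(ph)[pm] >= 40 & t2Map(ph)[pm] <= 60))
})

test_that("phantom invariants hold and degenerate inputs error", {
  ph <- makePhantom(c(64L, 64L), nLesions = 1L, seed = 5L)
  expect_true(all(protonDensity(ph) >= 0))
  sup <- tissueLabels(ph) != 0L
  expect_true(all(t2Map(ph)[sup] > 0))
  expect_identical(dim(protonDensity(ph)), dim(phaseMap(ph)))

  expect_error(makePhantom(c(16L, 64L), seed = 1L), "rows")
  # impossible placement: far more lesions than the parenchyma can hold
  expect_error(
    makePhantom(c(48L, 48L), nLesions = 60L, seed = 2L,
                maxPlacementTries = 10L),
    "failed to place")
})

test_that("ground-truth image applies T2 weighting and phase", {
  ph <- fixPhantom64()
  gt <- groundTruthImage(ph, teMs = 100)
  expect_type(gt, "complex")
  expect_equal(abs(gt), protonDensity(ph) * exp(-100 / t2Map(ph)))
  # long-T2 (fluid) pixels retain more signal than parenchyma at equal PD
  expect_equal(Arg(gt[abs(gt) > 0]),
               phaseMap(ph)[abs(gt) > 0], tolerance = 1e-12)
})

test_that("coil simulation is RSS-normalized, smooth and deterministic", {
  # single-coil convention: sensitivity identically 1
  c1 <- simulateCoils(c(64L, 64L), 1L)
  expect_true(all(sensitivities(c1) == 1 + 0i))

  cs <- simulateCoils(c(64L, 64L), 8L, seed = 2L)
  rss <- sqrt(apply(abs(sensitivities(cs))^2, c(1, 2), sum))
  expect_lt(max(abs(rss[supportMask(cs)] - 1)), 1e-6)

  # smoothness: finite differences bounded by the construction scale
  for (sm in c(24, 48)) {
    ck <- simulateCoils(c(64L, 64L), 8L, smoothness = sm, seed = 5L)
    s <- sensitivities(ck)
    md <- 0
    for (k in 1:8) {
      m <- s[, , k]
      md <- max(md, abs(m[-1, ] - m[-64, ]), abs(m[, -1] - m[, -64]))
    }
    expect_lt(md, 2 / sm)
  }

  expect_identical(sensitivities(simulateCoils(c(64L, 64L), 4L, seed = 9L)),
                   sensitivities(simulateCoils(c(64L, 64L), 4L, seed = 9L)))
  expect_error(simulateCoils(c(64L, 64L), 0L), "nCoils")
})
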