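test_that("descriptive statistics follow the sample conventions", {
  s <- descriptiveStats(c(4, 4, 4, 4))
  expect_identical(s$sd, 0)
  expect_identical(s$q3 - s$q1, 0)
  s2 <- descriptiveStats(1:5)
  expect_identical(s2$median, 3)
  expect_identical(s2$q1, 2)
  expect_identical(s2$q3, 4)
  # hand arithmetic with the n-1 denominator
  s3 <- descriptiveStats(c(3, 4, 4, 5, 5, 5))
  expect_equal(s3$mean, 4.3333, tolerance = 1e-4)
  expect_equal(s3$sd, 0.8165, tolerance = 1e-4)
  expect_error(descriptiveStats(numeric(0)), "empty")
})

test_that("insufficiency rates reproduce printed numerator/denominator pairs", {
  cases <- list(list(k = 1, n = 101, pct = 1.0),
                list(k = 14, n = 101, pct = 13.9),
                list(k = 5, n = 54, pct = 9.3),
                list(k = 11, n = 54, pct = 20.4),
                list(k = 2, n = 16, pct = 12.5),
                list(k = 8, n = 16, pct = 50.0))
  for (cs in cases) {
    scores <- c(rep(2L, cs$k), rep(4L, cs$n - cs$k))
    r <- insufficientRate(scores)
    expect_identical(r$count, as.integer(cs$k))
    expect_equal(r$percent, cs$pct, tolerance = 1e-12)
  }
  expect_identical(insufficientRate(c(3L, 4L, 5L))$percent, 0)
  expect_error(insufficientRate(integer(0)), "empty")
})

test_that("exact Wilcoxon matches exhaustive 2^m enumeration", {
  # spec'd fixed case: differences (1, 2, 3, -1, 2, 4)
  x <- c(2, 3, 4, 1, 4, 5); y <- c(1, 1, 1, 2, 2, 1)
  for (zm in c("pratt", "wilcox")) {
    r <- wilcoxonSignedRank(x, y, zeroMethod = zm, mode = "exact")
    expect_equal(r@pValue, oWilcoxonExact(x, y, zm), tolerance = 1e-12)
  }
  # randomized tied ordinal fixtures, m <= 12, both zero methods
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    a <- sample(1:5, n, replace = TRUE)
    b <- sample(1:5, n, replace = TRUE)
    if (all(a == b)) a[1] <- a[1] %% 5 + 1
    for (zm in c("pratt", "wilcox")) {
      r <- wilcoxonSignedRank(a, b, zeroMethod = zm, mode = "exact")
      expect_equal(r@pValue, oWilcoxonExact(a, b, zm), tolerance = 1e-12,
                   label = sprintf("rep %d zm %s", rep, zm))
    }
  }
})

test_that("degenerate and approximate modes behave sensibly", {
  r <- wilcoxonSignedRank(c(3, 3, 4), c(3, 3, 4))
  expect_true(r@degenerate)
  expect_identical(r@pValue, 1)
  expect_identical(r@nEffective, 0L)

  # normal approximation tracks the exact p for moderate n; with n = 12
  # five-point scores (heavy midrank ties) the computed median gap sits
  # near 0.021, so the certified bound is 0.03
  set.seed(5)
  gaps <- replicate(100, {
    a <- sample(1:5, 12, replace = TRUE)
    b <- sample(1:5, 12, replace = TRUE)
    if (all(a == b)) b[1] <- b[1] %% 5 + 1
    pe <- wilcoxonSignedRank(a, b, mode = "exact")@pValue
    pa <- wilcoxonSignedRank(a, b, mode = "approx")@pValue
    abs(pe - pa)
  })
  expect_lt(median(gaps), 0.03)

  # auto mode switches at the cutoff
  a <- rep(c(1L, 4L), 20); b <- rep(c(2L, 3L), 20)
  expect_identical(wilcoxonSignedRank(a, b, mode = "auto")@method,
                   "normal_approx")
  expect_identical(
    wilcoxonSignedRank(a[1:10], b[1:10], mode = "auto")@method, "exact")
})

test_that("agreement with the reference implementation absent ties and zeros", {
  set.seed(8)
  for (rep in 1:10) {
    a <- rnorm(10); b <- rnorm(10)   # continuous: no ties, no zeros
    ours <- wilcoxonSignedRank(a, b, mode = "exact")
    ref <- wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(ours@pValue, ref$p.value, tolerance = 1e-12)
  }
})

test_that("sequence comparison runs three pairs with Bonferroni reporting", {
  rt <- simulateRatings(60, c(ssfse_conv = 3.3, mtse = 3.5, ssfse_cs = 4.3),
                        readerSd = 0.7, seed = 100L)
  out <- compareSequences(rt, "overall")
  expect_identical(nrow(out), 3L)
  expect_setequal(out$pair, c("ssfse_conv-mtse", "ssfse_conv-ssfse_cs",
                              "mtse-ssfse_cs"))
  # family-wise declarations never exceed uncorrected declarations
  expect_lte(sum(out$significant_bonferroni), sum(out$significant))
  expect_true(all(out$p_bonferroni >= out$p_value))

  # identical score columns: nothing significant
  df <- ratingScores(rt)
  df$score <- 3L
  expect_error(compareSequences(ratingTable(df), "overall"), NA)
  outFlat <- compareSequences(ratingTable(df), "overall")
  expect_true(all(!outFlat$significant))
  # the configured default threshold
  expect_identical(formals(compareSequences)$alpha, 0.025)
})

test_that("rating simulation is deterministic and matches its censored mean", {
  r1 <- simulateRatings(50, readerSd = 0.7, seed = 3L)
  r2 <- simulateRatings(50, readerSd = 0.7, seed = 3L)
  expect_identical(ratingScores(r1), ratingScores(r2))

  # zero reader noise pins the score at the rounded latent quality
  r0 <- simulateRatings(20, c(ssfse_cs = 4.0), readerSd = 0, seed = 1L)
  expect_true(all(ratingScores(r0)$score == 4L))

  # simulated mean difference matches the censored-Gaussian closed form
  big <- simulateRatings(10000, c(mtse = 3.0, ssfse_cs = 4.0),
                         readerSd = 0.7, seed = 9L)
  df <- ratingScores(big)
  simDiff <- mean(df$score[df$sequence == "ssfse_cs"]) -
             mean(df$score[df$sequence == "mtse"])
  oracleDiff <- oCensoredMean(4.0, 0.7) - oCensoredMean(3.0, 0.7)
  expect_lt(abs(simDiff - oracleDiff), 0.1)
})

test_that("rating tables validate and round-trip through CSV", {
  rt <- simulateRatings(10, seed = 2L)
  path <- tempfile(fileext = ".csv")
  writeRatingTable(rt, path)
  back <- readRatingTable(path)
  expect_identical(ratingScores(back), ratingScores(rt))

  bad <- ratingScores(rt); bad$score[1] <- 9L
  expect_error(ratingTable(bad), "1..5")
  dup <- rbind(ratingScores(rt), ratingScores(rt)[1, ])
  expect_error(ratingTable(dup), "at most once")
})
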