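# Reader-study statistics: five-point ordinal rating tables, descriptive
# statistics, insufficiency rates, exact/approximate Wilcoxon signed-rank
# tests (Pratt or Wilcoxon zero handling), pairwise sequence comparisons
# with Bonferroni adjustment, and a synthetic ratings generator so the
# workflow is testable without readers.

#' Construct a rating table
#'
#' @param scores data.frame with columns `case_id`, `sequence`
#'   (`"ssfse_conv"`, `"mtse"`, `"ssfse_cs"`), `criterion` (`"artifact"`,
#'   `"organ_sharpness"`, `"small_structure"`, `"overall"`,
#'   `"liver_lesion"`, `"pancreatic_lesion"`) and integer `score` in 1..5.
#' @return a [RatingTable-class].
#' @export
ratingTable <- function(scores) {
  scores$score <- as.integer(scores$score)
  methods::new("RatingTable", scores = as.data.frame(scores))
}

#' Read / write rating tables as CSV
#'
#' @param path CSV file path.
#' @return `readRatingTable` returns a [RatingTable-class];
#'   `writeRatingTable` returns `path` invisibly.
#' @export
readRatingTable <- function(path) {
  ratingTable(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname readRatingTable
#' @param table a [RatingTable-class].
#' @export
writeRatingTable <- function(table, path) {
  stopifnot(is(table, "RatingTable"))
  utils::write.csv(table@scores, path, row.names = FALSE)
  invisible(path)
}

#' Descriptive statistics of a score vector
#'
#' Mean with sample (n-1) standard deviation, median, quartiles by the
#' inclusive linear-interpolation rule, and the min-max range.
#'
#' @param scores non-empty numeric vector.
#' @return named list: `mean`, `sd`, `median`, `q1`, `q3`, `range`
#'   (length-2 vector).
#' @examples
#' descriptiveStats(c(3, 4, 4, 5, 5, 5))  # mean 4.333, sd 0.8165
#' @export
descriptiveStats <- function(scores) {
  if (length(scores) == 0L) stop("empty score vector")
  q <- stats::quantile(scores, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(mean = mean(scores),
       sd = if (length(scores) > 1L) stats::sd(scores) else 0,
       median = q[2], q1 = q[1], q3 = q[3],
       range = range(scores))
}

#' Insufficiency count and rate
#'
#' A case is insufficient when rated 1 or 2 on the five-point scale. The
#' percentage is reported to one decimal, the convention used when quoting
#' such rates.
#'
#' @param scores non-empty integer vector of five-point scores.
#' @return named list: `count`, `percent` (one decimal).
#' @examples
#' insufficientRate(c(rep(2, 14), rep(4, 87)))  # 14 of 101 -> 13.9%
#' @export
insufficientRate <- function(scores) {
  if (length(scores) == 0L) stop("empty score vector")
  cnt <- sum(scores <= 2)
  list(count = cnt, percent = round(100 * cnt / length(scores), 1))
}

# Exact distribution of the positive-rank sum over all 2^m sign
# assignments, via the generating polynomial prod_i (1 + z^(2*r_i)) on
# doubled ranks (midranks may be half-integers). Returns P(W <= w) and
# P(W >= w) for the observed statistic.
.exactSignedRankP <- function(ranks, w) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  dist <- numeric(total + 1L)   # index k+1 holds count of doubled-sum k
  dist[1L] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), dist[seq_len(total + 1L - r)])
    dist <- dist + shifted
  }
  dist <- dist / 2^length(r2)
  w2 <- round(2 * w)
  sums <- 0:total
  pLess <- sum(dist[sums <= w2 + 1e-9])
  pGreater <- sum(dist[sums >= w2 - 1e-9])
  c(pLess, pGreater)
}

#' Wilcoxon signed-rank test for paired five-point scores
#'
#' Two-sided paired signed-rank test built for heavily tied ordinal data.
#' Zero differences are handled by `"pratt"` (zeros are ranked with the
#' rest, then dropped from the rank sum; the default, appropriate for
#' rating scales with many ties) or `"wilcox"` (zeros discarded before
#' ranking). Ties receive midranks.
#'
#' In `"exact"` mode the null distribution of the positive-rank sum over
#' all `2^m` sign assignments of the nonzero ranked differences is
#' enumerated (via its generating polynomial) and the two-sided p-value is
#' `min(1, 2 * min(P(W <= w), P(W >= w)))`. In `"approx"` mode the normal
#' approximation with midrank tie correction, Pratt zero correction and a
#' 0.5 continuity correction is used. `"auto"` picks exact for at most
#' `exactCutoff` nonzero differences.
#'
#' @param x,y equal-length paired score vectors.
#' @param zeroMethod `"pratt"` or `"wilcox"`.
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @param exactCutoff switch point for `"auto"` (default 25).
#' @param alpha significance threshold recorded in the result (default
#'   0.025).
#' @return a [WilcoxonResult-class]. All-zero differences give the
#'   degenerate result `p = 1` with `degenerate = TRUE`.
#' @export
wilcoxonSignedRank <- function(x, y, zeroMethod = c("pratt", "wilcox"),
                               mode = c("auto", "exact", "approx"),
                               exactCutoff = 25L, alpha = 0.025) {
  zeroMethod <- match.arg(zeroMethod)
  mode <- match.arg(mode)
  if (length(x) != length(y) || length(x) < 1L)
    stop("x and y must be non-empty vectors of equal length")
  d <- as.numeric(x) - as.numeric(y)
  nz <- d != 0
  m <- sum(nz)
  if (m == 0L)
    return(methods::new("WilcoxonResult", statistic = 0, pValue = 1,
                        method = "exact", nEffective = 0L,
                        significant = FALSE, degenerate = TRUE))

  if (zeroMethod == "pratt") {
    rk <- rank(abs(d))          # zeros ranked with the rest ...
    ranks <- rk[nz]             # ... then dropped from the sum
    n0 <- sum(!nz)
  } else {
    dd <- d[nz]
    ranks <- rank(abs(dd))
    n0 <- 0L
  }
  w <- sum(ranks[d[nz] > 0])

  useExact <- switch(mode, exact = TRUE, approx = FALSE, auto = m <= exactCutoff)
  if (useExact) {
    p2 <- .exactSignedRankP(ranks, w)
    p <- min(1, 2 * min(p2))
    method <- "exact"
  } else {
    n <- length(d)
    if (zeroMethod == "pratt") {
      e <- (n * (n + 1) - n0 * (n0 + 1)) / 4
      v <- (n * (n + 1) * (2 * n + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24
    } else {
      e <- m * (m + 1) / 4
      v <- m * (m + 1) * (2 * m + 1) / 24
    }
    ties <- table(ranks)
    v <- v - sum(ties^3 - ties) / 48
    if (v <= 0) {
      p <- 1
    } else {
      z <- (w - e - 0.5 * sign(w - e)) / sqrt(v)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  methods::new("WilcoxonResult", statistic = w, pValue = p, method = method,
               nEffective = as.integer(m), significant = p < alpha,
               degenerate = FALSE)
}

#' Pairwise sequence comparisons for one criterion
#'
#' Runs the three pairwise Wilcoxon signed-rank tests (conv-mtse, conv-cs,
#' mtse-cs) on the cases rated under both members of each pair.
#' Significance is declared on the raw p-value at `alpha` (default 0.025,
#' the conventional threshold for this design); Bonferroni-adjusted
#' p-values for the three-test family are reported alongside.
#'
#' @param table a [RatingTable-class] containing all three sequences for
#'   `criterion`.
#' @param criterion one of the rating criteria.
#' @param alpha per-test significance threshold (default 0.025).
#' @param ... passed to [wilcoxonSignedRank()].
#' @return data.frame with one row per pair: `pair`, `statistic`,
#'   `n_effective`, `p_value`, `p_bonferroni`, `significant`,
#'   `significant_bonferroni`.
#' @export
compareSequences <- function(table, criterion, alpha = 0.025, ...) {
  stopifnot(is(table, "RatingTable"))
  criterion <- match.arg(criterion, .RATING_CRITERIA)
  df <- table@scores[table@scores$criterion == criterion, ]
  if (!all(.RATING_SEQUENCES %in% df$sequence))
    stop("all three sequences must be present for the criterion")
  pairs <- list(c("ssfse_conv", "mtse"), c("ssfse_conv", "ssfse_cs"),
                c("mtse", "ssfse_cs"))
  rows <- lapply(pairs, function(pr) {
    a <- df[df$sequence == pr[1], c("case_id", "score")]
    b <- df[df$sequence == pr[2], c("case_id", "score")]
    common <- intersect(a$case_id, b$case_id)
    if (length(common) < 2L)
      stop(sprintf("fewer than 2 complete pairs for %s-%s", pr[1], pr[2]))
    res <- wilcoxonSignedRank(a$score[match(common, a$case_id)],
                              b$score[match(common, b$case_id)],
                              alpha = alpha, ...)
    data.frame(pair = paste(pr, collapse = "-"), statistic = res@statistic,
               n_effective = res@nEffective, p_value = res@pValue,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- stats::p.adjust(out$p_value, method = "bonferroni")
  out$significant <- out$p_value < alpha
  out$significant_bonferroni <- out$p_bonferroni < alpha
  out
}

#' Simulate a consensus five-point rating table
#'
#' A latent-quality model of the reading session: each case's score for a
#' sequence is `clip(round(latent + N(0, readerSd)), 1, 5)`. One criterion
#' per call; scores are deterministic under a fixed seed.
#'
#' @param nCases number of cases (>= 1).
#' @param latentQuality named numeric vector of latent quality per
#'   sequence; names must be valid sequence labels.
#' @param readerSd reader noise standard deviation (>= 0).
#' @param criterion criterion label for the table.
#' @param seed integer seed.
#' @return a [RatingTable-class].
#' @examples
#' rt <- simulateRatings(10, c(ssfse_conv = 3.5, mtse = 3.4, ssfse_cs = 4.4),
#'                       readerSd = 0.7, seed = 1)
#' head(ratingScores(rt))
#' @export
simulateRatings <- function(nCases,
                            latentQuality = c(ssfse_conv = 3.5, mtse = 3.4,
                                              ssfse_cs = 4.4),
                            readerSd = 0.7, criterion = "overall",
                            seed = NULL) {
  nCases <- .assertScalarCount(nCases, "nCases")
  if (readerSd < 0) stop("readerSd must be >= 0")
  if (is.null(names(latentQuality)) ||
      !all(names(latentQuality) %in% .RATING_SEQUENCES))
    stop("latentQuality must be named with valid sequence labels")
  criterion <- match.arg(criterion, .RATING_CRITERIA)
  .withSeed(seed, {
    rows <- lapply(names(latentQuality), function(sq) {
      noise <- stats::rnorm(nCases, sd = readerSd)
      score <- pmin(5L, pmax(1L, as.integer(round(latentQuality[[sq]] + noise))))
      data.frame(case_id = sprintf("case%03d", seq_len(nCases)),
                 sequence = sq, criterion = criterion, score = score,
                 stringsAsFactors = FALSE)
    })
    ratingTable(do.call(rbind, rows))
  })
}

#' Expected score of the latent-quality rating model
#'
#' Closed-form mean of `clip(round(latent + N(0, sd)), 1, 5)` via the
#' Gaussian CDF over the rounding bins; the independent check for the
#' simulator.
#'
#' @param latent latent quality.
#' @param sd reader noise standard deviation (> 0).
#' @return expected score in `[1, 5]`.
#' @export
expectedRatingMean <- function(latent, sd) {
  if (sd <= 0) return(min(5, max(1, round(latent))))
  p <- numeric(5)
  p[1] <- stats::pnorm((1.5 - latent) / sd)
  for (k in 2:4)
    p[k] <- stats::pnorm((k + 0.5 - latent) / sd) -
            stats::pnorm((k - 0.5 - latent) / sd)
  p[5] <- 1 - stats::pnorm((4.5 - latent) / sd)
  sum((1:5) * p)
}
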