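# Independent oracle implementations used to cross-check the package.
# These deliberately avoid the package's internal code paths: plain fft()
# arithmetic, literal double loops and exhaustive enumeration.

# Centered unitary FFT pair written out directly (not the package helpers).
oShift <- function(m, inverse = FALSE) {
  f <- function(n) {
    s <- if (inverse) floor(n / 2) else n - floor(n / 2)
    c((s + 1L):n, 1L:s)
  }
  m[f(nrow(m)), f(ncol(m)), drop = FALSE]
}
oUfft2 <- function(x) oShift(fft(oShift(x, TRUE))) / sqrt(length(x))
oUifft2 <- function(k) oShift(fft(oShift(k, TRUE), inverse = TRUE)) / sqrt(length(k))

# Independent SENSE forward/adjoint on plain arrays (sens: r x c x nc,
# rows: sampled line indices).
oForward <- function(img, sens, rows) {
  nc <- dim(sens)[3]
  out <- array(0i, dim = c(dim(img), nc))
  for (c in seq_len(nc)) {
    K <- oUfft2(sens[, , c] * img)
    out[rows, , c] <- K[rows, ]
  }
  out
}
oAdjoint <- function(ks, sens, rows) {
  nc <- dim(sens)[3]
  img <- matrix(0i, dim(ks)[1], dim(ks)[2])
  for (c in seq_len(nc)) {
    K <- matrix(0i, dim(ks)[1], dim(ks)[2])
    K[rows, ] <- ks[rows, , c]
    img <- img + Conj(sens[, , c]) * oUifft2(K)
  }
  img
}

# Independent recursive orthonormal 2D Haar analysis (top-left nesting).
oHaar2 <- function(x, levels) {
  step1 <- function(v) {
    n <- length(v)
    o <- v[seq(1, n, 2)]; e <- v[seq(2, n, 2)]
    c((o + e) / sqrt(2), (o - e) / sqrt(2))
  }
  r <- nrow(x); c <- ncol(x)
  for (l in seq_len(levels)) {
    blk <- x[1:r, 1:c, drop = FALSE]
    blk <- apply(blk, 2, step1)
    blk <- t(apply(t(blk), 2, step1))
    x[1:r, 1:c] <- blk
    r <- r %/% 2L; c <- c %/% 2L
  }
  x
}

# Inverse of oHaar2 (independent synthesis path).
oHaar2Inv <- function(x, levels) {
  istep1 <- function(v) {
    n <- length(v); h <- n %/% 2
    a <- v[1:h]; d <- v[(h + 1):n]
    out <- numeric(n)
    out[seq(1, n, 2)] <- (a + d) / sqrt(2)
    out[seq(2, n, 2)] <- (a - d) / sqrt(2)
    out
  }
  rs <- nrow(x) %/% 2L^((levels - 1L):0L)
  cs <- ncol(x) %/% 2L^((levels - 1L):0L)
  for (l in seq_len(levels)) {
    r <- rs[l]; c <- cs[l]
    blk <- x[1:r, 1:c, drop = FALSE]
    blk <- t(apply(t(blk), 2, istep1))
    blk <- apply(blk, 2, istep1)
    x[1:r, 1:c] <- blk
  }
  x
}

# Straightforward double-loop SSIM with Gaussian window over the valid
# region; mirrors the documented definition literally.
oSsim <- function(test, reference, window, sigma = 1.5, k1 = 0.01, k2 = 0.03) {
  half <- (window - 1) / 2
  g <- exp(-((-half):half)^2 / (2 * sigma^2))
  w <- outer(g, g); w <- w / sum(w)
  L <- max(reference)
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  vals <- c()
  for (i in (half + 1):(nrow(test) - half)) {
    for (j in (half + 1):(ncol(test) - half)) {
      px <- test[(i - half):(i + half), (j - half):(j + half)]
      py <- reference[(i - half):(i + half), (j - half):(j + half)]
      mx <- sum(w * px); my <- sum(w * py)
      vx <- sum(w * px^2) - mx^2; vy <- sum(w * py^2) - my^2
      cv <- sum(w * px * py) - mx * my
      vals <- c(vals, ((2 * mx * my + c1) * (2 * cv + c2)) /
                        ((mx^2 + my^2 + c1) * (vx + vy + c2)))
    }
  }
  mean(vals)
}

# Exhaustive 2^m enumeration of the two-sided exact Wilcoxon signed-rank
# p-value (midranks; pratt or wilcox zero handling).
oWilcoxonExact <- function(x, y, zeroMethod = "pratt") {
  d <- as.numeric(x) - as.numeric(y)
  nz <- d != 0
  if (!any(nz)) return(1)
  ranks <- if (zeroMethod == "pratt") rank(abs(d))[nz] else rank(abs(d[nz]))
  w <- sum(ranks[d[nz] > 0])
  m <- length(ranks)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  ws <- as.numeric(signs %*% ranks)
  pl <- mean(ws <= w + 1e-9)
  pg <- mean(ws >= w - 1e-9)
  min(1, 2 * min(pl, pg))
}

# Closed-form expected score of clip(round(latent + N(0, sd)), 1, 5).
oCensoredMean <- function(latent, sd) {
  p <- c(pnorm((1.5 - latent) / sd),
         pnorm((2.5 - latent) / sd) - pnorm((1.5 - latent) / sd),
         pnorm((3.5 - latent) / sd) - pnorm((2.5 - latent) / sd),
         pnorm((4.5 - latent) / sd) - pnorm((3.5 - latent) / sd),
         1 - pnorm((4.5 - latent) / sd))
  sum((1:5) * p)
}

# Small shared fixtures ------------------------------------------------------

fixPhantom64 <- function(...) makePhantom(c(64L, 64L), nLesions = 0L, seed = 42L, ...)

fixProtocol <- function(nPE = 64L, accel = 1, nACS = 16L, ...) {
  protocolParams(matrixRead = 64L, matrixPE = as.integer(nPE),
                 acceleration = accel, nACS = as.integer(nACS), ...)
}

# NRMSE between magnitudes after matching the reference l2 norm.
fixNRMSE <- function(img, gt) {
  t <- abs(img); r <- abs(gt)
  t <- t * sqrt(sum(r^2)) / sqrt(sum(t^2))
  sqrt(sum((t - r)^2)) / sqrt(sum(r^2))
}
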