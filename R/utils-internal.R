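# Internal numeric helpers shared across modules.
#
# k-space convention used package-wide: the DC (zero-frequency) sample of an
# n-point axis sits at 1-based index floor(n/2) + 1, and all FFTs are unitary
# (scaled by 1/sqrt(N)), so forward/adjoint pairs are exact adjoints and
# Parseval holds at machine precision.

.fftshift1 <- function(v) {
  n <- length(v)
  s <- n - floor(n / 2)
  v[c((s + 1L):n, 1L:s)]
}

.ifftshift1 <- function(v) {
  n <- length(v)
  s <- floor(n / 2)
  v[c((s + 1L):n, 1L:s)]
}

.shift_idx <- function(n, inverse = FALSE) {
  s <- if (inverse) floor(n / 2) else n - floor(n / 2)
  c((s + 1L):n, 1L:s)
}

.fftshift2 <- function(m) m[.shift_idx(nrow(m)), .shift_idx(ncol(m)), drop = FALSE]

.ifftshift2 <- function(m) {
  m[.shift_idx(nrow(m), inverse = TRUE), .shift_idx(ncol(m), inverse = TRUE),
    drop = FALSE]
}

# Centered unitary 2D FFT and its inverse.
.ufft2 <- function(x) .fftshift2(stats::fft(.ifftshift2(x))) / sqrt(length(x))

.uifft2 <- function(k) {
  .fftshift2(stats::fft(.ifftshift2(k), inverse = TRUE)) / sqrt(length(k))
}

# 1-based index of the DC phase-encode line for an n-line axis.
.centerLine <- function(n) floor(n / 2) + 1L

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream. `seed = NULL` leaves the stream untouched.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number or NULL")
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic derivation of per-stage seeds from one experiment seed; keeps
# results inside 32-bit integer range.
.stageSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1009 + stage * 9973) %% 2147483647)
}

.assertScalarCount <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) ||
      x < min)
    stop(sprintf("`%s` must be a single integer >= %d", name, min))
  invisible(as.integer(x))
}

# Smooth low-order 2D polynomial on the [-1, 1]^2 grid; used for phase maps
# and coil phase profiles.
.polynomial2d <- function(rows, cols, coef) {
  u <- matrix(seq(-1, 1, length.out = rows), rows, cols)
  v <- matrix(seq(-1, 1, length.out = cols), rows, cols, byrow = TRUE)
  coef[1] + coef[2] * u + coef[3] * v + coef[4] * u^2 + coef[5] * u * v +
    coef[6] * v^2
}

# Separable Gaussian smoothing with periodic boundary, used for smooth
# texture fields in the phantom generator.
.gaussSmooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  g <- exp(-((-half):half)^2 / (2 * sigma^2))
  g <- g / sum(g)
  smooth1 <- function(x) {
    n <- length(x)
    idx <- outer(seq_len(n), (-half):half, function(i, o) ((i + o - 1) %% n) + 1)
    as.numeric(matrix(x[idx], n) %*% g)
  }
  m <- apply(m, 2, smooth1)
  t(apply(m, 1, smooth1))
}
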