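# Orthonormal multilevel 2D Haar transform. With the 1/sqrt(2) analysis
# pair (a = (x1+x2)/sqrt(2), d = (x1-x2)/sqrt(2)) the transform is unitary,
# so synthesis is the exact inverse, Parseval holds to machine precision,
# and the proximal step of the l1 penalty is exact soft-thresholding in the
# coefficient domain.

#' Construct a Haar wavelet operator
#'
#' @param levels decomposition depth (default 3).
#' @param boundary boundary rule; only `"periodic"` is supported (Haar on
#'   even-length axes never crosses the boundary, so the rule only matters
#'   through the padding contract).
#' @param pad zero-pad images whose sides are not divisible by
#'   `2^levels`; if `FALSE`, such shapes are an error.
#' @return a [WaveletOperator-class].
#' @export
waveletOperator <- function(levels = 3L, boundary = "periodic", pad = TRUE) {
  methods::new("WaveletOperator", levels = as.integer(levels),
               boundary = boundary, pad = isTRUE(pad))
}

.haarStepRows <- function(m) {
  n <- nrow(m)
  o <- m[seq(1L, n, 2L), , drop = FALSE]
  e <- m[seq(2L, n, 2L), , drop = FALSE]
  rbind((o + e) / sqrt(2), (o - e) / sqrt(2))
}

.haarStepRowsInv <- function(m) {
  n <- nrow(m)
  h <- n %/% 2L
  a <- m[seq_len(h), , drop = FALSE]
  d <- m[(h + 1L):n, , drop = FALSE]
  out <- m
  out[seq(1L, n, 2L), ] <- (a + d) / sqrt(2)
  out[seq(2L, n, 2L), ] <- (a - d) / sqrt(2)
  out
}

.padTo <- function(image, mult) {
  r <- nrow(image); c <- ncol(image)
  rp <- as.integer(ceiling(r / mult) * mult)
  cp <- as.integer(ceiling(c / mult) * mult)
  if (rp == r && cp == c) return(image)
  out <- matrix(if (is.complex(image)) 0i else 0, rp, cp)
  out[seq_len(r), seq_len(c)] <- image
  out
}

#' @rdname waveletForward
#' @export
setMethod("waveletForward", "WaveletOperator", function(wavelet, image) {
  mult <- 2L^wavelet@levels
  if (nrow(image) %% mult != 0L || ncol(image) %% mult != 0L) {
    if (!wavelet@pad)
      stop("image sides must be divisible by 2^levels (padding disabled)")
    image <- .padTo(image, mult)
  }
  x <- image
  r <- nrow(x); c <- ncol(x)
  for (l in seq_len(wavelet@levels)) {
    blk <- x[seq_len(r), seq_len(c), drop = FALSE]
    blk <- .haarStepRows(blk)
    blk <- t(.haarStepRows(t(blk)))
    x[seq_len(r), seq_len(c)] <- blk
    r <- r %/% 2L; c <- c %/% 2L
  }
  x
})

#' @rdname waveletInverse
#' @export
setMethod("waveletInverse", "WaveletOperator", function(wavelet, coeffs,
                                                        shape = NULL) {
  x <- coeffs
  L <- wavelet@levels
  rs <- nrow(x) %/% 2L^((L - 1L):0L)
  cs <- ncol(x) %/% 2L^((L - 1L):0L)
  for (l in seq_len(L)) {
    r <- rs[l]; c <- cs[l]
    blk <- x[seq_len(r), seq_len(c), drop = FALSE]
    blk <- t(.haarStepRowsInv(t(blk)))
    blk <- .haarStepRowsInv(blk)
    x[seq_len(r), seq_len(c)] <- blk
  }
  if (!is.null(shape)) x <- x[seq_len(shape[1]), seq_len(shape[2]), drop = FALSE]
  x
})

#' Complex soft-thresholding (proximal operator of the l1 norm)
#'
#' Elementwise `sign(x) * max(|x| - t, 0)`; for complex input the magnitude
#' is shrunk and the phase preserved. This is the exact proximal map of
#' `t * ||.||_1`, the step that enforces wavelet-domain sparsity in the
#' reconstruction.
#'
#' @param x numeric or complex array.
#' @param t threshold, `t >= 0`.
#' @return array of the same shape.
#' @examples
#' softThreshold(c(-1.3, 0.2, 2), 0.5)  # -0.8 0.0 1.5
#' @export
softThreshold <- function(x, t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("threshold t must be a single number >= 0")
  if (t == 0) return(x)
  a <- abs(x)
  scale <- ifelse(a > t, (a - t) / a, 0)
  scale[a == 0] <- 0
  x * scale
}
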