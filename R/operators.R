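# System operator (coil maps o unitary FFT o masking), its adjoint, and
# coil-map estimation from the calibration scan.

#' Construct the system operator
#'
#' @param coils a [CoilSet-class].
#' @param mask a [SamplingMask-class] with `nPE` equal to the image rows.
#' @return a [SystemOperator-class].
#' @export
systemOperator <- function(coils, mask) {
  stopifnot(is(coils, "CoilSet"), is(mask, "SamplingMask"))
  methods::new("SystemOperator", coils = coils, mask = mask,
               imageShape = dim(coils@sensitivities)[1:2])
}

#' @rdname applyForward
#' @export
setMethod("applyForward", "SystemOperator", function(op, image) {
  if (!identical(dim(image), op@imageShape))
    stop("image shape does not match the operator")
  nc <- dim(op@coils@sensitivities)[3]
  out <- array(0i, dim = c(op@imageShape, nc))
  lines <- op@mask@lines
  for (c in seq_len(nc)) {
    K <- .ufft2(op@coils@sensitivities[, , c] * image)
    out[lines, , c] <- K[lines, ]
  }
  out
})

#' @rdname applyAdjoint
#' @export
setMethod("applyAdjoint", "SystemOperator", function(op, kspace) {
  if (is(kspace, "KSpaceData")) kspace <- kspace@data
  d <- dim(kspace)
  if (length(d) != 3L || !identical(d[1:2], op@imageShape))
    stop("k-space shape does not match the operator")
  nc <- dim(op@coils@sensitivities)[3]
  if (d[3] != nc) stop("coil count mismatch")
  img <- matrix(0i, op@imageShape[1], op@imageShape[2])
  lines <- op@mask@lines
  for (c in seq_len(nc)) {
    K <- matrix(0i, d[1], d[2])
    K[lines, ] <- kspace[lines, , c]
    img <- img + Conj(op@coils@sensitivities[, , c]) * .uifft2(K)
  }
  img
})

#' Largest eigenvalue of A^H A by power iteration
#'
#' Used to set the gradient step of the proximal-gradient solver
#' (`step = 1 / L`). With RSS-normalized coil maps and the unitary FFT the
#' result is at most 1 (masking is an orthogonal projection).
#'
#' @param op a [SystemOperator-class].
#' @param nIter power-iteration count.
#' @param seed seed for the random start vector.
#' @return estimated largest eigenvalue `L` of `A^H A`.
#' @export
operatorNorm2 <- function(op, nIter = 30L, seed = 1L) {
  v <- .withSeed(seed, matrix(stats::rnorm(prod(op@imageShape)),
                              op@imageShape[1], op@imageShape[2]))
  v <- v / sqrt(sum(abs(v)^2))
  lam <- 0
  for (i in seq_len(nIter)) {
    w <- applyAdjoint(op, applyForward(op, v))
    nw <- sqrt(sum(abs(w)^2))
    if (!is.finite(nw) || nw == 0)
      stop("power iteration failed (operator maps start vector to zero)")
    lam <- nw
    v <- w / nw
  }
  lam
}

#' Estimate coil sensitivity maps from the calibration scan
#'
#' Per-coil low-resolution images are formed by Hann-apodized zero-filled
#' inverse FFT of the autocalibration lines and divided by their
#' root-sum-of-squares, yielding RSS-normalized maps wherever the RSS
#' magnitude exceeds `supportThreshold` times its maximum, and 0 elsewhere
#' (the threshold avoids division blow-up outside the object).
#'
#' @param reference a [KSpaceData-class] with `isReference = TRUE` and at
#'   least 8 calibration lines.
#' @param supportThreshold support cut as a fraction of the peak RSS
#'   magnitude (default 0.05).
#' @return a [CoilSet-class]; `supportMask` marks the retained pixels.
#' @export
estimateMaps <- function(reference, supportThreshold = 0.05) {
  stopifnot(is(reference, "KSpaceData"))
  if (!reference@isReference)
    stop("estimateMaps expects the separate reference (calibration) scan")
  lines <- sort(reference@mask@lines)
  if (length(lines) < 8L) stop("need at least 8 calibration lines")
  if (all(reference@data == 0)) stop("all-zero reference scan")

  d <- dim(reference@data)
  nc <- d[3]
  # Cosine taper symmetric about the DC line: suppresses ringing in the
  # low-resolution coil images, and its conjugate symmetry keeps the
  # low-resolution images free of window-induced phase (a real object
  # yields real coil images).
  ctr <- .centerLine(d[1])
  h <- min(ctr - min(lines), max(lines) - ctr)
  band <- (ctr - h):(ctr + h)
  w <- cos(pi * (band - ctr) / (2 * (h + 1)))^2
  low <- array(0i, dim = d)
  for (c in seq_len(nc)) {
    K <- matrix(0i, d[1], d[2])
    K[band, ] <- reference@data[band, , c] * w
    low[, , c] <- .uifft2(K)
  }
  rss <- sqrt(apply(abs(low)^2, c(1, 2), sum))
  support <- rss > supportThreshold * max(rss)
  sens <- array(0i, dim = d)
  for (c in seq_len(nc)) {
    s <- matrix(0i, d[1], d[2])
    s[support] <- low[, , c][support] / rss[support]
    sens[, , c] <- s
  }
  methods::new("CoilSet", sensitivities = sens, supportMask = support)
}
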