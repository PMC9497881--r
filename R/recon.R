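# Reconstruction suite: l1-Haar-wavelet regularized proximal-gradient
# solver (ISTA / FISTA with function-value restart), homodyne
# partial-Fourier synthesis, and the coil-combined zero-filled adjoint.

#' Construct a reconstruction configuration
#'
#' @param lam regularization weight; `NA` (default) selects the
#'   data-scaled value `1e-3 * max |A^H D|`, which transfers across noise
#'   levels and image scales.
#' @param nIter iteration cap.
#' @param tol relative-change stopping tolerance on the iterate (0 runs
#'   all `nIter` iterations).
#' @param step gradient step; `NA` (default) uses `1 / L` with `L`
#'   estimated by power iteration on `A^H A`.
#' @param solver `"fista_restart"` (default) or `"ista"`.
#' @return a [ReconConfig-class].
#' @export
reconConfig <- function(lam = NA_real_, nIter = 100L, tol = 1e-5,
                        step = NA_real_, solver = c("fista_restart", "ista")) {
  methods::new("ReconConfig", lam = as.numeric(lam), nIter = as.integer(nIter),
               tol = as.numeric(tol), step = as.numeric(step),
               solver = match.arg(solver))
}

# Composite objective 0.5 ||A x - D||^2 + lam ||W x||_1.
.csObjective <- function(op, wav, x, D, lam, shape) {
  r <- applyForward(op, x) - D
  0.5 * sum(abs(r)^2) + lam * sum(abs(waveletForward(wav, x)))
}

# One proximal-gradient step from point y.
.proxStep <- function(op, wav, y, D, step, lam, shape) {
  g <- applyAdjoint(op, applyForward(op, y) - D)
  z <- y - step * g
  co <- softThreshold(waveletForward(wav, z), step * lam)
  waveletInverse(wav, co, shape = shape)
}

#' Compressed-sensing reconstruction
#'
#' Minimizes the convex objective
#' `0.5 * ||A I - D||_2^2 + lambda * ||W I||_1`
#' by proximal-gradient iteration, where `A` is the system operator
#' (coil maps, unitary FFT, masking), `D` the acquired k-space and `W` the
#' orthonormal multilevel Haar transform. Because `W` is orthonormal, the
#' proximal map of the penalty is exact: soft-threshold in the wavelet
#' domain and transform back; no inner iterations are needed.
#'
#' `solver = "fista_restart"` uses Nesterov momentum with a function-value
#' restart: an accepted iterate never increases the objective, so the
#' recorded trace is non-increasing. Plain `"ista"` is monotone for
#' `step <= 1/L`. The best (lowest-objective) iterate is returned.
#'
#' @param kspace a [KSpaceData-class] (imaging scan).
#' @param maps a [CoilSet-class], typically from [estimateMaps()].
#' @param cfg a [ReconConfig-class].
#' @param wavelet a [WaveletOperator-class]; image sides not divisible by
#'   `2^levels` are zero-padded internally.
#' @return a [ReconResult-class] with the complex image estimate, the
#'   per-iteration objective trace and solver metadata.
#' @export
csReconstruct <- function(kspace, maps, cfg = reconConfig(),
                          wavelet = waveletOperator()) {
  stopifnot(is(kspace, "KSpaceData"), is(maps, "CoilSet"),
            is(cfg, "ReconConfig"), is(wavelet, "WaveletOperator"))
  D <- kspace@data
  if (!all(is.finite(Re(D))) || !all(is.finite(Im(D))))
    stop("non-finite k-space data")
  op <- systemOperator(maps, kspace@mask)
  shape <- op@imageShape

  x <- applyAdjoint(op, D)
  lam <- if (is.na(cfg@lam)) {
    # data-scaled floor plus a noise-proportional term: the image-domain
    # noise std under the adjoint is sigma * sqrt(m / nPE) (unitary FFT,
    # RSS-normalized maps), and the per-iteration soft threshold should
    # sit a small factor above it
    sigmaImg <- kspace@noiseSigma *
      sqrt(length(kspace@mask@lines) / kspace@mask@nPE)
    max(1e-3 * max(abs(x)), 2 * sigmaImg)
  } else cfg@lam
  step <- if (is.na(cfg@step)) {
    L <- operatorNorm2(op)
    1 / max(L, .Machine$double.eps)
  } else cfg@step

  fx <- .csObjective(op, wavelet, x, D, lam, shape)
  trace <- numeric(cfg@nIter)
  best <- x; fbest <- fx
  converged <- FALSE
  nRun <- 0L

  if (cfg@solver == "ista") {
    for (k in seq_len(cfg@nIter)) {
      xn <- .proxStep(op, wavelet, x, D, step, lam, shape)
      fn <- .csObjective(op, wavelet, xn, D, lam, shape)
      rel <- sqrt(sum(abs(xn - x)^2)) / max(sqrt(sum(abs(x)^2)),
                                            .Machine$double.eps)
      x <- xn; fx <- fn
      nRun <- k; trace[k] <- fn
      if (fn < fbest) { fbest <- fn; best <- xn }
      if (rel < cfg@tol) { converged <- TRUE; break }
    }
  } else {
    y <- x; t <- 1
    for (k in seq_len(cfg@nIter)) {
      xn <- .proxStep(op, wavelet, y, D, step, lam, shape)
      fn <- .csObjective(op, wavelet, xn, D, lam, shape)
      if (fn > fx) {
        # momentum overshoot: restart from the current iterate
        t <- 1
        xn <- .proxStep(op, wavelet, x, D, step, lam, shape)
        fn <- .csObjective(op, wavelet, xn, D, lam, shape)
      }
      tn <- (1 + sqrt(1 + 4 * t^2)) / 2
      y <- xn + ((t - 1) / tn) * (xn - x)
      rel <- sqrt(sum(abs(xn - x)^2)) / max(sqrt(sum(abs(x)^2)),
                                            .Machine$double.eps)
      t <- tn; x <- xn
      fx <- min(fx, fn)
      nRun <- k; trace[k] <- fx
      if (fn < fbest) { fbest <- fn; best <- xn }
      if (rel < cfg@tol) { converged <- TRUE; break }
    }
  }

  methods::new("ReconResult", image = best, objectiveTrace = trace[seq_len(nRun)],
               nIterRun = nRun, converged = converged, lam = lam, step = step)
}

#' Zero-filled adjoint reconstruction
#'
#' The coil-combined adjoint of the system operator applied to the (zero
#' filled) acquired data: `sum_c conj(map_c) * unitaryIFFT(data_c)`. This
#' is the baseline every undersampling geometry is compared against; with
#' full sampling, normalized maps, no decay and no noise it inverts the
#' acquisition exactly. Without maps, coil images are combined by
#' root-sum-of-squares (magnitude only).
#'
#' @param kspace a [KSpaceData-class].
#' @param maps optional [CoilSet-class]; if missing, RSS combination.
#' @return complex matrix (with maps) or non-negative real matrix (RSS).
#' @export
zeroFilledRecon <- function(kspace, maps = NULL) {
  stopifnot(is(kspace, "KSpaceData"))
  if (!is.null(maps)) {
    op <- systemOperator(maps, kspace@mask)
    return(applyAdjoint(op, kspace@data))
  }
  d <- dim(kspace@data)
  acc <- matrix(0, d[1], d[2])
  for (c in seq_len(d[3])) acc <- acc + abs(.uifft2(kspace@data[, , c]))^2
  sqrt(acc)
}

#' Homodyne partial-Fourier reconstruction
#'
#' Synthesizes the unacquired conjugate-symmetric half of k-space:
#' the asymmetric data are pre-weighted so that the two conjugate copies
#' sum to weight 2 everywhere (linear ramp from 0 to 2 across the
#' symmetric band, weight 2 where only one copy was acquired), the
#' coil-combined image is phase-corrected with the low-resolution phase
#' estimated from the symmetric center band, and the real part is taken
#' (negatives clipped to 0). Exact for zero-phase objects with full data;
#' accurate when the object phase varies slowly, the regime the smooth
#' phantom phase map emulates.
#'
#' @param kspace a [KSpaceData-class] acquired under a mask of kind
#'   `"partial_fourier"` (or `"full"`).
#' @param maps optional [CoilSet-class] for coil combination; single-coil
#'   data may omit it.
#' @return real non-negative matrix.
#' @export
homodyneRecon <- function(kspace, maps = NULL) {
  stopifnot(is(kspace, "KSpaceData"))
  mask <- kspace@mask
  if (!mask@kind %in% c("partial_fourier", "full"))
    stop("homodyneRecon requires a partial-Fourier (or full) mask")
  nPE <- mask@nPE
  lines <- sort(mask@lines)
  if (length(lines) <= nPE / 2)
    stop("homodyne requires more than half of k-space")
  ctr <- .centerLine(nPE)
  d <- dim(kspace@data)
  nc <- d[3]
  if (is.null(maps)) {
    if (nc != 1L) stop("multi-coil homodyne needs coil maps")
    sens <- array(1 + 0i, dim = d)
  } else sens <- maps@sensitivities

  lo <- min(lines)                      # first acquired line
  hiSym <- min(2L * ctr - lo, max(lines))  # mirror of `lo`: end of symmetric band
  # Homodyne weights along phase encode: 0 unacquired; linear ramp 0..2
  # across the symmetric band [lo, 2*ctr - lo] (value 1 at DC); 2 where only
  # one conjugate copy was acquired. The ramp is antisymmetric about DC, so
  # conjugate pairs always sum to weight 2 and real-part projection is exact
  # for zero-phase objects.
  idx <- seq_len(nPE)
  s <- max(ctr - lo, 1L)
  wpe <- 1 + pmin(1, pmax(-1, (idx - ctr) / s))
  wpe[!(idx %in% lines)] <- 0
  if (nPE %% 2L == 0L && 1L %in% lines)
    wpe[1L] <- 1  # Nyquist line is its own conjugate mirror on even grids

  # Low-resolution phase from the symmetric center band, apodized with a
  # cosine taper symmetric about the DC line: a conjugate-symmetric window
  # keeps the phase estimate exactly zero for zero-phase objects.
  hm <- min(ctr - lo, hiSym - ctr)
  band <- (ctr - hm):(ctr + hm)
  hw <- numeric(nPE)
  hw[band] <- cos(pi * (band - ctr) / (2 * (hm + 1)))^2

  # Coil-combine first (conjugate-map weighted zero-filled adjoint), then
  # run homodyne on the single combined k-space: demodulating the coil
  # phase before the asymmetric weighting keeps the real-part projection
  # exact for zero-phase objects regardless of coil count.
  y <- matrix(0i, d[1], d[2])
  for (c in seq_len(nc))
    y <- y + Conj(sens[, , c]) * .uifft2(kspace@data[, , c])
  K <- .ufft2(y)
  imgW <- .uifft2(K * wpe)
  imgLow <- .uifft2(K * hw)
  # phase-correct only where the low-resolution signal is meaningful; an
  # arbitrary phase at numerically-zero pixels would leak the imaginary
  # (anti-symmetric ramp) component into the output
  mag <- abs(imgLow)
  ph <- matrix(1 + 0i, d[1], d[2])
  ok <- mag > 1e-6 * max(mag)
  ph[ok] <- imgLow[ok] / mag[ok]
  out <- Re(imgW * Conj(ph))
  out[out < 0] <- 0
  out
}
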