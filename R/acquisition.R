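# Acquisition simulation: protocol arithmetic, sampling masks, echo-train
# ordering with T2 decay, reference (calibration) scans and noise.

#' Construct acquisition protocol parameters
#'
#' @param matrixRead readout matrix size.
#' @param matrixPE phase-encode matrix size (>= 32).
#' @param acceleration total phase-encode acceleration factor R (>= 1).
#' @param partialFourier acquired fraction of phase-encode lines, in
#'   (0.5, 1]; 6/8 = 0.75 is the usual single-shot choice.
#' @param nACS number of autocalibration lines (even).
#' @param trMs,teMs repetition/echo time, ms.
#' @param echoSpacingMs echo spacing within the train, ms.
#' @param nSlices,sliceIncrement slice count and acquisition stride.
#' @param flipDeg constant refocusing flip angle, degrees.
#' @param bandwidthHz receiver bandwidth (recorded, unused by the model).
#' @param sequenceKind `"ssfse_conv"`, `"mtse"` or `"ssfse_cs"`.
#' @return a [ProtocolParams-class].
#' @export
protocolParams <- function(matrixRead = 384L, matrixPE = 253L,
                           acceleration = 3, partialFourier = 1,
                           nACS = 24L, trMs = 500, teMs = 99,
                           echoSpacingMs = 3, nSlices = 32L,
                           sliceIncrement = 4L, flipDeg = 118,
                           bandwidthHz = 372, sequenceKind = "ssfse_cs") {
  methods::new("ProtocolParams",
    matrixRead = as.integer(matrixRead), matrixPE = as.integer(matrixPE),
    acceleration = as.numeric(acceleration),
    partialFourier = as.numeric(partialFourier), nACS = as.integer(nACS),
    trMs = as.numeric(trMs), teMs = as.numeric(teMs),
    echoSpacingMs = as.numeric(echoSpacingMs), nSlices = as.integer(nSlices),
    sliceIncrement = as.integer(sliceIncrement), flipDeg = as.numeric(flipDeg),
    bandwidthHz = as.numeric(bandwidthHz),
    sequenceKind = match.arg(sequenceKind, .SEQUENCE_KINDS))
}

#' Named protocol presets
#'
#' Protocol cards for the six sequence/scanner combinations of the study
#' design this package emulates: conventional single-shot FSE, multishot
#' TSE and CS-accelerated single-shot FSE on two 3T systems. The multishot
#' presets exist for the ratings workflow only; their segmented acquisition
#' is not simulated.
#'
#' @param name one of `"skyra_ssfse_conv"`, `"skyra_mtse"`,
#'   `"skyra_ssfse_cs"`, `"vida_ssfse_conv"`, `"vida_mtse"`,
#'   `"vida_ssfse_cs"`.
#' @return a [ProtocolParams-class].
#' @examples
#' echoTrainLength(protocolPreset("skyra_ssfse_cs"))  # 84
#' @export
protocolPreset <- function(name = c("skyra_ssfse_conv", "skyra_mtse",
                                    "skyra_ssfse_cs", "vida_ssfse_conv",
                                    "vida_mtse", "vida_ssfse_cs")) {
  name <- match.arg(name)
  switch(name,
    skyra_ssfse_conv = protocolParams(256L, 256L, acceleration = 2,
      partialFourier = 0.75, nACS = 24L, trMs = 732, teMs = 100,
      nSlices = 42L, sliceIncrement = 2L, flipDeg = 106, bandwidthHz = 977,
      sequenceKind = "ssfse_conv"),
    skyra_mtse = protocolParams(384L, 307L, acceleration = 2,
      partialFourier = 1, nACS = 24L, trMs = 2040, teMs = 101,
      nSlices = 42L, sliceIncrement = 2L, flipDeg = 134, bandwidthHz = 1085,
      sequenceKind = "mtse"),
    skyra_ssfse_cs = protocolParams(384L, 253L, acceleration = 3,
      partialFourier = 1, nACS = 24L, trMs = 500, teMs = 99,
      nSlices = 32L, sliceIncrement = 4L, flipDeg = 118, bandwidthHz = 372,
      sequenceKind = "ssfse_cs"),
    vida_ssfse_conv = protocolParams(384L, 250L, acceleration = 2,
      partialFourier = 0.75, nACS = 24L, trMs = 1000, teMs = 99,
      nSlices = 42L, sliceIncrement = 2L, flipDeg = 154, bandwidthHz = 372,
      sequenceKind = "ssfse_conv"),
    vida_mtse = protocolParams(384L, 307L, acceleration = 2,
      partialFourier = 1, nACS = 24L, trMs = 1700, teMs = 99,
      nSlices = 42L, sliceIncrement = 2L, flipDeg = 140, bandwidthHz = 303,
      sequenceKind = "mtse"),
    vida_ssfse_cs = protocolParams(384L, 253L, acceleration = 3,
      partialFourier = 1, nACS = 24L, trMs = 561, teMs = 96,
      nSlices = 32L, sliceIncrement = 4L, flipDeg = 135, bandwidthHz = 685,
      sequenceKind = "ssfse_cs"))
}

#' Echo-train length of a single-shot protocol
#'
#' The per-shot imaging-line budget: `floor(matrixPE / acceleration)`. Only
#' defined for single-shot sequence kinds; a multishot TSE distributes
#' lines over several excitations and needs a shots-based calculator, which
#' is out of scope here.
#'
#' @param params a [ProtocolParams-class] with a single-shot `sequenceKind`.
#' @return integer echo-train length.
#' @examples
#' echoTrainLength(protocolParams(matrixPE = 253L, acceleration = 3))  # 84
#' @export
echoTrainLength <- function(params) {
  stopifnot(is(params, "ProtocolParams"))
  if (params@sequenceKind == "mtse")
    stop("echoTrainLength is defined for single-shot kinds only; ",
         "multishot TSE needs a shots-based calculator (not implemented)")
  as.integer(floor(params@matrixPE / params@acceleration))
}

.newMask <- function(nPE, lines, kind, acsLines = integer(), seed = NA_integer_) {
  methods::new("SamplingMask", nPE = as.integer(nPE),
               lines = as.integer(lines), kind = kind,
               acsLines = as.integer(acsLines),
               seed = as.integer(seed))
}

#' Full (unaccelerated) sampling mask
#'
#' @param nPE number of phase-encode lines.
#' @return a [SamplingMask-class] sampling every line in ascending order.
#' @export
buildFullMask <- function(nPE) {
  nPE <- .assertScalarCount(nPE, "nPE")
  .newMask(nPE, seq_len(nPE), "full")
}

#' Variable-density random sampling mask
#'
#' Samples exactly `budget` of `nPE` lines: a fully sampled contiguous
#' center block of `round(centerFraction * budget)` lines about the DC
#' line, plus lines drawn without replacement from the remainder with a
#' sampling density that decreases linearly from the k-space center to the
#' periphery. `accelIncrement` controls how steeply the local acceleration
#' grows toward the edge (0 = flat residual density).
#'
#' When `budget == nPE` the full mask is returned.
#'
#' @param nPE number of phase-encode lines.
#' @param budget number of lines to sample (typically the echo-train
#'   length, e.g. 84 of 253 for total acceleration 3.0).
#' @param centerFraction fraction of the budget spent on the fully sampled
#'   center block; the default 24/84 makes the imaging scan cover the usual
#'   24-line calibration region.
#' @param accelIncrement non-negative slope of the center-to-edge density
#'   fall-off.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return a [SamplingMask-class] of kind `"variable_density"`; the center
#'   block is recorded in `acsLines`.
#' @examples
#' m <- buildVDMask(253L, 84L, seed = 1)
#' length(sampledLines(m))          # 84
#' round(253 / 84, 1)               # effective acceleration 3.0
#' @export
buildVDMask <- function(nPE, budget, centerFraction = 24 / 84,
                        accelIncrement = 1, seed = NULL) {
  nPE <- .assertScalarCount(nPE, "nPE")
  budget <- .assertScalarCount(budget, "budget")
  if (budget > nPE) stop("budget must not exceed nPE")
  if (accelIncrement < 0) stop("accelIncrement must be >= 0")
  nCenter <- as.integer(round(centerFraction * budget))
  if (nCenter < 1L) stop("centerFraction * budget must be >= 1")
  if (nCenter > budget) stop("center block exceeds the sampling budget")
  if (budget == nPE)
    return(.newMask(nPE, seq_len(nPE), "full", acsLines = seq_len(nPE)))

  ctr <- .centerLine(nPE)
  lo <- ctr - ((nCenter - 1L) %/% 2L)
  block <- lo:(lo + nCenter - 1L)
  if (min(block) < 1L || max(block) > nPE)
    stop("center block does not fit inside the phase-encode axis")

  rest <- setdiff(seq_len(nPE), block)
  nDraw <- budget - nCenter
  if (nDraw > length(rest)) stop("budget exceeds available lines")
  drawn <- integer()
  if (nDraw > 0L) {
    d <- abs(rest - ctr) / max(abs(seq_len(nPE) - ctr))
    w <- 1 / (1 + accelIncrement * d)   # local acceleration 1 + a*d
    drawn <- .withSeed(seed, sort(sample(rest, nDraw, prob = w)))
  }
  lines <- sort(c(block, drawn))
  .newMask(nPE, lines, "variable_density", acsLines = block,
           seed = if (is.null(seed)) NA_integer_ else seed)
}

#' Uniform (parallel-imaging geometry) sampling mask
#'
#' Every `r`-th line starting at 0-based offset `offset`, the undersampling
#' geometry of GRAPPA-style parallel imaging. Only the geometry is modeled;
#' kernel-based interpolation is not, and the matched baseline
#' reconstruction is the coil-combined zero-filled adjoint.
#'
#' @param nPE number of phase-encode lines.
#' @param r integer undersampling factor (>= 1).
#' @param offset 0-based starting offset, `0 <= offset < r`.
#' @return a [SamplingMask-class] of kind `"uniform"` (`"full"` when the
#'   factor is 1), with `ceiling((nPE - offset) / r)` lines.
#' @examples
#' length(sampledLines(buildUniformMask(250L, 2L)))  # 125
#' @export
buildUniformMask <- function(nPE, r, offset = 0L) {
  nPE <- .assertScalarCount(nPE, "nPE")
  r <- .assertScalarCount(r, "r")
  if (offset < 0L || offset >= r) stop("offset must satisfy 0 <= offset < r")
  lines <- seq.int(offset + 1L, nPE, by = r)
  .newMask(nPE, lines, if (r == 1L) "full" else "uniform")
}

#' Partial-Fourier sampling mask
#'
#' Retains `ceiling(fraction * nPE)` contiguous lines: all of the upper
#' half of k-space plus the symmetric margin below the center line; the
#' center (DC) line is always retained. Homodyne synthesis needs strictly
#' more than half coverage, so `fraction <= 0.5` is an error.
#'
#' @param nPE number of phase-encode lines.
#' @param fraction acquired fraction, in (0.5, 1]; 6/8 = 0.75 is typical.
#' @return a [SamplingMask-class] of kind `"partial_fourier"` (`"full"`
#'   when `fraction = 1`).
#' @examples
#' length(sampledLines(buildPFMask(256L, 6 / 8)))  # 192
#' @export
buildPFMask <- function(nPE, fraction) {
  nPE <- .assertScalarCount(nPE, "nPE")
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0.5 || fraction > 1)
    stop("fraction must lie in (0.5, 1]; homodyne requires > half coverage")
  m <- as.integer(ceiling(fraction * nPE))
  if (m >= nPE) return(.newMask(nPE, seq_len(nPE), "full"))
  lines <- (nPE - m + 1L):nPE
  .newMask(nPE, lines, "partial_fourier")
}

# Contiguous nACS-line calibration block about the center line.
.acsBlock <- function(nPE, nACS) {
  ctr <- .centerLine(nPE)
  lo <- ctr - (nACS %/% 2L)
  lines <- lo:(lo + nACS - 1L)
  if (min(lines) < 1L || max(lines) > nPE)
    stop("ACS block does not fit inside the phase-encode axis")
  lines
}

#' Slice acquisition order under a slice increment
#'
#' Visits slices in strides of `increment` over successive passes
#' (1, 1+inc, 1+2*inc, ..., then 2, 2+inc, ...), the ordering used to
#' reduce crosstalk and magnetization-transfer effects at short TR; a
#' larger increment (four for the CS-accelerated protocol versus two
#' conventionally) separates temporally adjacent slices further.
#'
#' @param nSlices number of slices.
#' @param increment slice stride, `1 <= increment <= nSlices`.
#' @return integer permutation of `1:nSlices` (1-based).
#' @examples
#' sliceOrder(8L, 4L)  # 1 5 2 6 3 7 4 8
#' @export
sliceOrder <- function(nSlices, increment) {
  nSlices <- .assertScalarCount(nSlices, "nSlices")
  increment <- .assertScalarCount(increment, "increment")
  if (increment > nSlices) stop("increment must not exceed nSlices")
  as.integer(unlist(lapply(seq_len(increment), function(s)
    seq.int(s, nSlices, by = increment))))
}

# Effective echo time per sampled line: echo index under the chosen
# ordering, with the center-most sampled line pinned to the nominal TE.
.echoTimes <- function(lines, nPE, teMs, espMs, ordering) {
  m <- length(lines)
  acqOrder <- switch(ordering,
    linear = sort(lines),
    center_out = lines[order(abs(lines - .centerLine(nPE)),
                             lines)],
    stop("ordering must be 'linear' or 'center_out'"))
  echoIdx <- seq_len(m) - 1L
  ctrPos <- which.min(abs(acqOrder - .centerLine(nPE)))
  eff <- teMs + (echoIdx - echoIdx[ctrPos]) * espMs
  list(order = acqOrder, effTE = eff)
}

#' Simulate an SSFSE echo-train acquisition
#'
#' For each sampled phase-encode line `j` acquired at echo index `e(j)`
#' under the chosen ordering, the acquired line is the corresponding row of
#' the centered unitary 2D FFT of
#' `coil_c * protonDensity * exp(-effTE(j) / T2) * exp(i * phase)`,
#' where the effective echo time `effTE(j) = TE + (e(j) - e_center) * esp`
#' pins the center-most sampled line to the protocol's nominal TE. The
#' line-by-line T2 decay along the train is the mechanism behind
#' phase-encode blurring in long echo trains; i.i.d. complex Gaussian noise
#' of standard deviation `noiseSigma` (per real/imaginary component,
#' identical across coils) is added to every sampled entry.
#'
#' @param phantom a [Phantom-class]; its row count must equal
#'   `params@matrixPE`.
#' @param coils a [CoilSet-class] on the same grid.
#' @param mask a [SamplingMask-class] with `nPE` equal to the phantom rows.
#' @param params a [ProtocolParams-class]; supplies TE and echo spacing.
#' @param ordering `"linear"` (bottom-to-top) or `"center_out"`.
#' @param noiseSigma complex-noise standard deviation (a.u.).
#' @param seed integer seed for the noise draw.
#' @param decay set `FALSE` to freeze the object at the nominal TE
#'   (no decay along the train); useful for exact-inversion checks.
#' @return a [KSpaceData-class].
#' @export
acquire <- function(phantom, coils, mask, params,
                    ordering = c("linear", "center_out"),
                    noiseSigma = 0, seed = NULL, decay = TRUE) {
  ordering <- match.arg(ordering)
  stopifnot(is(phantom, "Phantom"), is(coils, "CoilSet"),
            is(mask, "SamplingMask"), is(params, "ProtocolParams"))
  rows <- nrow(phantom@protonDensity)
  cols <- ncol(phantom@protonDensity)
  if (!identical(dim(coils@sensitivities)[1:2], c(rows, cols)))
    stop("coil maps and phantom shapes differ")
  if (mask@nPE != rows)
    stop("mask nPE must equal the phantom row (phase-encode) count")
  if (mask@nPE != params@matrixPE)
    stop("mask nPE and params matrixPE disagree")
  if (noiseSigma < 0) stop("noiseSigma must be >= 0")

  et <- .echoTimes(mask@lines, mask@nPE, params@teMs, params@echoSpacingMs,
                   ordering)
  nc <- dim(coils@sensitivities)[3]
  base <- phantom@protonDensity * exp(1i * phantom@phaseMap)
  data <- array(0i, dim = c(rows, cols, nc))

  if (!decay) {
    # static object: one FFT per coil, copy the sampled rows
    img <- base * exp(-params@teMs / phantom@t2Map)
    for (c in seq_len(nc)) {
      K <- .ufft2(coils@sensitivities[, , c] * img)
      data[et$order, , c] <- K[et$order, ]
    }
  } else {
    for (pos in seq_along(et$order)) {
      j <- et$order[pos]
      img <- base * exp(-et$effTE[pos] / phantom@t2Map)
      for (c in seq_len(nc)) {
        K <- .ufft2(coils@sensitivities[, , c] * img)
        data[j, , c] <- K[j, ]
      }
    }
  }

  if (noiseSigma > 0) {
    data <- .withSeed(seed, {
      nEl <- length(et$order) * cols * nc
      noise <- matrix(complex(real = stats::rnorm(nEl, sd = noiseSigma),
                              imaginary = stats::rnorm(nEl, sd = noiseSigma)),
                      nrow = length(et$order))
      d <- data
      for (c in seq_len(nc))
        d[et$order, , c] <- d[et$order, , c] +
          noise[, ((c - 1) * cols + 1):(c * cols)]
      d
    })
  }

  mask@lines <- as.integer(et$order)   # record acquisition order
  methods::new("KSpaceData", data = data, mask = mask,
               echoTimesMs = et$effTE, noiseSigma = as.numeric(noiseSigma),
               isReference = FALSE)
}

#' Simulate the separate calibration (reference) scan
#'
#' A second echo train acquiring a fully sampled contiguous block of
#' `params@nACS` center lines, used to estimate coil sensitivity maps. Same
#' forward model as [acquire()].
#'
#' @inheritParams acquire
#' @return a [KSpaceData-class] with `isReference = TRUE` and a mask of
#'   kind `"acs"`.
#' @export
acquireReference <- function(phantom, coils, params,
                             ordering = c("linear", "center_out"),
                             noiseSigma = 0, seed = NULL, decay = TRUE) {
  stopifnot(is(params, "ProtocolParams"))
  if (params@nACS < 1L)
    stop("reference scan requires nACS >= 1 calibration lines")
  if (params@nACS > params@matrixPE) stop("nACS must not exceed matrixPE")
  nPE <- params@matrixPE
  lines <- .acsBlock(nPE, params@nACS)
  kind <- if (params@nACS == nPE) "full" else "acs"
  mask <- .newMask(nPE, lines, kind, acsLines = lines)
  ks <- acquire(phantom, coils, mask, params, ordering = ordering,
                noiseSigma = noiseSigma, seed = seed, decay = decay)
  ks@isReference <- TRUE
  methods::validObject(ks)
  ks
}
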