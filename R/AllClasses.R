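#' @import methods
NULL

# ---------------------------------------------------------------------------
# Phantom
# ---------------------------------------------------------------------------

#' Ground-truth digital phantom for a T2-weighted abdominal slice
#'
#' Holds the piecewise-smooth tissue maps the forward acquisition model
#' images: proton density (arbitrary units), T2 relaxation times (ms), a
#' slowly varying phase map (radians) and an integer tissue-label map, plus
#' the bookkeeping for inserted focal lesions.
#'
#' Label conventions: 0 = background (air), 1 = body/soft tissue,
#' 2 = parenchyma (liver-like), 3 = secondary organ, 4 = native fluid
#' structure, 5 = fluid (cyst-like) lesion, 6 = solid lesion.
#'
#' @slot protonDensity non-negative matrix, arbitrary units.
#' @slot t2Map matrix of T2 times in ms; positive wherever `labels != 0`.
#' @slot phaseMap matrix of radians, smooth by construction.
#' @slot labels integer matrix of tissue labels.
#' @slot pixelSize isotropic pixel size in mm.
#' @slot lesions data.frame with one row per lesion: `row`, `col`,
#'   `radius` (px) and `class` (`"fluid"` or `"solid"`).
#'
#' @seealso [makePhantom()], [groundTruthImage()]
#' @export
setClass("Phantom",
  representation(
    protonDensity = "matrix",
    t2Map = "matrix",
    phaseMap = "matrix",
    labels = "matrix",
    pixelSize = "numeric",
    lesions = "data.frame"
  )
)

setValidity("Phantom", function(object) {
  msgs <- character()
  dm <- dim(object@protonDensity)
  if (!identical(dm, dim(object@t2Map)) ||
      !identical(dm, dim(object@phaseMap)) ||
      !identical(dm, dim(object@labels)))
    msgs <- c(msgs, "all maps must share one shape")
  if (any(object@protonDensity < 0))
    msgs <- c(msgs, "protonDensity must be non-negative everywhere")
  support <- object@labels != 0L
  if (any(object@t2Map[support] <= 0))
    msgs <- c(msgs, "t2Map must be positive on the object support")
  if (!all(is.finite(object@phaseMap)))
    msgs <- c(msgs, "phaseMap must be finite")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msgs <- c(msgs, "pixelSize must be a single positive number")
  if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# CoilSet
# ---------------------------------------------------------------------------

#' Complex receive-coil sensitivity maps
#'
#' Smooth complex per-coil weightings, root-sum-of-squares (RSS) normalized
#' to 1 wherever `supportMask` is `TRUE`. These maps are the
#' coil-multiplication factor of the system operator used by the
#' reconstruction.
#'
#' @slot sensitivities complex array of dim `(rows, cols, nCoils)`.
#' @slot supportMask logical matrix; where RSS normalization is enforced.
#'
#' @seealso [simulateCoils()], [estimateMaps()]
#' @export
setClass("CoilSet",
  representation(
    sensitivities = "array",
    supportMask = "matrix"
  )
)

setValidity("CoilSet", function(object) {
  msgs <- character()
  d <- dim(object@sensitivities)
  if (length(d) != 3L)
    msgs <- c(msgs, "sensitivities must be a 3D array (rows, cols, coils)")
  else {
    if (!identical(dim(object@supportMask), d[1:2]))
      msgs <- c(msgs, "supportMask shape must match the coil maps")
    if (d[3] < 1L) msgs <- c(msgs, "need at least one coil")
    rss <- sqrt(apply(abs(object@sensitivities)^2, c(1, 2), sum))
    if (any(abs(rss[object@supportMask] - 1) > 1e-6))
      msgs <- c(msgs, "RSS must equal 1 (within 1e-6) on the support")
  }
  if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# SamplingMask
# ---------------------------------------------------------------------------

.MASK_KINDS <- c("variable_density", "uniform", "partial_fourier", "full", "acs")

#' Phase-encode sampling pattern
#'
#' Records which of the `nPE` phase-encode lines are sampled and in what
#' temporal (echo-train) order, the mask family, and any autocalibration
#' (ACS) lines. Line indices are 1-based; the DC line of an `n`-line axis is
#' `floor(n/2) + 1`.
#'
#' @slot nPE total number of phase-encode lines of the grid.
#' @slot lines integer vector of sampled line indices in acquisition order.
#' @slot kind one of `"variable_density"`, `"uniform"`, `"partial_fourier"`,
#'   `"full"`, `"acs"`.
#' @slot acsLines integer vector of calibration line indices (possibly empty).
#' @slot seed integer seed used to draw the mask, or `NA` for deterministic
#'   kinds.
#'
#' @seealso [buildVDMask()], [buildUniformMask()], [buildPFMask()],
#'   [buildFullMask()]
#' @export
setClass("SamplingMask",
  representation(
    nPE = "integer",
    lines = "integer",
    kind = "character",
    acsLines = "integer",
    seed = "integer"
  )
)

setValidity("SamplingMask", function(object) {
  msgs <- character()
  n <- object@nPE
  ln <- object@lines
  if (length(n) != 1L || n < 1L) msgs <- c(msgs, "nPE must be a positive count")
  if (anyDuplicated(ln)) msgs <- c(msgs, "sampled line indices must be unique")
  if (length(ln) && (min(ln) < 1L || max(ln) > n))
    msgs <- c(msgs, "sampled line indices must lie in [1, nPE]")
  if (!object@kind %in% .MASK_KINDS)
    msgs <- c(msgs, paste("kind must be one of:", paste(.MASK_KINDS, collapse = ", ")))
  if (length(object@acsLines) && !all(object@acsLines %in% ln))
    msgs <- c(msgs, "acsLines must be a subset of the sampled lines")
  if (identical(object@kind, "uniform") && length(ln) > 1L) {
    d <- diff(sort(ln))
    if (length(unique(d)) != 1L)
      msgs <- c(msgs, "uniform mask indices must form an arithmetic progression")
  }
  if (object@kind %in% c("partial_fourier", "acs") && length(ln)) {
    srt <- sort(ln)
    if (!all(diff(srt) == 1L))
      msgs <- c(msgs, "partial-Fourier/ACS retained set must be contiguous")
    if (!(.centerLine(n) %in% srt))
      msgs <- c(msgs, "partial-Fourier/ACS block must contain the center line")
  }
  if (identical(object@kind, "full") && length(ln) != n)
    msgs <- c(msgs, "full mask must sample every line")
  if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# ProtocolParams
# ---------------------------------------------------------------------------

.SEQUENCE_KINDS <- c("ssfse_conv", "mtse", "ssfse_cs")

#' Acquisition protocol parameters
#'
#' Mirrors the fields of a clinical T2-weighted protocol card: matrix size,
#' acceleration, partial-Fourier factor, calibration lines, timings and
#' slice bookkeeping. Bandwidth is stored for the record but unused by the
#' forward model.
#'
#' @slot matrixRead readout matrix size.
#' @slot matrixPE number of phase-encode lines (>= 32).
#' @slot acceleration total phase-encode acceleration factor R (>= 1).
#' @slot partialFourier fraction of phase-encode lines acquired, in (0.5, 1].
#' @slot nACS number of autocalibration lines (even, >= 0).
#' @slot trMs,teMs repetition and echo time, ms.
#' @slot echoSpacingMs spacing between successive echoes in the train, ms.
#' @slot nSlices number of slices.
#' @slot sliceIncrement slice-index stride between temporally adjacent slices.
#' @slot flipDeg constant refocusing flip angle, degrees.
#' @slot bandwidthHz receiver bandwidth, Hz/pixel (stored, unused).
#' @slot sequenceKind `"ssfse_conv"`, `"mtse"` or `"ssfse_cs"`.
#'
#' @seealso [protocolParams()], [protocolPreset()], [echoTrainLength()]
#' @export
setClass("ProtocolParams",
  representation(
    matrixRead = "integer",
    matrixPE = "integer",
    acceleration = "numeric",
    partialFourier = "numeric",
    nACS = "integer",
    trMs = "numeric",
    teMs = "numeric",
    echoSpacingMs = "numeric",
    nSlices = "integer",
    sliceIncrement = "integer",
    flipDeg = "numeric",
    bandwidthHz = "numeric",
    sequenceKind = "character"
  )
)

setValidity("ProtocolParams", function(object) {
  msgs <- character()
  if (object@matrixPE < 32L) msgs <- c(msgs, "matrixPE must be >= 32")
  if (object@acceleration < 1) msgs <- c(msgs, "acceleration must be >= 1")
  if (object@partialFourier <= 0.5 || object@partialFourier > 1)
    msgs <- c(msgs, "partialFourier must lie in (0.5, 1]")
  if (object@nACS < 0L || object@nACS %% 2L != 0L)
    msgs <- c(msgs, "nACS must be even and >= 0")
  if (object@sliceIncrement < 1L) msgs <- c(msgs, "sliceIncrement must be >= 1")
  if (!object@sequenceKind %in% .SEQUENCE_KINDS)
    msgs <- c(msgs, paste("sequenceKind must be one of:",
                          paste(.SEQUENCE_KINDS, collapse = ", ")))
  if (object@teMs <= 0 || object@trMs <= 0 || object@echoSpacingMs <= 0)
    msgs <- c(msgs, "trMs, teMs, echoSpacingMs must be positive")
  if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# KSpaceData
# ---------------------------------------------------------------------------

#' Multi-coil Cartesian k-space data
#'
#' Complex k-space samples on a `(nPE, readout, nCoils)` grid; rows not in
#' the sampling mask are zero. Per-sampled-line effective echo times record
#' where in the echo train each line was acquired.
#'
#' @slot data complex array `(phase-encode, readout, coil)`.
#' @slot mask the [SamplingMask-class] the data were acquired under.
#' @slot echoTimesMs numeric vector, one effective TE per sampled line, in
#'   the acquisition order of `sampledLines(mask)`.
#' @slot noiseSigma standard deviation of the complex Gaussian noise added
#'   per real/imaginary component (a.u.).
#' @slot isReference `TRUE` for the separate calibration (ACS) scan.
#'
#' @seealso [acquire()], [acquireReference()]
#' @export
setClass("KSpaceData",
  representation(
    data = "array",
    mask = "SamplingMask",
    echoTimesMs = "numeric",
    noiseSigma = "numeric",
    isReference = "logical"
  )
)

setValidity("KSpaceData", function(object) {
  msgs <- character()
  d <- dim(object@data)
  if (length(d) != 3L)
    msgs <- c(msgs, "data must be a 3D array (pe, readout, coil)")
  else {
    if (d[1] != object@mask@nPE)
      msgs <- c(msgs, "first data dimension must equal mask nPE")
    unsampled <- setdiff(seq_len(d[1]), object@mask@lines)
    if (length(unsampled) && any(object@data[unsampled, , ] != 0))
      msgs <- c(msgs, "data must be zero on unsampled phase-encode lines")
  }
  if (length(object@echoTimesMs) != length(object@mask@lines))
    msgs <- c(msgs, "echoTimesMs must have one entry per sampled line")
  if (object@noiseSigma < 0) msgs <- c(msgs, "noiseSigma must be >= 0")
  if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# Operators and reconstruction containers
# ---------------------------------------------------------------------------

#' SENSE-type system operator
#'
#' The linear map of the reconstruction model: coil-sensitivity
#' multiplication, centered unitary 2D Fourier transform, and phase-encode
#' masking. With RSS-normalized maps and a unitary FFT its operator norm is
#' at most 1 (masking is a projection).
#'
#' @slot coils a [CoilSet-class].
#' @slot mask a [SamplingMask-class].
#' @slot imageShape integer 2-vector `(rows, cols)`.
#'
#' @seealso [systemOperator()], [applyForward()], [applyAdjoint()]
#' @export
setClass("SystemOperator",
  representation(
    coils = "CoilSet",
    mask = "SamplingMask",
    imageShape = "integer"
  )
)

setValidity("SystemOperator", function(object) {
  d <- dim(object@coils@sensitivities)
  if (!identical(object@imageShape, d[1:2]))
    return("imageShape must match the coil maps")
  if (object@mask@nPE != d[1])
    return("mask nPE must equal the number of image rows")
  TRUE
})

#' Orthonormal multilevel Haar wavelet transform
#'
#' Fixed-family (Haar) separable 2D wavelet analysis/synthesis used as the
#' sparsifying transform of the reconstruction. Orthonormal, so synthesis is
#' the exact inverse and Parseval holds; sides not divisible by `2^levels`
#' are zero-padded internally when `pad = TRUE`.
#'
#' @slot levels decomposition depth.
#' @slot boundary padding rule; `"periodic"` is the only supported value.
#' @slot pad whether non-divisible shapes are zero-padded (else an error).
#'
#' @seealso [waveletOperator()], [waveletForward()], [waveletInverse()]
#' @export
setClass("WaveletOperator",
  representation(
    levels = "integer",
    boundary = "character",
    pad = "logical"
  )
)

setValidity("WaveletOperator", function(object) {
  if (object@levels < 1L) return("levels must be >= 1")
  if (!identical(object@boundary, "periodic"))
    return("only periodic boundary handling is implemented")
  TRUE
})

#' Configuration of the l1-wavelet reconstruction solver
#'
#' @slot lam regularization weight; `NA` means the data-scaled default
#'   `1e-3 * max |A^H D|`.
#' @slot nIter iteration cap.
#' @slot tol relative-change stopping tolerance on the iterate.
#' @slot step gradient step size; `NA` means `1 / L` with `L` the largest
#'   eigenvalue of `A^H A` estimated by power iteration.
#' @slot solver `"ista"` or `"fista_restart"`.
#'
#' @seealso [reconConfig()], [csReconstruct()]
#' @export
setClass("ReconConfig",
  representation(
    lam = "numeric",
    nIter = "integer",
    tol = "numeric",
    step = "numeric",
    solver = "character"
  )
)

setValidity("ReconConfig", function(object) {
  msgs <- character()
  if (!is.na(object@lam) && object@lam < 0) msgs <- c(msgs, "lam must be >= 0")
  if (object@nIter < 1L) msgs <- c(msgs, "nIter must be >= 1")
  if (object@tol < 0) msgs <- c(msgs, "tol must be >= 0")
  if (!is.na(object@step) && object@step <= 0)
    msgs <- c(msgs, "step must be positive")
  if (!object@solver %in% c("ista", "fista_restart"))
    msgs <- c(msgs, "solver must be 'ista' or 'fista_restart'")
  if (length(msgs)) msgs else TRUE
})

#' Result of an iterative reconstruction
#'
#' @slot image complex matrix, the reconstructed image estimate.
#' @slot objectiveTrace per-iteration values of the composite objective
#'   `0.5 * ||A I - D||_2^2 + lambda * ||W I||_1`.
#' @slot nIterRun iterations actually run.
#' @slot converged whether the stopping tolerance was reached before the cap.
#' @slot lam the regularization weight actually used.
#' @slot step the gradient step actually used.
#'
#' @seealso [csReconstruct()]
#' @export
setClass("ReconResult",
  representation(
    image = "matrix",
    objectiveTrace = "numeric",
    nIterRun = "integer",
    converged = "logical",
    lam = "numeric",
    step = "numeric"
  )
)

setValidity("ReconResult", function(object) {
  msgs <- character()
  if (!all(is.finite(object@objectiveTrace)))
    msgs <- c(msgs, "objectiveTrace must be finite")
  if (length(object@objectiveTrace) != object@nIterRun)
    msgs <- c(msgs, "objectiveTrace length must equal nIterRun")
  if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# Metrics and ratings containers
# ---------------------------------------------------------------------------

#' Quantitative image-quality report
#'
#' Objective surrogates for the qualitative reading criteria: global and
#' per-tissue NRMSE, PSNR, SSIM and an organ-boundary sharpness score.
#'
#' @slot nrmse normalized root-mean-square error vs the reference.
#' @slot psnrDb peak signal-to-noise ratio in dB.
#' @slot ssim mean structural similarity index.
#' @slot edgeSharpness mean gradient magnitude across labeled organ
#'   boundaries (a.u.).
#' @slot perLabelNrmse named numeric vector, NRMSE restricted to each
#'   non-background tissue label.
#'
#' @seealso [computeMetrics()]
#' @export
setClass("MetricsReport",
  representation(
    nrmse = "numeric",
    psnrDb = "numeric",
    ssim = "numeric",
    edgeSharpness = "numeric",
    perLabelNrmse = "numeric"
  )
)

#' Five-point ordinal rating table
#'
#' Long-format consensus reading scores: one row per (case, sequence,
#' criterion), scores on the five-point scale 1 = unacceptable, 2 = poor,
#' 3 = fair, 4 = good, 5 = excellent. A case is "insufficient" on a
#' criterion when scored 1 or 2.
#'
#' @slot scores data.frame with columns `case_id`, `sequence`, `criterion`,
#'   `score`.
#'
#' @seealso [ratingTable()], [simulateRatings()], [compareSequences()]
#' @export
setClass("RatingTable", representation(scores = "data.frame"))

.RATING_SEQUENCES <- c("ssfse_conv", "mtse", "ssfse_cs")
.RATING_CRITERIA <- c("artifact", "organ_sharpness", "small_structure",
                      "overall", "liver_lesion", "pancreatic_lesion")

setValidity("RatingTable", function(object) {
  df <- object@scores
  need <- c("case_id", "sequence", "criterion", "score")
  if (!all(need %in% names(df)))
    return(paste("scores must have columns:", paste(need, collapse = ", ")))
  msgs <- character()
  if (!all(df$score %in% 1:5))
    msgs <- c(msgs, "scores must be integers in 1..5")
  if (!all(df$sequence %in% .RATING_SEQUENCES))
    msgs <- c(msgs, "unknown sequence labels")
  if (!all(df$criterion %in% .RATING_CRITERIA))
    msgs <- c(msgs, "unknown criterion labels")
  if (anyDuplicated(df[, c("case_id", "sequence", "criterion")]))
    msgs <- c(msgs, "each (case, sequence, criterion) may appear at most once")
  if (length(msgs)) msgs else TRUE
})

#' Wilcoxon signed-rank test result
#'
#' @slot statistic signed-rank sum W (sum of ranks of positive differences).
#' @slot pValue two-sided p-value.
#' @slot method `"exact"` or `"normal_approx"`.
#' @slot nEffective number of nonzero paired differences.
#' @slot significant flag at the configured threshold.
#' @slot degenerate `TRUE` when all paired differences were zero.
#'
#' @seealso [wilcoxonSignedRank()]
#' @export
setClass("WilcoxonResult",
  representation(
    statistic = "numeric",
    pValue = "numeric",
    method = "character",
    nEffective = "integer",
    significant = "logical",
    degenerate = "logical"
  )
)

setValidity("WilcoxonResult", function(object) {
  if (object@pValue < 0 || object@pValue > 1) return("pValue must lie in [0, 1]")
  TRUE
})
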