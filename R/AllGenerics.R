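# Generics and accessors. Slot access from user code should go through these.

#' Apply the forward system operator
#'
#' Maps an image to masked multi-coil k-space: per coil `c`,
#' `mask o unitaryFFT(coil_c * image)`, with unsampled phase-encode lines
#' set to zero.
#'
#' @param op a [SystemOperator-class].
#' @param image complex (or real) matrix matching `imageShape(op)`.
#' @return complex array `(pe, readout, coil)`.
#' @export
setGeneric("applyForward", function(op, image) standardGeneric("applyForward"))

#' Apply the adjoint system operator
#'
#' Maps masked multi-coil k-space back to the image domain:
#' `sum_c conj(coil_c) * unitaryIFFT(masked data_c)`.
#'
#' @param op a [SystemOperator-class].
#' @param kspace complex array `(pe, readout, coil)` or a
#'   [KSpaceData-class].
#' @return complex matrix of shape `imageShape(op)`.
#' @export
setGeneric("applyAdjoint", function(op, kspace) standardGeneric("applyAdjoint"))

#' Multilevel orthonormal Haar analysis
#'
#' @param wavelet a [WaveletOperator-class].
#' @param image numeric or complex matrix.
#' @return coefficient matrix of the (possibly padded) image size.
#' @export
setGeneric("waveletForward",
           function(wavelet, image) standardGeneric("waveletForward"))

#' Multilevel orthonormal Haar synthesis
#'
#' Exact inverse of [waveletForward()]; when the operator padded
#' internally, pass `shape` to crop back to the original image size.
#'
#' @param wavelet a [WaveletOperator-class].
#' @param coeffs coefficient matrix.
#' @param shape optional integer 2-vector, the original image shape.
#' @return image matrix.
#' @export
setGeneric("waveletInverse",
           function(wavelet, coeffs, shape = NULL) standardGeneric("waveletInverse"))

# --- accessors --------------------------------------------------------------

#' @describeIn Phantom-class proton-density map accessor.
#' @param object,x a `Phantom`.
#' @export
setGeneric("protonDensity", function(object) standardGeneric("protonDensity"))
#' @export
setMethod("protonDensity", "Phantom", function(object) object@protonDensity)

#' @describeIn Phantom-class T2 map accessor (ms).
#' @export
setGeneric("t2Map", function(object) standardGeneric("t2Map"))
#' @export
setMethod("t2Map", "Phantom", function(object) object@t2Map)

#' @describeIn Phantom-class phase map accessor (radians).
#' @export
setGeneric("phaseMap", function(object) standardGeneric("phaseMap"))
#' @export
setMethod("phaseMap", "Phantom", function(object) object@phaseMap)

#' @describeIn Phantom-class tissue-label map accessor.
#' @export
setGeneric("tissueLabels", function(object) standardGeneric("tissueLabels"))
#' @export
setMethod("tissueLabels", "Phantom", function(object) object@labels)

#' @describeIn Phantom-class lesion bookkeeping accessor.
#' @export
setGeneric("lesionList", function(object) standardGeneric("lesionList"))
#' @export
setMethod("lesionList", "Phantom", function(object) object@lesions)

#' @describeIn CoilSet-class complex sensitivity array accessor.
#' @param object a `CoilSet`.
#' @export
setGeneric("sensitivities", function(object) standardGeneric("sensitivities"))
#' @export
setMethod("sensitivities", "CoilSet", function(object) object@sensitivities)

#' @describeIn CoilSet-class number of coils.
#' @export
setGeneric("nCoils", function(object) standardGeneric("nCoils"))
#' @export
setMethod("nCoils", "CoilSet", function(object) dim(object@sensitivities)[3])

#' @describeIn CoilSet-class support mask accessor.
#' @export
setGeneric("supportMask", function(object) standardGeneric("supportMask"))
#' @export
setMethod("supportMask", "CoilSet", function(object) object@supportMask)

#' @describeIn SamplingMask-class sampled line indices in acquisition order.
#' @param object a `SamplingMask`.
#' @export
setGeneric("sampledLines", function(object) standardGeneric("sampledLines"))
#' @export
setMethod("sampledLines", "SamplingMask", function(object) object@lines)

#' @describeIn SamplingMask-class mask family.
#' @export
setGeneric("maskKind", function(object) standardGeneric("maskKind"))
#' @export
setMethod("maskKind", "SamplingMask", function(object) object@kind)

#' @describeIn SamplingMask-class ACS (calibration) line indices.
#' @export
setGeneric("acsLines", function(object) standardGeneric("acsLines"))
#' @export
setMethod("acsLines", "SamplingMask", function(object) object@acsLines)

#' @describeIn KSpaceData-class complex data array accessor.
#' @param object a `KSpaceData`.
#' @export
setGeneric("kspaceArray", function(object) standardGeneric("kspaceArray"))
#' @export
setMethod("kspaceArray", "KSpaceData", function(object) object@data)

#' @describeIn KSpaceData-class sampling mask accessor.
#' @export
setGeneric("samplingMask", function(object) standardGeneric("samplingMask"))
#' @export
setMethod("samplingMask", "KSpaceData", function(object) object@mask)

#' @describeIn KSpaceData-class per-line effective echo times (ms).
#' @export
setGeneric("echoTimesMs", function(object) standardGeneric("echoTimesMs"))
#' @export
setMethod("echoTimesMs", "KSpaceData", function(object) object@echoTimesMs)

#' @describeIn ReconResult-class reconstructed complex image.
#' @param object a `ReconResult`.
#' @export
setGeneric("reconImage", function(object) standardGeneric("reconImage"))
#' @export
setMethod("reconImage", "ReconResult", function(object) object@image)

#' @describeIn ReconResult-class per-iteration objective values.
#' @export
setGeneric("objectiveTrace", function(object) standardGeneric("objectiveTrace"))
#' @export
setMethod("objectiveTrace", "ReconResult", function(object) object@objectiveTrace)

#' @describeIn RatingTable-class underlying long-format data.frame.
#' @param object a `RatingTable`.
#' @export
setGeneric("ratingScores", function(object) standardGeneric("ratingScores"))
#' @export
setMethod("ratingScores", "RatingTable", function(object) object@scores)

# --- show methods -----------------------------------------------------------

setMethod("show", "Phantom", function(object) {
  d <- dim(object@protonDensity)
  cat(sprintf("Phantom: %d x %d, pixel %.2f mm, %d lesion(s)\n",
              d[1], d[2], object@pixelSize, nrow(object@lesions)))
  cat(sprintf("  labels: %s\n",
              paste(sort(unique(as.vector(object@labels))), collapse = " ")))
})

setMethod("show", "CoilSet", function(object) {
  d <- dim(object@sensitivities)
  cat(sprintf("CoilSet: %d coil(s) on %d x %d grid (RSS-normalized on support)\n",
              d[3], d[1], d[2]))
})

setMethod("show", "SamplingMask", function(object) {
  cat(sprintf("SamplingMask [%s]: %d of %d lines (R_eff = %.2f), %d ACS\n",
              object@kind, length(object@lines), object@nPE,
              object@nPE / max(1L, length(object@lines)),
              length(object@acsLines)))
})

setMethod("show", "ProtocolParams", function(object) {
  cat(sprintf("ProtocolParams [%s]: matrix %d x %d, R = %g, PF = %g, ACS = %d\n",
              object@sequenceKind, object@matrixRead, object@matrixPE,
              object@acceleration, object@partialFourier, object@nACS))
  cat(sprintf("  TR/TE = %g/%g ms, esp = %g ms, FA = %g deg, %d slices (inc %d)\n",
              object@trMs, object@teMs, object@echoSpacingMs, object@flipDeg,
              object@nSlices, object@sliceIncrement))
})

setMethod("show", "KSpaceData", function(object) {
  d <- dim(object@data)
  cat(sprintf("KSpaceData%s: %d x %d x %d coil(s), %d sampled line(s), sigma = %g\n",
              if (object@isReference) " (reference scan)" else "",
              d[1], d[2], d[3], length(object@mask@lines), object@noiseSigma))
})

setMethod("show", "SystemOperator", function(object) {
  cat(sprintf("SystemOperator: %d x %d image, %d coil(s), mask [%s] %d/%d lines\n",
              object@imageShape[1], object@imageShape[2],
              dim(object@coils@sensitivities)[3], object@mask@kind,
              length(object@mask@lines), object@mask@nPE))
})

setMethod("show", "ReconResult", function(object) {
  cat(sprintf("ReconResult: %d x %d image, %d iteration(s), %sconverged, lambda = %.3g\n",
              nrow(object@image), ncol(object@image), object@nIterRun,
              if (object@converged) "" else "not ", object@lam))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: NRMSE = %.4f, PSNR = %.2f dB, SSIM = %.4f, sharpness = %.4f\n",
              object@nrmse, object@psnrDb, object@ssim, object@edgeSharpness))
})

setMethod("show", "RatingTable", function(object) {
  df <- object@scores
  cat(sprintf("RatingTable: %d score(s), %d case(s), sequences: %s\n",
              nrow(df), length(unique(df$case_id)),
              paste(sort(unique(df$sequence)), collapse = " ")))
})

setMethod("show", "WilcoxonResult", function(object) {
  cat(sprintf("Wilcoxon signed-rank (%s%s): W = %g, n_eff = %d, p = %.4g%s\n",
              object@method, if (object@degenerate) ", degenerate" else "",
              object@statistic, object@nEffective, object@pValue,
              if (object@significant) " *" else ""))
})
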