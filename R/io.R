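# File I/O: array containers, mask/trace CSV exports, NIfTI image export.
# Masks, traces, metrics and configs use plain-text formats; the
# multi-array containers (phantom, k-space) use RDS serialization.

#' Save / load simulation containers
#'
#' Serializes [Phantom-class], [CoilSet-class] and [KSpaceData-class]
#' objects to single-object RDS container files.
#'
#' @param object the container to save.
#' @param path file path.
#' @return `saveContainer` returns `path` invisibly; `loadContainer`
#'   returns the object (validated).
#' @export
saveContainer <- function(object, path) {
  stopifnot(is(object, "Phantom") || is(object, "CoilSet") ||
            is(object, "KSpaceData") || is(object, "SamplingMask"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname saveContainer
#' @export
loadContainer <- function(path) {
  obj <- readRDS(path)
  methods::validObject(obj)
  obj
}

#' Export a sampling mask as a CSV index list
#'
#' Columns: `position` (acquisition order), `line` (1-based phase-encode
#' index), `is_acs`.
#'
#' @param mask a [SamplingMask-class].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
writeMaskCSV <- function(mask, path) {
  stopifnot(is(mask, "SamplingMask"))
  df <- data.frame(position = seq_along(mask@lines), line = mask@lines,
                   is_acs = mask@lines %in% mask@acsLines)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a magnitude image as a NIfTI volume
#'
#' @param image real or complex matrix; the magnitude is written.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param pixelSize isotropic pixel size in mm for the header.
#' @return `path`, invisibly.
#' @export
writeImageNIfTI <- function(image, path, pixelSize = 1.5) {
  img <- abs(image)
  vol <- array(img, dim = c(dim(img), 1L))
  nii <- RNifti::asNifti(vol, pixdim = c(pixelSize, pixelSize, 1))
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Export a magnitude image as CSV
#'
#' @inheritParams writeImageNIfTI
#' @export
writeImageCSV <- function(image, path) {
  utils::write.table(abs(image), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a protocol record as YAML
#'
#' @param params a [ProtocolParams-class].
#' @param path YAML path.
#' @return `path`, invisibly.
#' @export
writeProtocolYAML <- function(params, path) {
  stopifnot(is(params, "ProtocolParams"))
  fields <- list(
    matrix_read = params@matrixRead, matrix_pe = params@matrixPE,
    acceleration = params@acceleration,
    partial_fourier = params@partialFourier, n_acs = params@nACS,
    tr_ms = params@trMs, te_ms = params@teMs,
    echo_spacing_ms = params@echoSpacingMs, n_slices = params@nSlices,
    slice_increment = params@sliceIncrement, flip_deg = params@flipDeg,
    bandwidth_hz = params@bandwidthHz, sequence_kind = params@sequenceKind)
  yaml::write_yaml(fields, path)
  invisible(path)
}

#' Read a protocol record from YAML
#'
#' @param path YAML path written by [writeProtocolYAML()].
#' @return a [ProtocolParams-class].
#' @export
readProtocolYAML <- function(path) {
  f <- yaml::read_yaml(path)
  protocolParams(matrixRead = f$matrix_read, matrixPE = f$matrix_pe,
                 acceleration = f$acceleration,
                 partialFourier = f$partial_fourier, nACS = f$n_acs,
                 trMs = f$tr_ms, teMs = f$te_ms,
                 echoSpacingMs = f$echo_spacing_ms, nSlices = f$n_slices,
                 sliceIncrement = f$slice_increment, flipDeg = f$flip_deg,
                 bandwidthHz = f$bandwidth_hz, sequenceKind = f$sequence_kind)
}
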