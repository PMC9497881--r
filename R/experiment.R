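# End-to-end seeded experiment runner: one phantom, four acquisition arms
# (full, partial-Fourier, uniform, variable-density), each reconstructed
# with its matched method and scored against the ground-truth image.

.CONFIG_KEYS <- list(
  top = c("seed", "output_dir", "protocol", "phantom", "mask", "recon",
          "metrics", "noise_sigma", "decay"),
  protocol = c("matrix_read", "matrix_pe", "acceleration", "partial_fourier",
               "n_acs", "tr_ms", "te_ms", "echo_spacing_ms", "n_slices",
               "slice_increment", "flip_deg", "bandwidth_hz", "sequence_kind"),
  phantom = c("shape", "n_lesions", "lesion_classes", "phase_amplitude",
              "pixel_size", "texture_sd", "n_coils"),
  mask = c("center_fraction", "accel_increment", "uniform_r"),
  recon = c("lam", "n_iter", "tol", "solver", "wavelet_levels", "map_source"),
  metrics = c("ssim_window", "normalize"))

#' Default experiment configuration
#'
#' A desk-scale 128 x 128 version of the protocol geometry: total
#' acceleration 3 on the variable-density arm, 24 calibration lines,
#' 6/8 partial Fourier on the conventional arm, uniform R = 2 on the
#' parallel-imaging-geometry arm, 8 coils, small complex noise.
#'
#' @param seed global experiment seed; all stage seeds derive from it.
#' @param outputDir where [runExperiment()] writes its artifacts.
#' @return nested configuration list accepted by [runExperiment()].
#' @export
defaultRunConfig <- function(seed = 1L, outputDir = tempfile("ssfse_run_")) {
  list(
    seed = as.integer(seed),
    output_dir = outputDir,
    noise_sigma = 0.02,
    decay = TRUE,
    protocol = list(matrix_read = 128L, matrix_pe = 128L, acceleration = 3,
                    partial_fourier = 0.75, n_acs = 24L, tr_ms = 500,
                    te_ms = 99, echo_spacing_ms = 5, n_slices = 32L,
                    slice_increment = 4L, flip_deg = 118, bandwidth_hz = 372,
                    sequence_kind = "ssfse_cs"),
    phantom = list(shape = c(128L, 128L), n_lesions = 2L,
                   lesion_classes = c("fluid", "solid"),
                   phase_amplitude = 0.5, pixel_size = 1.5,
                   texture_sd = 0.05, n_coils = 8L),
    mask = list(center_fraction = 24 / 84, accel_increment = 1,
                uniform_r = 2L),
    recon = list(lam = NA_real_, n_iter = 80L, tol = 1e-6,
                 solver = "fista_restart", wavelet_levels = 3L,
                 map_source = "reference"),
    metrics = list(ssim_window = 11L, normalize = TRUE)
  )
}

#' Validate an experiment configuration
#'
#' Checks the nested key structure; unknown keys are rejected so that
#' config-file typos fail loudly instead of silently using defaults.
#'
#' @param config nested configuration list.
#' @return `config`, invisibly, on success.
#' @export
validateRunConfig <- function(config) {
  checkKeys <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra))
      stop(sprintf("unknown config key(s) under %s: %s", where,
                   paste(extra, collapse = ", ")))
    missing <- setdiff(allowed, names(x))
    if (length(missing))
      stop(sprintf("missing config key(s) under %s: %s", where,
                   paste(missing, collapse = ", ")))
  }
  checkKeys(config, .CONFIG_KEYS$top, "top level")
  for (section in c("protocol", "phantom", "mask", "recon", "metrics"))
    checkKeys(config[[section]], .CONFIG_KEYS[[section]], section)
  invisible(config)
}

#' Read / write experiment configurations as YAML
#'
#' Round-trips the nested configuration losslessly; unknown keys are
#' rejected on read.
#'
#' @param path YAML file path.
#' @return `readRunConfig` returns the validated configuration list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  # yaml scalarizes length-1 vectors; restore expected types
  cfg$seed <- as.integer(cfg$seed)
  cfg$phantom$shape <- as.integer(cfg$phantom$shape)
  if (is.null(cfg$recon$lam)) cfg$recon$lam <- NA_real_
  validateRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param config nested configuration list.
#' @export
writeRunConfig <- function(config, path) {
  validateRunConfig(config)
  yaml::write_yaml(config, path, precision = 15L)
  invisible(path)
}

.protocolFromConfig <- function(p) {
  protocolParams(matrixRead = p$matrix_read, matrixPE = p$matrix_pe,
                 acceleration = p$acceleration,
                 partialFourier = p$partial_fourier, nACS = p$n_acs,
                 trMs = p$tr_ms, teMs = p$te_ms,
                 echoSpacingMs = p$echo_spacing_ms, nSlices = p$n_slices,
                 sliceIncrement = p$slice_increment, flipDeg = p$flip_deg,
                 bandwidthHz = p$bandwidth_hz, sequenceKind = p$sequence_kind)
}

#' Run the full simulation / reconstruction / evaluation experiment
#'
#' From one configuration and one seed: simulates a phantom and coil set,
#' acquires full, partial-Fourier, uniform and variable-density k-space
#' (plus the calibration scan), reconstructs each arm with its matched
#' method (zero-filled adjoint, homodyne, zero-filled adjoint, CS solver;
#' the variable-density arm is additionally reconstructed zero-filled for
#' the baseline comparison), scores every reconstruction against the
#' ground-truth image, and writes images, masks, the objective trace and a
#' metrics CSV under `config$output_dir`. Fully reproducible: all stage
#' seeds derive deterministically from `config$seed`.
#'
#' @param config nested configuration list, see [defaultRunConfig()].
#' @param writeArtifacts set `FALSE` to skip writing files.
#' @return (invisibly) list with `metrics` (data.frame, one row per arm),
#'   `phantom`, `coils`, `recons` (named list of images), `csResult`
#'   (the [ReconResult-class]) and `paths`.
#' @export
runExperiment <- function(config = defaultRunConfig(), writeArtifacts = TRUE) {
  validateRunConfig(config)
  seed <- config$seed
  proto <- .protocolFromConfig(config$protocol)
  nPE <- proto@matrixPE
  ph <- config$phantom

  phantom <- makePhantom(shape = ph$shape, nLesions = ph$n_lesions,
                         lesionClasses = ph$lesion_classes,
                         seed = .stageSeed(seed, 1),
                         phaseAmplitude = ph$phase_amplitude,
                         pixelSize = ph$pixel_size, textureSd = ph$texture_sd)
  coils <- simulateCoils(ph$shape, nCoils = ph$n_coils,
                         seed = .stageSeed(seed, 2))
  gt <- groundTruthImage(phantom, proto@teMs)
  labels <- tissueLabels(phantom)
  sigma <- config$noise_sigma
  decay <- isTRUE(config$decay)

  budget <- echoTrainLength(proto)
  masks <- list(
    full = buildFullMask(nPE),
    partial_fourier = buildPFMask(nPE, proto@partialFourier),
    uniform = buildUniformMask(nPE, config$mask$uniform_r),
    variable_density = buildVDMask(nPE, budget,
                                   centerFraction = config$mask$center_fraction,
                                   accelIncrement = config$mask$accel_increment,
                                   seed = .stageSeed(seed, 3)))

  acq <- function(mask, stage, ordering = "linear") {
    acquire(phantom, coils, mask, proto, ordering = ordering,
            noiseSigma = sigma, seed = .stageSeed(seed, stage), decay = decay)
  }
  # center-out ordering for the full train: a full single-shot train is
  # longer than TE allows under linear ordering (effective TE would go
  # negative before the center line)
  ksFull <- acq(masks$full, 4, ordering = "center_out")
  ksPF <- acq(masks$partial_fourier, 5)
  ksUnif <- acq(masks$uniform, 6)
  ksVD <- acq(masks$variable_density, 7)
  ksRef <- acquireReference(phantom, coils, proto, noiseSigma = sigma,
                            seed = .stageSeed(seed, 8), decay = decay)

  rc <- config$recon
  # "reference": the faithful pipeline (maps from the calibration scan);
  # "true": the generator's maps, for exact-inversion checks.
  maps <- switch(match.arg(rc$map_source, c("reference", "true")),
                 reference = estimateMaps(ksRef),
                 true = coils)
  cfg <- reconConfig(lam = rc$lam, nIter = rc$n_iter, tol = rc$tol,
                     solver = rc$solver)
  wav <- waveletOperator(levels = rc$wavelet_levels)
  csRes <- csReconstruct(ksVD, maps, cfg, wav)

  recons <- list(
    full_adjoint = zeroFilledRecon(ksFull, coils),
    pf_homodyne = homodyneRecon(ksPF, coils),
    pf_zero_filled = zeroFilledRecon(ksPF, coils),
    uniform_zero_filled = zeroFilledRecon(ksUnif, coils),
    vd_zero_filled = zeroFilledRecon(ksVD, maps),
    vd_cs = reconImage(csRes))

  mw <- config$metrics$ssim_window
  norm <- isTRUE(config$metrics$normalize)
  metrics <- do.call(rbind, lapply(names(recons), function(nm) {
    metricsAsRow(computeMetrics(recons[[nm]], gt, labels = labels,
                                normalize = norm, ssimWindow = mw),
                 method = nm)
  }))

  paths <- list()
  if (writeArtifacts) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$output_dir, f)
    utils::write.csv(metrics, out("metrics.csv"), row.names = FALSE)
    for (nm in names(masks)) writeMaskCSV(masks[[nm]], out(paste0("mask_", nm, ".csv")))
    utils::write.csv(data.frame(iteration = seq_along(objectiveTrace(csRes)),
                                objective = objectiveTrace(csRes)),
                     out("cs_objective_trace.csv"), row.names = FALSE)
    for (nm in names(recons))
      writeImageNIfTI(recons[[nm]], out(paste0(nm, ".nii.gz")),
                      pixelSize = ph$pixel_size)
    writeImageNIfTI(gt, out("ground_truth.nii.gz"), pixelSize = ph$pixel_size)
    writeRunConfig(config, out("config.yaml"))
    paths <- list(dir = config$output_dir, metrics = out("metrics.csv"))
  }

  invisible(list(metrics = metrics, phantom = phantom, coils = coils,
                 recons = recons, csResult = csRes, paths = paths))
}
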