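# Phantom and coil-sensitivity generation.
#
# The generator does not attempt anatomy; it builds a piecewise-smooth
# abdominal-like slice (body ellipse, a large parenchymal organ, a secondary
# organ, a native fluid structure) with known tissue masks so that every
# image-quality metric can be verified against ground truth. T2 classes
# follow abdominal values at 3T: parenchyma ~40-60 ms, solid lesions
# 60-120 ms, fluid (cyst-like) structures >= 500 ms.

.LABELS <- c(background = 0L, body = 1L, parenchyma = 2L, organ2 = 3L,
             fluid_structure = 4L, lesion_fluid = 5L, lesion_solid = 6L)

.ellipseMask <- function(rows, cols, center, semi, angle = 0) {
  u <- matrix(seq(-1, 1, length.out = rows), rows, cols)
  v <- matrix(seq(-1, 1, length.out = cols), rows, cols, byrow = TRUE)
  du <- u - center[1]; dv <- v - center[2]
  ca <- cos(angle); sa <- sin(angle)
  ru <- ca * du + sa * dv
  rv <- -sa * du + ca * dv
  (ru / semi[1])^2 + (rv / semi[2])^2 <= 1
}

.diskMask <- function(rows, cols, center, radius) {
  r <- matrix(seq_len(rows), rows, cols)
  c <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  (r - center[1])^2 + (c - center[2])^2 <= radius^2
}

#' Generate a T2-weighted abdominal-like digital phantom
#'
#' Builds piecewise-smooth proton-density / T2 / phase / label maps for a
#' single axial slice: an elliptical body, a large parenchymal (liver-like)
#' organ, a secondary organ, a native bright-fluid structure, and `nLesions`
#' focal lesions placed inside the parenchyma without overlap. Fluid
#' lesions are long-T2 (cyst-like, bright on T2-weighting); solid lesions
#' sit in the mid-T2 range typical of solid focal lesions.
#'
#' The phase map is a low-order 2D polynomial whose amplitude is a knob:
#' homodyne partial-Fourier reconstruction assumes slowly varying phase, and
#' raising `phaseAmplitude` probes that assumption's failure mode.
#'
#' @param shape integer 2-vector `(rows, cols)`, both >= 32.
#' @param nLesions number of focal lesions to place (>= 0).
#' @param lesionClasses character vector drawn from `"fluid"`, `"solid"`;
#'   recycled over lesions in order.
#' @param seed integer seed; fixed seed gives a bit-identical phantom.
#' @param t2Parenchyma,t2Solid,t2Fluid length-2 numeric ranges (ms) for the
#'   parenchyma, solid-lesion and fluid T2 classes.
#' @param phaseAmplitude peak-to-peak scale of the smooth phase map, radians.
#' @param pixelSize isotropic pixel size in mm.
#' @param textureSd relative standard deviation of the smooth
#'   proton-density texture (0 disables texture).
#' @param maxPlacementTries bounded retries per lesion before failing.
#' @return a [Phantom-class].
#' @examples
#' ph <- makePhantom(c(64, 64), nLesions = 1, lesionClasses = "fluid", seed = 1)
#' range(t2Map(ph)[tissueLabels(ph) == 5L])
#' @export
makePhantom <- function(shape = c(128L, 128L),
                        nLesions = 2L,
                        lesionClasses = c("fluid", "solid"),
                        seed = NULL,
                        t2Parenchyma = c(40, 60),
                        t2Solid = c(60, 120),
                        t2Fluid = c(500, 1200),
                        phaseAmplitude = 0.5,
                        pixelSize = 1.5,
                        textureSd = 0.05,
                        maxPlacementTries = 200L) {
  rows <- .assertScalarCount(shape[1], "rows", 32L)
  cols <- .assertScalarCount(shape[2], "cols", 32L)
  nLesions <- .assertScalarCount(nLesions, "nLesions", 0L)
  if (nLesions > 0L && !all(lesionClasses %in% c("fluid", "solid")))
    stop("lesionClasses must be drawn from 'fluid', 'solid'")

  .withSeed(seed, {
    labels <- matrix(.LABELS[["background"]], rows, cols)
    body <- .ellipseMask(rows, cols, c(0.02, 0), c(0.90, 0.76))
    labels[body] <- .LABELS[["body"]]
    paren <- .ellipseMask(rows, cols, c(-0.12, -0.22), c(0.52, 0.42),
                          angle = 0.35) & body
    labels[paren] <- .LABELS[["parenchyma"]]
    organ2 <- .ellipseMask(rows, cols, c(-0.05, 0.52), c(0.22, 0.14),
                           angle = -0.5) & body
    labels[organ2] <- .LABELS[["organ2"]]
    fluid0 <- .ellipseMask(rows, cols, c(0.42, -0.05), c(0.12, 0.09)) & body
    labels[fluid0] <- .LABELS[["fluid_structure"]]

    # Per-class T2 values: one draw per region, inside the configured range,
    # so the class ranges hold exactly on the label masks.
    rr <- function(rg) stats::runif(1, rg[1], rg[2])
    t2 <- matrix(1, rows, cols)
    t2[labels == .LABELS[["body"]]] <- stats::runif(1, 70, 100)
    t2[labels == .LABELS[["parenchyma"]]] <- rr(t2Parenchyma)
    t2[labels == .LABELS[["organ2"]]] <- stats::runif(1, 60, 90)
    t2[labels == .LABELS[["fluid_structure"]]] <- rr(t2Fluid)

    pdBase <- c(0, 0.55, 0.85, 0.75, 1.0, 1.0, 0.8)  # by label 0..6
    pd <- matrix(pdBase[labels + 1L], rows, cols)

    # Lesions: non-overlapping disks fully inside the parenchyma.
    lesions <- data.frame(row = integer(), col = integer(),
                          radius = numeric(), class = character(),
                          stringsAsFactors = FALSE)
    if (nLesions > 0L) {
      classes <- rep_len(lesionClasses, nLesions)
      parenIdx <- which(paren & labels == .LABELS[["parenchyma"]], arr.ind = TRUE)
      if (nrow(parenIdx) == 0L) stop("no parenchyma available for lesions")
      rmin <- max(2, round(min(rows, cols) / 32))
      rmax <- max(rmin + 1, round(min(rows, cols) / 12))
      for (i in seq_len(nLesions)) {
        placed <- FALSE
        for (try in seq_len(maxPlacementTries)) {
          ctr <- parenIdx[sample.int(nrow(parenIdx), 1L), ]
          rad <- stats::runif(1, rmin, rmax)
          disk <- .diskMask(rows, cols, ctr, rad)
          # must sit fully in parenchyma and clear of earlier lesions
          if (all(labels[disk] == .LABELS[["parenchyma"]])) {
            lab <- if (classes[i] == "fluid") .LABELS[["lesion_fluid"]]
                   else .LABELS[["lesion_solid"]]
            labels[disk] <- lab
            t2[disk] <- if (classes[i] == "fluid") rr(t2Fluid) else rr(t2Solid)
            pd[disk] <- pdBase[lab + 1L]
            lesions <- rbind(lesions, data.frame(
              row = as.integer(ctr[1]), col = as.integer(ctr[2]),
              radius = rad, class = classes[i], stringsAsFactors = FALSE))
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop(sprintf("failed to place lesion %d after %d tries", i,
                       maxPlacementTries))
      }
    }

    if (textureSd > 0) {
      tex <- .gaussSmooth(matrix(stats::rnorm(rows * cols), rows, cols),
                          sigma = min(rows, cols) / 16)
      tex <- tex / max(stats::sd(as.vector(tex)), .Machine$double.eps)
      pd <- pd * pmax(0, 1 + textureSd * tex)
    }
    pd[labels == 0L] <- 0

    coef <- stats::runif(6, -1, 1)
    phase <- .polynomial2d(rows, cols, coef)
    span <- diff(range(phase))
    phase <- if (span > 0) (phase - mean(phase)) * (phaseAmplitude / span) else phase * 0

    methods::new("Phantom", protonDensity = pd, t2Map = t2, phaseMap = phase,
                 labels = labels, pixelSize = pixelSize, lesions = lesions)
  })
}

#' Complex ground-truth image at the nominal echo time
#'
#' The single reference image all metrics compare against:
#' `protonDensity * exp(-TE / T2) * exp(i * phase)`.
#'
#' @param phantom a [Phantom-class].
#' @param teMs nominal echo time in ms.
#' @return complex matrix.
#' @export
groundTruthImage <- function(phantom, teMs = 100) {
  stopifnot(is(phantom, "Phantom"), teMs >= 0)
  phantom@protonDensity * exp(-teMs / phantom@t2Map) *
    exp(1i * phantom@phaseMap)
}

#' Simulate smooth multi-coil receive sensitivities
#'
#' Places `nCoils` coil centers on a circle around the field of view and
#' gives each a Gaussian magnitude profile of spatial scale `smoothness`
#' pixels with a smooth low-order polynomial phase, then normalizes so the
#' root-sum-of-squares across coils is exactly 1 at every pixel. A single
#' coil is the identity map (sensitivity 1 everywhere), the conventional
#' single-channel normalization.
#'
#' @param shape integer 2-vector `(rows, cols)`.
#' @param nCoils number of coils (>= 1).
#' @param smoothness Gaussian spatial scale of each coil profile, pixels.
#' @param seed integer seed for the per-coil phase and center jitter.
#' @return a [CoilSet-class] with `supportMask` all `TRUE` (Gaussian
#'   profiles are strictly positive, so RSS > 0 everywhere).
#' @examples
#' cs <- simulateCoils(c(64, 64), nCoils = 8, seed = 2)
#' max(abs(sqrt(apply(abs(sensitivities(cs))^2, c(1, 2), sum)) - 1))
#' @export
simulateCoils <- function(shape = c(128L, 128L), nCoils = 8L,
                          smoothness = 48, seed = NULL) {
  rows <- .assertScalarCount(shape[1], "rows", 2L)
  cols <- .assertScalarCount(shape[2], "cols", 2L)
  nCoils <- .assertScalarCount(nCoils, "nCoils", 1L)
  if (smoothness <= 0) stop("`smoothness` must be positive")

  support <- matrix(TRUE, rows, cols)
  if (nCoils == 1L) {
    sens <- array(1 + 0i, dim = c(rows, cols, 1L))
    return(methods::new("CoilSet", sensitivities = sens, supportMask = support))
  }

  .withSeed(seed, {
    sens <- array(0i, dim = c(rows, cols, nCoils))
    rc <- matrix(seq_len(rows), rows, cols)
    cc <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
    radius <- 0.62 * sqrt((rows / 2)^2 + (cols / 2)^2)
    for (k in seq_len(nCoils)) {
      ang <- 2 * pi * (k - 1) / nCoils + stats::runif(1, -0.1, 0.1)
      ctr <- c(rows / 2 + radius * cos(ang), cols / 2 + radius * sin(ang))
      # small body-coil-like floor keeps RSS strictly positive everywhere
      mag <- 1e-3 + exp(-((rc - ctr[1])^2 + (cc - ctr[2])^2) / (2 * smoothness^2))
      ph <- .polynomial2d(rows, cols, stats::runif(6, -0.5, 0.5))
      sens[, , k] <- mag * exp(1i * ph)
    }
    rss <- sqrt(apply(abs(sens)^2, c(1, 2), sum))
    for (k in seq_len(nCoils)) sens[, , k] <- sens[, , k] / rss
    methods::new("CoilSet", sensitivities = sens, supportMask = support)
  })
}
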