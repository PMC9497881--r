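# Quantitative image-quality surrogates for the qualitative reading
# criteria: NRMSE/PSNR for global fidelity, SSIM for structural fidelity,
# and a boundary-gradient sharpness score for organ-margin crispness.

#' Normalized root-mean-square error
#'
#' `||test - reference||_2 / ||reference||_2`. Note the normalization is by
#' the reference, so the measure is not symmetric in its arguments.
#'
#' @param test,reference real matrices of one shape.
#' @return non-negative scalar.
#' @examples
#' nrmse(matrix(c(1, 0, 0, 0), 2), matrix(c(0, 0, 0, 1), 2))  # sqrt(2)
#' @export
nrmse <- function(test, reference) {
  if (!identical(dim(test), dim(reference))) stop("shapes differ")
  nref <- sqrt(sum(reference^2))
  if (nref == 0) stop("reference image is all zero")
  sqrt(sum((test - reference)^2)) / nref
}

#' Peak signal-to-noise ratio in dB
#'
#' `10 log10(max(reference)^2 / MSE)`.
#'
#' @inheritParams nrmse
#' @return scalar in dB (`Inf` for identical images).
#' @export
psnr <- function(test, reference) {
  if (!identical(dim(test), dim(reference))) stop("shapes differ")
  mse <- mean((test - reference)^2)
  peak <- max(reference)
  if (peak <= 0) stop("reference peak must be positive")
  10 * log10(peak^2 / mse)
}

# Gaussian window weights, normalized to sum 1.
.ssimWindow <- function(size, sigma) {
  half <- (size - 1) / 2
  g <- exp(-((-half):half)^2 / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

# Weighted local moment of `img` over the valid region, computed as a
# shift-and-accumulate sum (equivalent to 'valid' correlation with w).
.localMoment <- function(img, w) {
  size <- nrow(w)
  half <- (size - 1L) %/% 2L
  vr <- nrow(img) - size + 1L
  vc <- ncol(img) - size + 1L
  out <- matrix(0, vr, vc)
  for (a in seq_len(size))
    for (b in seq_len(size))
      out <- out + w[a, b] * img[a:(a + vr - 1L), b:(b + vc - 1L)]
  out
}

#' Mean structural similarity index (SSIM)
#'
#' Local means, variances and covariance are taken under a Gaussian window
#' (only where the window fits entirely inside the image), and the standard
#' SSIM formula is averaged:
#' `((2*mu_x*mu_y + c1) * (2*cov + c2)) / ((mu_x^2 + mu_y^2 + c1) * (var_x + var_y + c2))`
#' with `c1 = (k1*L)^2`, `c2 = (k2*L)^2` and dynamic range
#' `L = max(reference)`.
#'
#' @inheritParams nrmse
#' @param window odd window size in pixels (default 11).
#' @param sigma Gaussian window standard deviation (default 1.5).
#' @param k1,k2 stabilization constants (conventional 0.01 and 0.03).
#' @return scalar, at most 1; 1 for identical images.
#' @export
ssim <- function(test, reference, window = 11L, sigma = 1.5,
                 k1 = 0.01, k2 = 0.03) {
  if (!identical(dim(test), dim(reference))) stop("shapes differ")
  window <- .assertScalarCount(window, "window", 1L)
  if (window %% 2L == 0L) stop("window must be odd")
  if (window > min(dim(test))) stop("window larger than the image")
  L <- max(reference)
  c1 <- (k1 * L)^2
  c2 <- (k2 * L)^2
  w <- .ssimWindow(window, sigma)
  mx <- .localMoment(test, w)
  my <- .localMoment(reference, w)
  sx <- .localMoment(test^2, w) - mx^2
  sy <- .localMoment(reference^2, w) - my^2
  sxy <- .localMoment(test * reference, w) - mx * my
  num <- (2 * mx * my + c1) * (2 * sxy + c2)
  den <- (mx^2 + my^2 + c1) * (sx + sy + c2)
  mean(num / den)
}

#' Organ-boundary edge sharpness
#'
#' Mean central-difference gradient magnitude of the image over the
#' boundary pixels of non-background tissue labels (pixels whose label
#' differs from at least one 4-neighbor). Invariant to a global intensity
#' offset; decreases under blurring.
#'
#' @param image real matrix.
#' @param labels integer label matrix aligned to `image`; 0 = background.
#' @return non-negative scalar.
#' @export
edgeSharpness <- function(image, labels) {
  if (!identical(dim(image), dim(labels))) stop("shapes differ")
  r <- nrow(labels); c <- ncol(labels)
  inner <- labels[2:(r - 1), 2:(c - 1)]
  boundary <- (inner != labels[1:(r - 2), 2:(c - 1)]) |
              (inner != labels[3:r, 2:(c - 1)]) |
              (inner != labels[2:(r - 1), 1:(c - 2)]) |
              (inner != labels[2:(r - 1), 3:c])
  boundary <- boundary & inner != 0L
  if (!any(boundary)) stop("no boundary pixels in the label map")
  gx <- (image[3:r, 2:(c - 1)] - image[1:(r - 2), 2:(c - 1)]) / 2
  gy <- (image[2:(r - 1), 3:c] - image[2:(r - 1), 1:(c - 2)]) / 2
  gm <- sqrt(gx^2 + gy^2)
  mean(gm[boundary])
}

#' Full image-quality report
#'
#' Magnitude images are compared after rescaling the test image to the
#' reference's l2 norm (reconstruction methods differ by a global scale),
#' then NRMSE, PSNR, SSIM, organ-boundary sharpness and per-tissue NRMSE
#' are computed.
#'
#' @param test complex or real matrix (magnitude is taken).
#' @param reference complex or real reference image.
#' @param labels optional tissue-label matrix for sharpness and per-label
#'   NRMSE.
#' @param normalize rescale the test image to the reference l2 norm.
#' @param ssimWindow SSIM window size.
#' @return a [MetricsReport-class].
#' @export
computeMetrics <- function(test, reference, labels = NULL, normalize = TRUE,
                           ssimWindow = 11L) {
  tm <- abs(test)
  rm_ <- abs(reference)
  if (normalize) {
    nt <- sqrt(sum(tm^2))
    if (nt > 0) tm <- tm * sqrt(sum(rm_^2)) / nt
  }
  perLabel <- numeric(0)
  sharp <- NA_real_
  if (!is.null(labels)) {
    sharp <- edgeSharpness(tm, labels)
    labs <- sort(setdiff(unique(as.vector(labels)), 0L))
    perLabel <- vapply(labs, function(l) {
      m <- labels == l
      sqrt(sum((tm[m] - rm_[m])^2)) / max(sqrt(sum(rm_[m]^2)),
                                          .Machine$double.eps)
    }, numeric(1))
    names(perLabel) <- as.character(labs)
  }
  methods::new("MetricsReport",
    nrmse = nrmse(tm, rm_),
    psnrDb = psnr(tm, rm_),
    ssim = ssim(tm, rm_, window = ssimWindow),
    edgeSharpness = sharp,
    perLabelNrmse = perLabel)
}

#' Flatten a metrics report to a one-row data.frame
#'
#' @param report a [MetricsReport-class].
#' @param method optional method label for the row.
#' @return data.frame with one row.
#' @export
metricsAsRow <- function(report, method = NA_character_) {
  row <- data.frame(method = method, nrmse = report@nrmse,
                    psnr_db = report@psnrDb, ssim = report@ssim,
                    edge_sharpness = report@edgeSharpness,
                    stringsAsFactors = FALSE)
  for (nm in names(report@perLabelNrmse))
    row[[paste0("nrmse_label_", nm)]] <- report@perLabelNrmse[[nm]]
  row
}
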