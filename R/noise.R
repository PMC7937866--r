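#' Estimate the Rician noise correction factor from the b0 image
#'
#' The noise correction factor (NCF) is the square of the mode of the
#' signal histogram of the non-diffusion-weighted image. On magnitude MRI
#' the signal-free background follows a Rayleigh distribution whose mode
#' equals the per-channel noise level, so with enough background in the
#' field of view the histogram mode tracks the noise floor.
#'
#' By default all finite, strictly positive voxels of the image enter the
#' histogram (exact zeros are treated as padding); a mask restricts it.
#' Bin width follows the Freedman–Diaconis rule; the mode is reported as
#' the median of the samples in the fullest bin, which is exact for
#' discrete-valued images.
#'
#' @param b0 numeric array (typically 3D), the S(0) image.
#' @param mask optional logical array of the same shape; voxels to include.
#' @return a [NoiseModel-class] object.
#' @examples
#' estimateNCF(array(7, c(10, 10, 2)))  # mode 7, NCF 49
#' @export
estimateNCF <- function(b0, mask = NULL) {
  x <- as.vector(b0)
  if (!is.null(mask)) {
    if (length(mask) != length(x)) stop("mask shape must match the image")
    keep <- as.vector(mask) & is.finite(x)
    if (!any(keep)) stop("mask excludes every voxel")
    x <- x[keep]
  } else {
    x <- x[is.finite(x) & x > 0]
  }
  if (length(x) < 100)
    stop("need at least 100 finite voxels to estimate the noise floor")

  rng <- range(x)
  if (diff(rng) == 0) {
    return(new("NoiseModel", ncf = rng[1]^2, modeEstimate = rng[1],
               binWidth = 0))
  }
  bw <- 2 * stats::IQR(x) / length(x)^(1 / 3)
  if (bw <= 0) bw <- diff(rng) / ceiling(sqrt(length(x)))
  breaks <- seq(rng[1], rng[2] + bw, by = bw)
  bin <- findInterval(x, breaks, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = length(breaks))
  top <- which.max(counts)
  # with fine bins the single fullest bin jitters across the flat top of
  # a smooth peak, so average the near-maximal plateau; a lone dominant
  # bin (discrete-valued images) keeps its exact sample median instead
  plateau <- which(counts >= 0.95 * counts[top])
  if (length(plateau) > 1) {
    mids <- breaks[plateau] + bw / 2
    mode <- sum(mids * counts[plateau]) / sum(counts[plateau])
  } else {
    mode <- stats::median(x[bin == top])
  }
  if (top == length(counts) || counts[top] < 3)
    warning("weak histogram mode; the image may lack a noise background ",
            "and the NCF may be meaningless")
  new("NoiseModel", ncf = mode^2, modeEstimate = mode, binWidth = bw)
}

#' Rician noise-floor correction of measured magnitudes
#'
#' The squared measured magnitude is modelled as the squared noise-free
#' signal plus the noise correction factor, so the corrected signal is
#' \eqn{\sqrt{\max(\hat S^2 - NCF, 0)}}. Values whose square falls below
#' the NCF are floored at zero.
#'
#' @param measured numeric vector/array of measured magnitudes (>= 0).
#' @param ncf noise correction factor (squared signal units), or a
#'   [NoiseModel-class] object.
#' @return corrected signal, same shape as `measured`.
#' @examples
#' correctSignal(5, 9)  # 4
#' @export
correctSignal <- function(measured, ncf) {
  if (is(ncf, "NoiseModel")) ncf <- ncf@ncf
  if (length(ncf) != 1L || !is.finite(ncf) || ncf < 0)
    stop("ncf must be a single non-negative number")
  if (any(measured < 0, na.rm = TRUE)) stop("magnitudes must be >= 0")
  sqrt(pmax(measured^2 - ncf, 0))
}
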