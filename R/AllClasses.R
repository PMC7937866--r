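#' @import methods
NULL

#' Acquisition scheme of a diffusion-weighted series
#'
#' Ordered per-frame b-values and motion-probing-gradient (MPG) direction
#' vectors describing the layout of the fourth dimension of a 4D IVIM series.
#' Frames are grouped direction-major: all b-values of the first MPG
#' direction, then all b-values of the second, and so on.  A \code{b = 0}
#' frame may carry either the zero vector or its block's direction vector.
#'
#' @slot bValues numeric vector, one b-value (s/mm^2) per frame.
#' @slot directions 3 x n numeric matrix of unit (or zero, at b = 0)
#'   direction vectors, one column per frame.
#'
#' @seealso [ivimScheme()] for the default brain protocol (17 b-values
#'   from 0 to 2500 s/mm^2 in 6 MPG directions), [seriesLayout()].
#' @export
setClass("AcquisitionScheme",
  representation(bValues = "numeric", directions = "matrix"))

setValidity("AcquisitionScheme", function(object) {
  b <- object@bValues
  g <- object@directions
  if (!is.numeric(g) || nrow(g) != 3L)
    return("directions must be a 3 x n numeric matrix")
  if (ncol(g) != length(b))
    return("number of direction columns must equal number of b-values")
  if (any(!is.finite(b)) || any(b < 0))
    return("b-values must be finite and non-negative")
  nrm <- sqrt(colSums(g^2))
  if (any(b > 0 & nrm < 1e-8))
    return("zero direction vectors are only allowed at b = 0")
  if (any(nrm > 1e-8 & abs(nrm - 1) > 1e-6))
    return("non-zero direction vectors must be unit-normalized")
  TRUE
})

#' Rician noise model estimated from the b0 image
#'
#' The noise correction factor (NCF) is the square of the mode of the
#' signal histogram of the non-diffusion-weighted image; measured
#' magnitudes are corrected as \eqn{\sqrt{\max(\hat S^2 - NCF, 0)}}.
#'
#' @slot ncf noise correction factor (squared signal units).
#' @slot modeEstimate histogram mode of the b0 image (signal units).
#' @slot binWidth histogram bin width used for the mode (signal units).
#'
#' @seealso [estimateNCF()], [correctSignal()]
#' @export
setClass("NoiseModel",
  representation(ncf = "numeric", modeEstimate = "numeric",
                 binWidth = "numeric"))

setValidity("NoiseModel", function(object) {
  if (length(object@ncf) != 1L || !is.finite(object@ncf) || object@ncf < 0)
    return("ncf must be a single finite non-negative number")
  if (abs(object@ncf - object@modeEstimate^2) > 1e-6 * max(1, object@ncf))
    return("ncf must equal modeEstimate^2")
  TRUE
})

#' Volumetric IVIM parameter maps
#'
#' Output of [fitVolume()]: perfusion fraction (stored in percent),
#' pseudo-diffusion coefficient, mean diffusivity and apparent mean kurtosis
#' maps, the integer-coded optimal-model map (0 = background/unfit,
#' 1 = Gaussian, 2 = Kurtosis, 3 = Gamma) and a per-voxel flag bitmask.
#'
#' Flag bits: 1 = no model converged in all directions (voxel unfit),
#' 2 = perfusion fit pinned at a parameter bound, 4 = two or more
#' high-b points zero-floored after noise correction (low quality),
#' 8 = all perfusion residuals non-positive (Sv0 forced to 0).
#'
#' @slot fp perfusion fraction map, percent.
#' @slot dstar pseudo-diffusion coefficient map, mm^2/s.
#' @slot md mean diffusivity map, mm^2/s.
#' @slot kapp apparent mean kurtosis map, dimensionless.
#' @slot model integer-coded model map.
#' @slot flags integer flag bitmask map.
#' @slot mode fitting mode used: "optimal" or a forced model name.
#'
#' @seealso [fitVolume()], [writeParameterMaps()], [modelTerritory()]
#' @export
setClass("ParameterMaps",
  representation(fp = "array", dstar = "array", md = "array",
                 kapp = "array", model = "array", flags = "array",
                 mode = "character"))

setValidity("ParameterMaps", function(object) {
  d <- dim(object@fp)
  for (s in c("dstar", "md", "kapp", "model", "flags"))
    if (!identical(dim(slot(object, s)), d))
      return("all maps must share the same dimensions")
  m <- object@model
  if (any(!(m[is.finite(m)] %in% 0:3)))
    return("model map values must be integer codes 0..3")
  TRUE
})

#' Digital phantom specification
#'
#' Geometry (a region label map), per-region generative model and ground
#' truth parameters, the Rician noise level and the number of repeated
#' acquisitions, from which [generatePhantom()] simulates a full 4D IVIM
#' series.
#'
#' @slot labels integer 3D array; 0 is background, positive values are
#'   region labels matching the \code{label} column of \code{regions}.
#' @slot regions data.frame with columns \code{label}, \code{tissue},
#'   \code{model}, \code{Se0}, \code{D}, \code{K}, \code{fp}, \code{Dstar}.
#'   \code{fp} is the dimensionless perfusion fraction in [0, 0.5];
#'   \code{Dstar} may be NA when \code{fp} is 0.
#' @slot sigma Rician noise level per complex channel (signal units).
#' @slot nRepeats number of repeated acquisitions to simulate (for
#'   number-of-averages experiments).
#' @slot seed integer RNG seed making the phantom reproducible.
#'
#' @seealso [phantomSpec()], [defaultPhantomSpec()], [generatePhantom()]
#' @export
setClass("PhantomSpec",
  representation(labels = "array", regions = "data.frame",
                 sigma = "numeric", nRepeats = "integer", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  r <- object@regions
  need <- c("label", "tissue", "model", "Se0", "D", "K", "fp", "Dstar")
  if (!all(need %in% names(r)))
    return(paste("regions must have columns:", paste(need, collapse = ", ")))
  lab <- unique(as.vector(object@labels))
  lab <- lab[lab != 0]
  if (!all(lab %in% r$label))
    return("every non-zero label needs a row in regions")
  if (nrow(r)) {
    if (any(r$Se0 < 0) || any(r$D <= 0) || any(r$K < 0))
      return("region parameters must satisfy Se0 >= 0, D > 0, K >= 0")
    if (any(r$fp < 0 | r$fp > 0.5))
      return("region fp must lie in [0, 0.5]")
    if (any(r$fp > 0 & (!is.finite(r$Dstar) | r$Dstar <= 0)))
      return("regions with fp > 0 need a positive Dstar")
    if (!all(r$model %in% c("gaussian", "kurtosis", "gamma")))
      return("region model must be gaussian, kurtosis or gamma")
  }
  if (object@sigma < 0) return("sigma must be non-negative")
  if (object@nRepeats < 1L) return("nRepeats must be at least 1")
  TRUE
})

#' Complete fit record for a single voxel
#'
#' All outputs of the two-step fit at one voxel: the per-direction diffusion
#' fits (for each candidate model in optimal mode), the selected model, the
#' direction-averaged scalar parameters and the joint perfusion fit.
#'
#' @slot fits data.frame of per-direction diffusion fits with columns
#'   \code{model}, \code{direction}, \code{Se0}, \code{D}, \code{K},
#'   \code{rss}, \code{caic}, \code{n}, \code{converged}.
#' @slot selectedModel character, the selected (or forced) model.
#' @slot se0Mean mean of the six selected-model Se0 estimates.
#' @slot md mean diffusivity: mean of the six selected-model D estimates.
#' @slot kappMean apparent mean kurtosis: mean of the six selected-model K
#'   estimates (identically 0 when the Gaussian model is selected).
#' @slot sv0 intravascular non-diffusion-weighted signal.
#' @slot dstar pseudo-diffusion coefficient, mm^2/s.
#' @slot fp perfusion fraction, dimensionless.
#' @slot flags integer flag bitmask (see [ParameterMaps-class]).
#'
#' @seealso [fitVoxel()]
#' @export
setClass("VoxelRecord",
  representation(fits = "data.frame", selectedModel = "character",
                 se0Mean = "numeric", md = "numeric", kappMean = "numeric",
                 sv0 = "numeric", dstar = "numeric", fp = "numeric",
                 flags = "integer"))

#' Regional parameter summary
#'
#' Per-region means and standard deviations of the IVIM parameters over
#' filtered region masks, with GM/WM ratios of the perfusion parameters and
#' voxel counts before/after exclusions.
#'
#' @slot table data.frame with columns \code{region}, \code{parameter},
#'   \code{mean}, \code{sd}, \code{n}.
#' @slot ratios named numeric vector of GM/WM ratios (fp, dstar) when both
#'   regions are present, otherwise empty.
#' @slot counts data.frame with columns \code{region}, \code{before},
#'   \code{after} (voxel counts around exclusions).
#'
#' @seealso [regionalSummary()], [applyExclusions()]
#' @export
setClass("RegionalSummary",
  representation(table = "data.frame", ratios = "numeric",
                 counts = "data.frame"))
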