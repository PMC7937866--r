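#' @describeIn AcquisitionScheme-class number of frames in the series
#' @param object,x an object of the documented class
#' @export
setMethod("length", "AcquisitionScheme", function(x) length(x@bValues))

#' Per-frame b-values of a scheme
#' @param scheme an [AcquisitionScheme-class] object
#' @return numeric vector of b-values (s/mm^2), one per frame
#' @export
bValues <- function(scheme) scheme@bValues

#' Per-frame MPG direction vectors of a scheme
#' @param scheme an [AcquisitionScheme-class] object
#' @return 3 x n matrix of direction vectors, one column per frame
#' @export
mpgDirections <- function(scheme) scheme@directions

setMethod("show", "AcquisitionScheme", function(object) {
  lay <- seriesLayout(object)
  cat("AcquisitionScheme:", length(object@bValues), "frames,",
      length(lay$bGrid), "b-values x", lay$nDirections, "directions\n")
  cat("  b:", paste(format(lay$bGrid, trim = TRUE), collapse = ", "),
      "s/mm^2\n")
})

#' Noise correction factor of a NoiseModel
#' @param noise a [NoiseModel-class] object
#' @return the NCF (squared signal units)
#' @export
ncf <- function(noise) noise@ncf

setMethod("show", "NoiseModel", function(object) {
  cat(sprintf("NoiseModel: mode = %.4g, NCF = %.4g (bin width %.4g)\n",
              object@modeEstimate, object@ncf, object@binWidth))
})

#' Extract one map from a ParameterMaps object
#'
#' @param maps a [ParameterMaps-class] object
#' @param which one of "fp" (percent), "dstar" (mm^2/s), "md" (mm^2/s),
#'   "kapp", "model" (integer codes) or "flags"
#' @return the requested 3D array
#' @export
parameterMap <- function(maps,
                         which = c("fp", "dstar", "md", "kapp",
                                   "model", "flags")) {
  which <- match.arg(which)
  slot(maps, which)
}

setMethod("show", "ParameterMaps", function(object) {
  d <- dim(object@fp)
  fitted <- sum(object@model > 0, na.rm = TRUE)
  cat("ParameterMaps (mode:", object@mode, ") ",
      paste(d, collapse = " x "), "voxels,", fitted, "fitted\n")
  if (fitted > 0) {
    tab <- modelTerritory(object@model, object@model > 0)
    cat("  model territory (%):",
        paste(sprintf("%s %.1f", names(tab), tab), collapse = ", "), "\n")
    cat(sprintf("  fp %%: median %.2f | D* median %.3g | MD median %.3g | Kapp median %.2f\n",
                stats::median(object@fp[object@model > 0], na.rm = TRUE),
                stats::median(object@dstar[object@model > 0], na.rm = TRUE),
                stats::median(object@md[object@model > 0], na.rm = TRUE),
                stats::median(object@kapp[object@model > 0], na.rm = TRUE)))
  }
})

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec:", paste(dim(object@labels), collapse = " x "),
      "grid,", nrow(object@regions), "regions, sigma =", object@sigma,
      ", repeats =", object@nRepeats, ", seed =", object@seed, "\n")
  print(phantomTruthTable(object))
})

setMethod("show", "VoxelRecord", function(object) {
  cat("VoxelRecord: selected model =", object@selectedModel, "\n")
  cat(sprintf("  MD = %.4g mm^2/s, Kapp = %.3f, Se0 = %.4g\n",
              object@md, object@kappMean, object@se0Mean))
  cat(sprintf("  fp = %.3f (%.1f%%), D* = %.4g mm^2/s, Sv0 = %.4g, flags = %d\n",
              object@fp, 100 * object@fp, object@dstar, object@sv0,
              object@flags))
})

#' Selected (optimal or forced) model of a voxel fit
#' @param record a [VoxelRecord-class] object
#' @return character model name
#' @export
selectedModel <- function(record) record@selectedModel

#' Per-direction diffusion fits of a voxel record
#' @param record a [VoxelRecord-class] object
#' @return data.frame of per-direction, per-model fits
#' @export
diffusionFits <- function(record) record@fits

#' Scalar parameters of a voxel record
#' @param record a [VoxelRecord-class] object
#' @return named numeric vector (se0Mean, md, kapp, fp, dstar, sv0)
#' @export
voxelParams <- function(record) {
  c(se0Mean = record@se0Mean, md = record@md, kapp = record@kappMean,
    fp = record@fp, dstar = record@dstar, sv0 = record@sv0)
}

setMethod("show", "RegionalSummary", function(object) {
  cat("RegionalSummary over", nrow(object@counts), "regions\n")
  print(object@table, row.names = FALSE)
  if (length(object@ratios)) {
    cat("GM/WM ratios:",
        paste(sprintf("%s = %.3g", names(object@ratios), object@ratios),
              collapse = ", "), "\n")
  }
})

#' Summary table of a RegionalSummary
#' @param summary a [RegionalSummary-class] object
#' @return data.frame (region, parameter, mean, sd, n)
#' @export
regionalTable <- function(summary) summary@table

#' GM/WM perfusion-parameter ratios of a RegionalSummary
#' @param summary a [RegionalSummary-class] object
#' @return named numeric vector (possibly empty)
#' @export
regionalRatios <- function(summary) summary@ratios
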