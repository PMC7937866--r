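# restore trailing singleton dimensions (NIfTI writers drop them)
.pad3d <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  if (length(d) < 3) dim(x) <- c(d, rep(1L, 3 - length(d)))
  x
}

#' Fit a whole 4D IVIM volume
#'
#' Applies the two-step segmented fit voxel-by-voxel over a mask and
#' assembles the parameter maps: perfusion fraction (percent),
#' pseudo-diffusion coefficient, mean diffusivity, apparent mean kurtosis,
#' the integer-coded optimal-model map and a per-voxel flag map.
#' The result is deterministic given identical inputs and settings and
#' does not depend on voxel traversal order; per-voxel failures are
#' recorded in the flag map and never abort the run.
#'
#' @param volume 4D numeric array; the 4th dimension follows `scheme`.
#' @param scheme an [AcquisitionScheme-class] matching `dim(volume)[4]`.
#' @param mask logical 3D array of voxels to fit; default: voxels whose
#'   b = 0 signal (first direction block) is positive.
#' @param noise optional [NoiseModel-class] (or a single NCF value); when
#'   given, all magnitudes are noise-floor corrected before fitting. NULL
#'   applies no correction.
#' @param mode "optimal" or a forced model name.
#' @param control an [ivimControl()] list.
#' @param verbose print progress every few hundred voxels.
#' @return a [ParameterMaps-class] object.
#' @export
fitVolume <- function(volume, scheme, mask = NULL, noise = NULL,
                      mode = c("optimal", "gaussian", "kurtosis", "gamma"),
                      control = ivimControl(), verbose = FALSE) {
  mode <- match.arg(mode)
  d <- dim(volume)
  if (length(d) != 4) stop("volume must be a 4D array")
  if (d[4] != length(scheme@bValues))
    stop("4th dimension (", d[4], ") does not match the scheme (",
         length(scheme@bValues), " frames)")
  lay <- seriesLayout(scheme)

  if (!is.null(noise)) {
    ncfVal <- if (is(noise, "NoiseModel")) noise@ncf else as.numeric(noise)
    if (ncfVal > 0) volume <- correctSignal(volume, ncfVal)
  }

  if (is.null(mask)) {
    b0frame <- lay$frameIndex[which.min(lay$bGrid), 1]
    mask <- volume[, , , b0frame] > 0
  }
  mask <- .pad3d(mask)
  if (!identical(as.integer(dim(mask)), as.integer(d[1:3])))
    stop("mask shape must match the volume")

  dims3 <- d[1:3]
  mk <- function(init) array(init, dims3)
  fp <- mk(NA_real_); dstar <- mk(NA_real_); md <- mk(NA_real_)
  kapp <- mk(NA_real_); modelMap <- mk(0L); flagMap <- mk(0L)

  idx <- which(mask)
  if (length(idx) == 0) {
    warning("empty mask: no voxels to fit")
    return(new("ParameterMaps", fp = fp, dstar = dstar, md = md,
               kapp = kapp, model = modelMap, flags = flagMap, mode = mode))
  }

  nvox <- prod(dims3)
  flat <- matrix(volume, nrow = nvox)  # voxels x frames
  b <- lay$bGrid
  fIdx <- lay$frameIndex
  for (k in seq_along(idx)) {
    v <- idx[k]
    sig <- matrix(flat[v, fIdx], nrow = length(b))
    rec <- tryCatch(.fitVoxelCore(b, sig, mode, control),
                    error = function(e) NULL)
    if (is.null(rec)) {
      flagMap[v] <- 1L
      next
    }
    flagMap[v] <- as.integer(rec$flags)
    if (is.na(rec$selected)) next
    modelMap[v] <- modelCode(rec$selected)
    fp[v] <- 100 * rec$fp
    dstar[v] <- rec$dstar
    md[v] <- rec$md
    kapp[v] <- rec$kapp
    if (verbose && k %% 500 == 0)
      message("fitted ", k, " / ", length(idx), " voxels")
  }
  new("ParameterMaps", fp = fp, dstar = dstar, md = md, kapp = kapp,
      model = modelMap, flags = flagMap, mode = mode)
}

#' Average repeated acquisitions
#'
#' Voxelwise arithmetic mean of the first `nAvg` repeats of an acquisition,
#' the number-of-averages (NA) mechanism used to trade scan time for SNR.
#'
#' @param volumes list of identically shaped 4D arrays (repeats).
#' @param nAvg how many of the leading repeats to average.
#' @return a 4D array.
#' @export
averageRepeats <- function(volumes, nAvg = length(volumes)) {
  if (!is.list(volumes) || length(volumes) == 0)
    stop("volumes must be a non-empty list")
  if (nAvg < 1 || nAvg > length(volumes))
    stop("nAvg must be between 1 and the number of repeats")
  d <- dim(volumes[[1]])
  for (v in volumes[seq_len(nAvg)])
    if (!identical(dim(v), d)) stop("repeat shapes differ")
  out <- volumes[[1]]
  if (nAvg > 1) for (i in 2:nAvg) out <- out + volumes[[i]]
  out / nAvg
}

#' Proportional territory of each model within a region
#'
#' Percentage of region voxels assigned to each candidate model in an
#' optimal-model map.
#'
#' @param modelMap integer-coded model map (array).
#' @param regionMask logical array of the region.
#' @return named numeric vector (gaussian, kurtosis, gamma), percent;
#'   sums to 100 over fitted voxels.
#' @export
modelTerritory <- function(modelMap, regionMask) {
  if (!identical(dim(modelMap), dim(regionMask)))
    stop("map and mask shapes differ")
  m <- modelMap[regionMask]
  if (length(m) == 0) stop("empty region")
  counts <- vapply(MODEL_CODES, function(code) sum(m == code), 0)
  total <- sum(counts)
  if (total == 0) stop("region contains no fitted voxels")
  100 * counts / total
}

#' Percentage of voxels whose optimal model differs between two maps
#'
#' Used to quantify model-selection stability, e.g. between analyses at
#' different numbers of averages.
#'
#' @param mapA,mapB integer-coded model maps of identical shape.
#' @param mask logical array of voxels to compare; default: voxels fitted
#'   in both maps.
#' @return percentage of differing voxels.
#' @export
territoryChange <- function(mapA, mapB, mask = NULL) {
  if (!identical(dim(mapA), dim(mapB))) stop("map shapes differ")
  if (is.null(mask)) mask <- mapA > 0 & mapB > 0
  if (!identical(dim(mask), dim(mapA))) stop("mask shape differs")
  n <- sum(mask)
  if (n == 0) stop("empty mask")
  100 * sum(mapA[mask] != mapB[mask]) / n
}
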