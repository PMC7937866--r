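#' Build region masks from tissue probability maps
#'
#' A voxel belongs to a tissue iff that tissue's probability (or
#' partial-volume fraction, resampled to the IVIM grid) strictly exceeds
#' the threshold; the default 0.95 collects near-pure voxels and guards
#' against partial-volume, mis-segmentation and mis-registration effects.
#'
#' @param probMaps named list of numeric arrays in [0, 1] (e.g. GM, WM,
#'   CSF), co-registered to the parameter maps.
#' @param threshold inclusion threshold, in (0.5, 1].
#' @return named list of logical arrays.
#' @export
buildRegionMasks <- function(probMaps, threshold = 0.95) {
  if (!is.list(probMaps) || is.null(names(probMaps)))
    stop("probMaps must be a named list")
  if (threshold <= 0.5 || threshold > 1)
    stop("threshold must lie in (0.5, 1]")
  lapply(probMaps, function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
      stop("probabilities must lie in [0, 1]")
    !is.na(p) & p > threshold
  })
}

#' Apply the physiology-based exclusion rules to region masks
#'
#' In tissue regions (any region not named "CSF") voxels with MD > D* are
#' excluded: a pseudo-diffusion coefficient below the tissue diffusivity
#' marks a failed perfusion fit. In the CSF region voxels with apparent
#' mean kurtosis > 0.1 are excluded: free water must be nearly Gaussian.
#'
#' @param masks named list of logical arrays (names containing "CSF",
#'   case-insensitively, get the CSF rule).
#' @param maps a [ParameterMaps-class] object.
#' @return the filtered mask list.
#' @export
applyExclusions <- function(masks, maps) {
  md <- maps@md; dstar <- maps@dstar; kapp <- maps@kapp
  lapply(stats::setNames(names(masks), names(masks)), function(nm) {
    m <- masks[[nm]]
    if (!identical(dim(m), dim(md))) stop("mask shape differs from maps")
    if (grepl("csf", nm, ignore.case = TRUE)) {
      m & !(is.finite(kapp) & kapp > 0.1)
    } else {
      m & !(is.finite(md) & is.finite(dstar) & md > dstar)
    }
  })
}

#' Regional means and GM/WM ratios of the IVIM parameters
#'
#' Means and standard deviations of fp (percent), D*, MD and apparent mean
#' kurtosis over each (already filtered) region mask, plus the GM/WM
#' ratios of the fp and D* means when both regions are present. Regions
#' left empty after exclusion are flagged with a warning and omitted.
#'
#' @param masks named list of logical arrays; pass the result of
#'   [applyExclusions()] for the standard workflow.
#' @param maps a [ParameterMaps-class] object.
#' @param masksBefore optional unfiltered masks, used only to report voxel
#'   counts before exclusion.
#' @return a [RegionalSummary-class] object.
#' @export
regionalSummary <- function(masks, maps, masksBefore = NULL) {
  params <- c(fp = "fp", dstar = "dstar", md = "md", kapp = "kapp")
  rows <- list(); counts <- list()
  means <- list()
  for (nm in names(masks)) {
    m <- masks[[nm]] & maps@model > 0
    nAfter <- sum(m)
    nBefore <- if (!is.null(masksBefore)) sum(masksBefore[[nm]]) else
      sum(masks[[nm]])
    counts[[nm]] <- data.frame(region = nm, before = nBefore,
                               after = nAfter)
    if (nAfter == 0) {
      warning("region ", nm, " is empty after exclusions; omitted")
      next
    }
    means[[nm]] <- list()
    for (p in names(params)) {
      vals <- slot(maps, params[[p]])[m]
      vals <- vals[is.finite(vals)]
      rows[[paste(nm, p)]] <- data.frame(
        region = nm, parameter = p,
        mean = if (length(vals)) mean(vals) else NA_real_,
        sd = if (length(vals) > 1) stats::sd(vals) else 0,
        n = length(vals))
      means[[nm]][[p]] <- if (length(vals)) mean(vals) else NA_real_
    }
  }
  ratios <- numeric(0)
  gm <- names(means)[grepl("^gm$", names(means), ignore.case = TRUE)]
  wm <- names(means)[grepl("^wm$", names(means), ignore.case = TRUE)]
  if (length(gm) == 1 && length(wm) == 1) {
    for (p in c("fp", "dstar")) {
      a <- means[[gm]][[p]]; b <- means[[wm]][[p]]
      if (is.finite(a) && is.finite(b) && b != 0)
        ratios[p] <- a / b
    }
  }
  new("RegionalSummary",
      table = if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
              else data.frame(),
      ratios = ratios,
      counts = do.call(rbind, c(counts, list(make.row.names = FALSE))))
}
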