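#' Reference tissue parameter sets for phantom construction
#'
#' Literature-derived healthy-brain IVIM parameters for gray matter, white
#' matter and CSF, one set per analysis model. The "optimal" set pairs
#' each tissue with its dominant model (CSF Gaussian, WM Kurtosis, GM
#' Gamma) and that model's in-vivo parameter values; the single-model sets
#' carry the values the corresponding forced-model analysis yields. fp is
#' dimensionless; D, Dstar in mm^2/s. Se0 values are representative
#' relative signal levels at the long echo times of IVIM EPI (CSF
#' brightest).
#'
#' @param set "optimal", "gaussian", "kurtosis" or "gamma".
#' @return data.frame with columns tissue, model, Se0, D, K, fp, Dstar.
#' @export
tissueParams <- function(set = c("optimal", "gaussian", "kurtosis",
                                 "gamma")) {
  set <- match.arg(set)
  mk <- function(model, D, K, fp, Dstar)
    data.frame(tissue = c("CSF", "WM", "GM"),
               model = model, Se0 = c(1200, 800, 1000),
               D = D, K = K, fp = fp, Dstar = Dstar)
  switch(set,
    optimal = mk(c("gaussian", "kurtosis", "gamma"),
                 D = c(2.9e-3, 0.79e-3, 1.05e-3), K = c(0, 0.82, 1.0),
                 fp = c(0, 0.054, 0.066), Dstar = c(NA, 5.2e-3, 6.4e-3)),
    gaussian = mk("gaussian",
                  D = c(2.91e-3, 0.58e-3, 0.72e-3), K = 0,
                  fp = c(0, 0.148, 0.172), Dstar = c(NA, 4.0e-3, 4.7e-3)),
    kurtosis = mk(c("gaussian", "kurtosis", "kurtosis"),
                  D = c(2.94e-3, 0.79e-3, 0.90e-3), K = c(0, 0.82, 0.55),
                  fp = c(0, 0.054, 0.097), Dstar = c(NA, 5.2e-3, 6.2e-3)),
    gamma = mk(c("gaussian", "gamma", "gamma"),
               D = c(3.01e-3, 0.89e-3, 1.05e-3), K = c(0, 1.55, 1.02),
               fp = c(0, 0.034, 0.066), Dstar = c(NA, 4.1e-3, 6.4e-3)))
}

#' Nested-slab region geometry
#'
#' Builds the default phantom label map: a background margin, an outer
#' white-matter slab, a gray-matter shell and a CSF core, nested in-plane
#' and constant along the slice axis. Labels: 0 background, 1 CSF, 2 WM,
#' 3 GM.
#'
#' @param dims length-3 integer grid size.
#' @param margin background border width (voxels, in-plane).
#' @param widths length-2: in-plane widths of the WM and GM shells.
#' @return integer 3D array of labels.
#' @export
nestedSlabLabels <- function(dims = c(32, 32, 8), margin = 2,
                             widths = c(5, 5)) {
  dims <- as.integer(dims)
  lab <- array(0L, dims)
  ix <- seq_len(dims[1]); iy <- seq_len(dims[2])
  # in-plane Chebyshev distance to the volume edge
  dEdge <- outer(pmin(ix - 1L, dims[1] - ix),
                 pmin(iy - 1L, dims[2] - iy), pmin)
  sl <- array(0L, dims[1:2])
  sl[dEdge >= margin] <- 2L                       # WM slab
  sl[dEdge >= margin + widths[1]] <- 3L           # GM shell
  sl[dEdge >= margin + widths[1] + widths[2]] <- 1L  # CSF core
  for (z in seq_len(dims[3])) lab[, , z] <- sl
  lab
}

#' Construct a phantom specification
#'
#' @param labels integer 3D label array (0 = background); see
#'   [nestedSlabLabels()].
#' @param regions data.frame with one row per label: columns `label`,
#'   `tissue`, `model`, `Se0`, `D`, `K`, `fp` (dimensionless), `Dstar`.
#' @param sigma Rician noise level per complex channel (signal units).
#' @param nRepeats number of repeated acquisitions to simulate.
#' @param seed RNG seed.
#' @return a [PhantomSpec-class] object.
#' @export
phantomSpec <- function(labels, regions, sigma = 0, nRepeats = 1L,
                        seed = 1L) {
  new("PhantomSpec", labels = labels, regions = regions,
      sigma = sigma, nRepeats = as.integer(nRepeats),
      seed = as.integer(seed))
}

#' Default three-tissue digital phantom
#'
#' Nested CSF/GM/WM slabs with the reference tissue parameters, emulating
#' the reference brain acquisition. `snr` sets the Rician noise level as
#' the GM b = 0 signal divided by `snr` (per complex channel); `sigma`
#' overrides it directly.
#'
#' @param dims grid size, default 32 x 32 x 8.
#' @param set which [tissueParams()] set to embed.
#' @param snr b0 signal-to-noise ratio of GM defining sigma (Inf = no
#'   noise).
#' @param sigma explicit noise level, overrides `snr`.
#' @param nRepeats repeats for number-of-averages experiments.
#' @param seed RNG seed.
#' @param margin,widths geometry, see [nestedSlabLabels()].
#' @return a [PhantomSpec-class] object.
#' @export
defaultPhantomSpec <- function(dims = c(32, 32, 8), set = "optimal",
                               snr = Inf, sigma = NULL, nRepeats = 1L,
                               seed = 1L, margin = 2, widths = c(5, 5)) {
  pars <- tissueParams(set)
  regions <- cbind(label = c(1L, 2L, 3L),
                   pars[match(c("CSF", "WM", "GM"), pars$tissue), ])
  if (is.null(sigma)) {
    gm <- regions[regions$tissue == "GM", ]
    s0 <- gm$Se0 / (1 - gm$fp)  # total S(0) = Se0 + Sv0
    sigma <- if (is.finite(snr)) s0 / snr else 0
  }
  phantomSpec(nestedSlabLabels(dims, margin, widths), regions,
              sigma = sigma, nRepeats = nRepeats, seed = seed)
}

#' Noise-free signal table per region
#' @noRd
.regionSignals <- function(regions, scheme) {
  b <- scheme@bValues
  out <- matrix(0, length(b), nrow(regions))
  for (r in seq_len(nrow(regions))) {
    p <- regions[r, ]
    Sv0 <- if (p$fp > 0) p$Se0 * p$fp / (1 - p$fp) else 0
    out[, r] <- ivimSignal(b, p$Se0, p$D, p$K, Sv0,
                           if (Sv0 > 0) p$Dstar else NA_real_,
                           model = p$model)
  }
  out
}

#' Generate a synthetic 4D IVIM series with known ground truth
#'
#' Each voxel's noise-free signal follows the two-compartment IVIM model
#' of its region; perfusion is generated isotropically (identical Sv0 and
#' D* in every MPG direction, matching the fitting assumption). Rician
#' noise is realized per volume and repeat as the magnitude
#' \eqn{\sqrt{(S + g_1)^2 + g_2^2}} with independent
#' \eqn{g_1, g_2 \sim N(0, \sigma^2)}; background voxels contain pure
#' Rayleigh noise. Fully reproducible from the spec's seed.
#'
#' @param spec a [PhantomSpec-class] object.
#' @param scheme an [AcquisitionScheme-class]; default the reference
#'   17 b-value x 6 direction protocol.
#' @return list with `repeats` (list of 4D arrays, one per repeat),
#'   `truth` (list of 3D arrays: fp in percent, dstar, md, kapp, model
#'   codes), `labels` (the label map) and `scheme`.
#' @export
generatePhantom <- function(spec, scheme = ivimScheme()) {
  lab <- spec@labels
  dims <- dim(lab)
  reg <- spec@regions
  nFrames <- length(scheme@bValues)
  clean <- .regionSignals(reg, scheme)    # frames x regions

  regIdx <- match(as.vector(lab), reg$label)  # NA for background
  nvox <- length(regIdx)
  signal <- matrix(0, nvox, nFrames)
  inReg <- !is.na(regIdx)
  signal[inReg, ] <- t(clean)[regIdx[inReg], ]

  set.seed(spec@seed)
  reps <- vector("list", spec@nRepeats)
  for (r in seq_len(spec@nRepeats)) {
    if (spec@sigma > 0) {
      g1 <- matrix(stats::rnorm(nvox * nFrames, sd = spec@sigma),
                   nvox, nFrames)
      g2 <- matrix(stats::rnorm(nvox * nFrames, sd = spec@sigma),
                   nvox, nFrames)
      m <- sqrt((signal + g1)^2 + g2^2)
    } else {
      m <- signal
    }
    reps[[r]] <- array(m, c(dims, nFrames))
  }

  toMap <- function(vals, init = NA_real_) {
    m <- array(init, dims)
    m[inReg] <- vals[regIdx[inReg]]
    m
  }
  truth <- list(
    fp = toMap(100 * reg$fp), dstar = toMap(reg$Dstar),
    md = toMap(reg$D), kapp = toMap(reg$K),
    model = {
      m <- array(0L, dims)
      m[inReg] <- modelCode(reg$model)[regIdx[inReg]]
      m
    },
    se0 = toMap(reg$Se0))
  list(repeats = reps, truth = truth, labels = lab, scheme = scheme)
}

#' Ground-truth parameter table of a phantom
#'
#' @param spec a [PhantomSpec-class] object.
#' @return data.frame with one row per region: tissue, model, Se0, D, K,
#'   fp (percent), Dstar, and the region's voxel count.
#' @export
phantomTruthTable <- function(spec) {
  reg <- spec@regions
  if (nrow(reg) == 0)
    return(data.frame(tissue = character(), model = character(),
                      Se0 = numeric(), D = numeric(), K = numeric(),
                      fp = numeric(), Dstar = numeric(),
                      nVoxels = integer()))
  data.frame(tissue = reg$tissue, model = reg$model, Se0 = reg$Se0,
             D = reg$D, K = reg$K, fp = 100 * reg$fp, Dstar = reg$Dstar,
             nVoxels = vapply(reg$label,
                              function(l) sum(spec@labels == l), 0L))
}
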