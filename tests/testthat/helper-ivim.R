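# shared fixtures: tissue rows, noiseless voxel series, Rician sampling

tissueRow <- function(tissue, set = "optimal") {
  tp <- tissueParams(set)
  tp[tp$tissue == tissue, ]
}

sv0Of <- function(p) if (p$fp > 0) p$Se0 * p$fp / (1 - p$fp) else 0

# noise-free 17 x nDir signal matrix for one tissue (isotropic)
voxelSeries <- function(p, bGrid = defaultBValues(), nDir = 6) {
  sv0 <- sv0Of(p)
  s <- ivimSignal(bGrid, p$Se0, p$D, p$K, sv0,
                  if (sv0 > 0) p$Dstar else NA_real_, model = p$model)
  matrix(rep(s, nDir), ncol = nDir)
}

riceNoise <- function(s, sigma) {
  sqrt((s + stats::rnorm(length(s), 0, sigma))^2 +
         stats::rnorm(length(s), 0, sigma)^2)
}

# small three-tissue phantom grid used across tests (200 in-mask voxels:
# 128 WM, 64 GM, 8 CSF)
smallSpec <- function(...) {
  defaultPhantomSpec(dims = c(12, 12, 2), margin = 1, widths = c(2, 2), ...)
}

relErr <- function(est, truth) {
  abs(est - truth) / pmax(abs(truth), 1e-12)
}

# NIfTI voxel data as a bare array (no RNifti attributes)
niftiArray <- function(path) {
  x <- RNifti::readNifti(path)
  array(as.vector(x), dim(x))
}
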