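bGrid <- defaultBValues()
hiIdx <- bGrid >= 600
bh <- bGrid[hiIdx]

test_that("noiseless high-b series are recovered exactly per direction", {
  s <- 1000 * attenuation(bh, 0.7e-3, model = "gaussian")
  f <- fitDiffusionDirection(bh, s, "gaussian")
  expect_lt(relErr(f$Se0, 1000), 1e-6)
  expect_lt(relErr(f$D, 0.7e-3), 1e-6)
  expect_lt(f$rss, 1e-10)
  expect_true(f$converged)

  s <- 800 * attenuation(bh, 0.8e-3, K = 0.8, model = "kurtosis")
  f <- fitDiffusionDirection(bh, s, "kurtosis")
  expect_lt(relErr(f$D, 0.8e-3), 1e-6)
  expect_lt(relErr(f$K, 0.8), 1e-6)
})

test_that("the generating model attains the smallest cAIC on clean data", {
  s <- 1000 * attenuation(bh, 1.0e-3, K = 1.0, model = "gamma")
  fits <- lapply(c(gaussian = "gaussian", kurtosis = "kurtosis",
                   gamma = "gamma"),
                 function(m) fitDiffusionDirection(bh, s, m))
  caics <- vapply(fits, `[[`, 0, "caic")
  expect_identical(names(which.min(caics)), "gamma")
  # extra parameter can only decrease the optimal RSS (nested models)
  expect_lt(fits$kurtosis$rss, fits$gaussian$rss)
  expect_lt(fits$gamma$rss, fits$gaussian$rss)

  sk <- 800 * attenuation(bh, 0.8e-3, K = 0.8, model = "kurtosis")
  rssG <- fitDiffusionDirection(bh, sk, "gaussian")$rss
  rssK <- fitDiffusionDirection(bh, sk, "kurtosis")$rss
  expect_lt(rssK, rssG)
})

test_that("selection takes the minimal mean cAIC with parsimony ties", {
  m <- cbind(gaussian = rep(150.7, 6), kurtosis = rep(138.8, 6),
             gamma = rep(134.6, 6))
  expect_identical(selectOptimalModel(m), "gamma")
  tie <- cbind(gaussian = rep(1, 6), kurtosis = rep(1, 6),
               gamma = rep(1, 6))
  expect_identical(selectOptimalModel(tie), "gaussian")
  # one non-converged direction excludes the candidate entirely
  m2 <- m
  m2[3, "gamma"] <- Inf
  expect_identical(selectOptimalModel(m2), "kurtosis")
  allBad <- m
  allBad[] <- Inf
  expect_identical(selectOptimalModel(allBad), NA_character_)
})

test_that("perfusion residuals isolate the intravascular component", {
  # pure diffusion: residuals vanish at every b
  p <- tissueRow("CSF")
  sig <- voxelSeries(p)
  fits <- lapply(1:6, function(i)
    fitDiffusionDirection(bh, sig[hiIdx, i], "gaussian"))
  res <- extractPerfusionSeries(bGrid, sig, fits)
  expect_lt(max(abs(res)), 1e-6)

  # two-compartment voxel: residual(0) ~ Sv0, decaying with Dstar
  gm <- tissueRow("GM")
  sv0 <- sv0Of(gm)
  sig <- voxelSeries(gm)
  # diffusion fits taken at the known truth so the residual is exact
  truthFit <- list(model = "gamma", Se0 = gm$Se0, D = gm$D, K = gm$K)
  res <- extractPerfusionSeries(bGrid, sig, rep(list(truthFit), 6))
  expect_equal(res[1, 1], sv0, tolerance = 1e-9)
  expect_equal(res[, 1], sv0 * exp(-bGrid * gm$Dstar), tolerance = 1e-9)
  expect_lt(abs(res[length(bGrid), 1]), 1e-6 * sv0)
})

test_that("the joint perfusion fit recovers (Sv0, Dstar) across directions", {
  res0 <- matrix(0, length(bGrid), 6)
  pf <- fitPerfusion(bGrid, res0)
  expect_equal(pf$Sv0, 0)
  expect_true(pf$allNegative)

  res <- matrix(rep(100 * exp(-bGrid * 10e-3), 6), ncol = 6)
  pf <- fitPerfusion(bGrid, res, scale = 900, s0Max = 1000)
  expect_lt(relErr(pf$Sv0, 100), 1e-6)
  expect_lt(relErr(pf$Dstar, 10e-3), 1e-6)
  expect_true(pf$converged)
})

test_that("fitVoxel recovers noiseless voxels of every tissue class", {
  for (tissue in c("CSF", "WM", "GM")) {
    p <- tissueRow(tissue)
    rec <- fitVoxel(bGrid, voxelSeries(p))
    expect_identical(selectedModel(rec), p$model)
    pars <- voxelParams(rec)
    expect_lt(relErr(pars["md"], p$D), 1e-4)
    expect_lt(relErr(pars["se0Mean"], p$Se0), 1e-4)
    if (p$K > 0) expect_lt(relErr(pars["kapp"], p$K), 1e-4)
    if (p$fp > 0) {
      expect_lt(relErr(pars["fp"], p$fp), 1e-4)
      expect_lt(relErr(pars["dstar"], p$Dstar), 1e-4)
    } else {
      expect_equal(unname(pars["fp"]), 0)
    }
  }
})

test_that("gaussian-selected voxels report zero apparent kurtosis", {
  rec <- fitVoxel(bGrid, voxelSeries(tissueRow("CSF")))
  expect_identical(selectedModel(rec), "gaussian")
  expect_identical(unname(voxelParams(rec)["kapp"]), 0)
})

test_that("forcing the generating model equals optimal-mode output", {
  sig <- voxelSeries(tissueRow("CSF"))
  opt <- fitVoxel(bGrid, sig, mode = "optimal")
  forced <- fitVoxel(bGrid, sig, mode = "gaussian")
  expect_identical(selectedModel(opt), "gaussian")
  expect_equal(voxelParams(forced), voxelParams(opt), tolerance = 1e-12)
})

test_that("all-zero voxels and short windows are rejected", {
  expect_error(fitVoxel(bGrid, matrix(0, 17, 6)), "all-zero")
  expect_error(fitDiffusionDirection(bh[1:3], rep(1, 3), "gaussian"),
               "at least 5")
  expect_error(fitDiffusionDirection(bh, rep(0, length(bh)), "gaussian"),
               "all-zero")
})

test_that("rescaling noisy signals preserves the analysis to float precision", {
  # on noisy data the independent per-element rounding of the rescaled
  # input is amplified through the iterated fit, so agreement is to the
  # propagated float precision rather than the exact-arithmetic identity
  # (which the noise-free suite checks at 1e-8)
  set.seed(23)
  gm <- tissueRow("GM")
  sig <- voxelSeries(gm)
  sig[] <- riceNoise(sig, 4)
  base <- fitVoxel(bGrid, sig)
  for (alpha in c(10, 1 / 1000)) {
    scaled <- fitVoxel(bGrid, sig * alpha)
    expect_identical(selectedModel(scaled), selectedModel(base))
    pb <- voxelParams(base)
    ps <- voxelParams(scaled)
    for (nm in c("md", "kapp", "fp", "dstar"))
      expect_lt(relErr(ps[nm], pb[nm]), 1e-5)
    expect_lt(relErr(ps["se0Mean"], alpha * pb["se0Mean"]), 1e-5)
    fb <- diffusionFits(base)
    fs <- diffusionFits(scaled)
    expect_lt(max(abs((fs$caic - fb$caic) -
                        caicScaleShift(fb$n, alpha))), 1e-4)
  }
})
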