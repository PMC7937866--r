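test_that("noise-free phantom signals equal the forward model exactly", {
  sch <- ivimScheme()
  spec <- smallSpec()
  ph <- generatePhantom(spec, sch)
  vol <- ph$repeats[[1]]
  lay <- seriesLayout(sch)
  for (lab in 1:3) {
    p <- spec@regions[spec@regions$label == lab, ]
    v <- which(ph$labels == lab)[1]
    got <- matrix(vol, prod(dim(ph$labels)))[v, ]
    sv0 <- if (p$fp > 0) p$Se0 * p$fp / (1 - p$fp) else 0
    want <- ivimSignal(bValues(sch), p$Se0, p$D, p$K, sv0,
                       if (sv0 > 0) p$Dstar else NA_real_, model = p$model)
    expect_equal(got, want, tolerance = 1e-12)
    if (p$fp == 0)  # zero perfusion: pure extravascular decay
      expect_equal(got, p$Se0 * attenuation(bValues(sch), p$D, p$K,
                                            model = p$model),
                   tolerance = 1e-12)
  }
  expect_true(all(vol[rep(ph$labels == 0, length(bValues(sch)))] == 0))
})

test_that("phantom noise is Rician with the requested sigma", {
  # single-frame scheme keeps the background sample cheap but large
  sch <- ivimScheme(bGrid = 0, directions = cbind(c(1, 0, 0)))
  labels <- array(0L, c(350, 350, 1))
  regions <- tissueParams("optimal")[0, ]
  regions$label <- integer(0)
  spec <- phantomSpec(labels, regions, sigma = 10, seed = 7)
  ph <- generatePhantom(spec, sch)
  x <- as.vector(ph$repeats[[1]])
  # Rayleigh mean sigma * sqrt(pi/2) on signal-free voxels
  expect_lt(abs(mean(x) - 10 * sqrt(pi / 2)) / (10 * sqrt(pi / 2)), 0.02)
  # squared histogram mode tracks sigma^2
  nm <- estimateNCF(ph$repeats[[1]])
  expect_lt(abs(ncf(nm) - 100) / 100, 0.10)
})

test_that("phantom generation is reproducible from the seed", {
  sch <- ivimScheme()
  a <- generatePhantom(smallSpec(snr = 50, seed = 99, nRepeats = 2), sch)
  b <- generatePhantom(smallSpec(snr = 50, seed = 99, nRepeats = 2), sch)
  expect_identical(a$repeats, b$repeats)
  expect_false(identical(a$repeats[[1]], a$repeats[[2]]))
  c1 <- generatePhantom(smallSpec(snr = 50, seed = 100), sch)
  expect_false(identical(a$repeats[[1]], c1$repeats[[1]]))
})

test_that("truth tables carry the seeded tissue parameters", {
  tab <- phantomTruthTable(smallSpec())
  expect_equal(tab$fp[tab$tissue == "GM"], 6.6)
  expect_equal(tab$Dstar[tab$tissue == "WM"], 5.2e-3)
  expect_identical(tab$model[tab$tissue == "CSF"], "gaussian")
  expect_true(all(tab$nVoxels > 0))

  noRegions <- cbind(label = integer(0), tissueParams()[0, ])
  empty <- phantomSpec(array(0L, c(4, 4, 1)), noRegions)
  expect_identical(nrow(phantomTruthTable(empty)), 0L)
})

test_that("phantom geometry nests CSF inside GM inside WM", {
  lab <- nestedSlabLabels(c(32, 32, 8), margin = 2, widths = c(5, 5))
  expect_identical(dim(lab), c(32L, 32L, 8L))
  expect_setequal(unique(as.vector(lab)), c(0L, 1L, 2L, 3L))
  # walking inward from the edge crosses background, WM, GM, then CSF
  z <- lab[, , 1]
  expect_identical(z[1, 16], 0L)    # margin
  expect_identical(z[4, 16], 2L)    # WM slab
  expect_identical(z[9, 16], 3L)    # GM shell
  expect_identical(z[16, 16], 1L)   # CSF core
  expect_error(phantomSpec(lab, cbind(label = integer(0),
                                      tissueParams()[0, ])), "regions")
})
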