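test_that("volume fitting reproduces the generating label map at sigma = 0", {
  sch <- ivimScheme()
  spec <- smallSpec()
  ph <- generatePhantom(spec, sch)
  maps <- fitVolume(ph$repeats[[1]], sch, mask = ph$labels > 0)
  expect_identical(parameterMap(maps, "model"), ph$truth$model)
  expect_true(all(parameterMap(maps, "model")[ph$labels == 0] == 0L))
  # background voxels carry no parameters
  expect_true(all(is.na(parameterMap(maps, "fp")[ph$labels == 0])))

  # forced single-model mode labels every fitted voxel with that model
  g <- fitVolume(ph$repeats[[1]], sch, mask = ph$labels > 0,
                 mode = "gaussian")
  expect_true(all(parameterMap(g, "model")[ph$labels > 0] == 1L))

  expect_warning(
    e <- fitVolume(ph$repeats[[1]], sch,
                   mask = array(FALSE, dim(ph$labels))),
    "empty mask")
  expect_true(all(parameterMap(e, "model") == 0L))
})

test_that("volume/scheme mismatches are rejected", {
  sch <- ivimScheme()
  expect_error(fitVolume(array(1, c(4, 4, 2, 10)), sch), "scheme")
  expect_error(fitVolume(array(1, c(4, 4, 2)), sch), "4D")
})

test_that("averaging repeats is the voxelwise mean with 1/sqrt(N) noise", {
  v1 <- array(stats::runif(4 * 4 * 2 * 6), c(4, 4, 2, 6))
  expect_identical(averageRepeats(list(v1), 1), v1)
  expect_equal(averageRepeats(list(v1, v1), 2), v1)
  expect_error(averageRepeats(list(v1, array(0, c(2, 2, 2, 6)))),
               "shapes differ")
  expect_error(averageRepeats(list(v1), 2), "nAvg")

  set.seed(31)
  reps <- lapply(1:4, function(i)
    array(riceNoise(rep(0, 40^3), 10), c(40, 40, 40, 1)))
  sd1 <- stats::sd(averageRepeats(reps, 1))
  sd4 <- stats::sd(averageRepeats(reps, 4))
  expect_equal(sd4 / sd1, 1 / sqrt(4), tolerance = 0.05)
})

test_that("model territory counts percentages over a region", {
  mm <- array(c(rep(1L, 3), rep(2L, 3), rep(3L, 4)), c(10, 1, 1))
  msk <- array(TRUE, c(10, 1, 1))
  t <- modelTerritory(mm, msk)
  expect_equal(unname(t), c(30, 30, 40))
  expect_equal(sum(t), 100)
  uni <- array(2L, c(5, 1, 1))
  expect_equal(unname(modelTerritory(uni, array(TRUE, c(5, 1, 1)))),
               c(0, 100, 0))
  expect_error(modelTerritory(mm, array(FALSE, c(10, 1, 1))), "empty")
})

test_that("territory change counts differing optimal models", {
  a <- array(sample(1:3, 24, replace = TRUE), c(4, 3, 2))
  expect_equal(territoryChange(a, a), 0)
  b <- a %% 3L + 1L  # every label shifted
  expect_equal(territoryChange(a, b), 100)
  b2 <- a
  b2[1:6] <- a[1:6] %% 3L + 1L
  expect_equal(territoryChange(a, b2), 100 * 6 / 24)
  expect_error(territoryChange(a, array(1L, c(2, 2, 2))), "shapes")
})

test_that("model selection stabilizes as averages accumulate", {
  # number-of-averages analogue: territory change relative to the
  # highest-SNR analysis declines as more repeats are averaged
  sch <- ivimScheme()
  spec <- defaultPhantomSpec(dims = c(14, 14, 2), margin = 1,
                             widths = c(3, 4), snr = 100, nRepeats = 6,
                             seed = 7)
  ph <- generatePhantom(spec, sch)
  mask <- ph$labels > 0
  fit1 <- function(n) {
    avg <- averageRepeats(ph$repeats, n)
    nm <- estimateNCF(avg[, , , 1, drop = TRUE], mask = ph$labels == 0)
    parameterMap(fitVolume(avg, sch, mask = mask, noise = nm), "model")
  }
  m1 <- fit1(1); m3 <- fit1(3); m6 <- fit1(6)
  ch1 <- territoryChange(m1, m6, mask)
  ch3 <- territoryChange(m3, m6, mask)
  expect_gt(ch1, 0)
  expect_lte(ch3, ch1)
  # and agreement with the generating labels does not degrade
  acc1 <- mean(m1[mask] == ph$truth$model[mask])
  acc6 <- mean(m6[mask] == ph$truth$model[mask])
  expect_gte(acc6, acc1)
})
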