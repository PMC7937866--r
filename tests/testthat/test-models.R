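test_that("attenuation matches the closed forms of the three models", {
  for (m in c("gaussian", "kurtosis", "gamma"))
    expect_equal(attenuation(0, D = 1e-3, K = 1, model = m), 1)
  expect_equal(attenuation(1000, D = 1e-3, model = "gaussian"), exp(-1))
  expect_equal(attenuation(600, D = 1e-3, K = 1, model = "kurtosis"),
               exp(-0.54))
  expect_equal(attenuation(600, D = 1e-3, K = 1, model = "gamma"),
               1.2^(-3))
  expect_error(attenuation(-10, D = 1e-3), "b-values")
  expect_error(attenuation(100, D = 0), "D must")
  expect_error(attenuation(100, D = 1e-3, K = -1), "K must")
})

test_that("kurtosis and gamma reduce to the gaussian model as K -> 0", {
  bGrid <- seq(0, 2500, by = 100)
  for (D in c(0.5e-3, 1e-3, 3e-3)) {
    eg <- attenuation(bGrid, D, model = "gaussian")
    for (m in c("kurtosis", "gamma")) {
      expect_equal(attenuation(bGrid, D, K = 0, model = m), eg,
                   tolerance = 1e-12)
      expect_lt(max(abs(attenuation(bGrid, D, K = 1e-6, model = m) - eg)),
                1e-5)
    }
  }
  # continuity across the small-K series branch of the gamma form
  e1 <- attenuation(2500, 1e-3, K = 1e-5 * (1 - 1e-9), model = "gamma")
  e2 <- attenuation(2500, 1e-3, K = 1e-5 * (1 + 1e-9), model = "gamma")
  expect_equal(e1, e2, tolerance = 1e-10)
})

test_that("kurtosis and gamma agree to <1% at b = 600 with DK = 1e-3", {
  ek <- attenuation(600, 1e-3, K = 1, model = "kurtosis")
  eg <- attenuation(600, 1e-3, K = 1, model = "gamma")
  expect_lt(abs(eg - ek) / ek, 0.01)
})

test_that("ivim signal is the two-compartment sum with S(0) = Se0 + Sv0", {
  expect_equal(ivimSignal(0, Se0 = 900, D = 1e-3, Sv0 = 100,
                          Dstar = 10e-3), 1000)
  expect_equal(ivimSignal(800, Se0 = 900, D = 1e-3, Sv0 = 0),
               900 * exp(-0.8))
  expect_equal(
    ivimSignal(1000, Se0 = 900, D = 1e-3, Sv0 = 100, Dstar = 10e-3,
               model = "gaussian"),
    900 * exp(-1) + 100 * exp(-10))
  # strictly decreasing within validity when Dstar > D
  s <- ivimSignal(seq(0, 2500, 50), 900, 1e-3, K = 0.8, Sv0 = 100,
                  Dstar = 10e-3, model = "kurtosis")
  expect_true(all(diff(s) < 0))
})

test_that("perfusion fraction follows Sv0 / (Sv0 + Se0)", {
  expect_equal(perfusionFraction(0, 900), 0)
  expect_equal(perfusionFraction(100, 900), 0.10)
  expect_equal(perfusionFraction(42, 42), 0.5)
  expect_error(perfusionFraction(0, 0), "positive")
})

test_that("caic matches its definition and rejects degenerate input", {
  expect_equal(caic(11, 2, 11), 5.5)
  expect_equal(caic(11, 3, 11), 6 + 24 / 7)
  expect_error(caic(4, 3, 1), "n > P")
  expect_error(caic(11, 2, 0), "rss")
})

test_that("caic shifts by 2n log(alpha) under data rescaling", {
  set.seed(1)
  for (i in 1:20) {
    n <- sample(6:30, 1)
    P <- sample(2:4, 1)
    rss <- stats::runif(1, 1e-6, 1e3)
    a <- stats::runif(1, 1e-4, 1e3)
    expect_equal(caic(n, P, a^2 * rss) - caic(n, P, rss),
                 caicScaleShift(n, a), tolerance = 1e-12)
  }
})

test_that("equal-cAIC RSS ratio agrees with a numerical root solve", {
  # independent oracle: solve caic(n, p, r) = caic(n, pRef, 1) for r
  oracle <- function(n, p, pRef = 2) {
    100 * stats::uniroot(function(r) caic(n, p, r) - caic(n, pRef, 1),
                         c(1e-8, 1), tol = 1e-14)$root
  }
  expect_equal(equalCaicRssRatio(11, 3), oracle(11, 3), tolerance = 1e-8)
  expect_equal(equalCaicRssRatio(11, 4), oracle(11, 4), tolerance = 1e-8)
  expect_equal(equalCaicRssRatio(17, 3), oracle(17, 3), tolerance = 1e-8)
})

test_that("gamma-distribution parameters are the algebraic (D, K) map", {
  g <- kurtosisToGamma(1e-3, 1)
  expect_equal(g$alpha, 3)
  expect_equal(g$beta, 3000)
  g <- kurtosisToGamma(1e-3, 3)
  expect_equal(g$alpha, 1)
  expect_equal(g$beta, 1000)
  # round trip through the distribution's mean and variance
  for (D in c(0.7e-3, 2.9e-3)) for (K in c(0.3, 1.5)) {
    g <- kurtosisToGamma(D, K)
    back <- gammaToKurtosis(g$alpha, g$beta)
    expect_equal(back$D, D, tolerance = 1e-12)
    expect_equal(back$K, K, tolerance = 1e-12)
  }
  expect_error(kurtosisToGamma(1e-3, 0), "K")
})

test_that("validity bounds reproduce the 3/(DK) and 27/(6DK) limits", {
  expect_equal(unname(validityBounds(1e-3, 0.5)["kurtosis"]), 6000)
  expect_equal(unname(validityBounds(1e-3, 0.65)["kurtosis"]), 3 / 0.65e-3)
  expect_equal(unname(validityBounds(1e-3, 1.38)["gamma"]),
               27 / (6 * 1.38e-3))
  b0 <- validityBounds(1e-3, 0)
  expect_true(all(is.infinite(b0)))
})

test_that("model codes are stable and invertible", {
  expect_identical(modelCode(c("gaussian", "kurtosis", "gamma")), 1:3)
  expect_identical(modelName(c(0L, 3L)), c("none", "gamma"))
  expect_error(modelCode("biexponential"), "unknown")
})
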