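test_that("the odds-quantile parameterization maps to the logit-normal SD", {
  expect_equal(sigmaFromOddsQuantile(1.2, 0.90), log(1.2) / qnorm(0.9))
  expect_equal(sigmaFromOddsQuantile(1.2, 0.90), 0.14226, tolerance = 1e-4)
  expect_identical(sigmaFromOddsQuantile(1), 0)
  expect_error(sigmaFromOddsQuantile(0.8), "at least 1",
               class = "crcValidationError")

  # sampled check: the q-th quantile of the odds multiplier exp(eps) is r
  set.seed(20)
  sh <- sigmaFromOddsQuantile(1.2, 0.90)
  q90 <- quantile(exp(rnorm(1e6, 0, sh)), 0.9, names = FALSE)
  expect_lt(abs(q90 - 1.2) / 1.2, 0.005)
})

test_that("intercept calibration hits the target capture fractions", {
  expect_equal(calibrateEventIntercepts(1000, 500, sigma = 0), 0)
  mu <- calibrateEventIntercepts(10000, 2205, sigma = 0.5)
  gh <- crcsize:::ghNormal(20)
  achieved <- sum(gh$w * plogis(mu + 0.5 * gh$x))
  expect_equal(achieved, 0.2205, tolerance = 1e-6)

  mus <- calibrateEventIntercepts(10000, c(1000, 2000, 4000), sigma = 0.3)
  expect_true(all(diff(mus) > 0))   # larger targets need larger intercepts
  expect_error(calibrateEventIntercepts(100, 150), "0 < n_j < N",
               class = "crcValidationError")
})

test_that("simulated studies have the configured expected event totals", {
  # certain capture: everyone shows the all-ones history
  all1 <- simulateStudy(50, probs = rep(1 - 1e-12, 3), seed = 1)
  expect_identical(unname(historyCounts(all1)["111"]), 50L)
  expect_identical(totalObserved(all1), 50L)

  # determinism
  expect_identical(
    historyCounts(simulateStudy(500, nj = c(150, 120, 100), sigma = 0.3,
                                seed = 5)),
    historyCounts(simulateStudy(500, nj = c(150, 120, 100), sigma = 0.3,
                                seed = 5)))

  # mean realized totals across replicates sit within 3 SE of the targets
  set.seed(33)
  R <- 200
  N <- 800
  nj <- c(240, 160, 200)
  tot <- matrix(NA_real_, R, 3)
  for (r in 1:R) {
    tot[r, ] <- descriptiveStats(
      simulateStudy(N, nj = nj, sigma = 0.4))@nj
  }
  se <- sqrt(nj * (1 - nj / N) / R)
  expect_true(all(abs(colMeans(tot) - nj) < 3 * se))
})

test_that("precision tables are monotone and handle degenerate runs", {
  pt <- precisionSimulation(1000, c(300, 300, 300), replicates = 150,
                            seed = 17)
  expect_false(is.unsorted(pt@withinFraction))
  expect_false(is.unsorted(pt@errorQuantiles))
  expect_identical(pt@config$estimator, "Mt")   # homogeneous -> Mt
  expect_gte(pt@withinFraction[4], pt@withinFraction[2])  # 10% vs 5%

  one <- precisionSimulation(1000, c(300, 300, 300), replicates = 1, seed = 3)
  expect_true(all(one@withinFraction %in% c(0, 1)))
  expect_length(one@estimates, 1L)
})

test_that("heterogeneous designs default to the Mth-normal estimator", {
  pt <- precisionSimulation(2000, c(500, 450, 400), oddsRatio = 1.2,
                            replicates = 5, seed = 2)
  expect_identical(pt@config$estimator, "MthNormal")
  expect_equal(pt@config$sigma, sigmaFromOddsQuantile(1.2, 0.9))
})

test_that("the Mt estimator is approximately unbiased on homogeneous designs", {
  pt <- precisionSimulation(1000, rep(300, 3), replicates = 500, seed = 41)
  medBias <- abs(median(pt@estimates) - 1000) / 1000
  expect_lt(medBias, 0.02)
})

test_that("larger samples do not worsen the median relative error", {
  med <- function(nj, seed) {
    pt <- precisionSimulation(1000, nj, replicates = 120, seed = seed)
    pt@errorQuantiles["q50"]
  }
  worse <- 0L
  for (s in 1:3) {
    small <- med(rep(150, 3), seed = 60 + s)
    large <- med(rep(350, 3), seed = 60 + s)
    worse <- worse + (large > small)
  }
  expect_lte(worse, 1L)   # statistical tendency, allow one reversal
})
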