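# Independent closed forms used as oracles.
petersen <- function(tab) {
  d <- descriptiveStats(tab)
  m <- historyCounts(tab)[["11"]]
  d@nj[1] * d@nj[2] / m
}

# Brute-force grid search over N of the multinomial profile likelihood in its
# continuous-N (Stirling-coefficient) form, the estimand targeted by the
# log-linear unobserved-cell extrapolation. `exact = TRUE` keeps the exact
# lgamma coefficient, giving the unconditional multinomial MLE, which is
# known to sit O(1) below the conditional/Poisson estimate.
bruteForceN <- function(tab, model, exact = FALSE) {
  d <- descriptiveStats(tab)
  n <- d@n; k <- d@k; nj <- d@nj
  P <- historyPatterns(tab); x <- historyCounts(tab)
  prof <- function(N) {
    pj <- if (model == "Mt") nj / N else rep(sum(nj) / (k * N), k)
    lp <- as.vector(P %*% log(pj) + (1 - P) %*% log1p(-pj))
    co <- if (exact) lgamma(N + 1) - lgamma(N - n + 1)
          else N * log(N) - N - ((N - n) * log(N - n) - (N - n))
    co + (N - n) * sum(log1p(-pj)) + sum(x * lp)
  }
  grid <- seq(n + 0.5, 10 * n, by = 0.1)
  grid[which.max(vapply(grid, prof, numeric(1)))]
}

test_that("design matrices carry the documented columns", {
  X <- buildDesignMatrix("M0", k = 3)
  expect_identical(dim(X), c(7L, 2L))
  expect_identical(unname(X[, 2]), c(1, 1, 1, 2, 2, 2, 3))

  Xt <- buildDesignMatrix("Mt", k = 2)
  expect_identical(dim(Xt), c(3L, 3L))
  expect_identical(unname(Xt[c("10", "01", "11"), c("e1", "e2")]),
                   rbind(c(1, 0), c(0, 1), c(1, 1)))

  Xd <- buildDesignMatrix("Mth", "darroch", k = 3)
  caps <- rowSums(crcsize:::patternMatrix(3))
  expect_equal(unname(Xd[, "g.darroch"]), caps^2 / 2)
  expect_setequal(unique(Xd[, "g.darroch"]), c(0.5, 2, 4.5))

  Xp <- buildDesignMatrix("Mh", "poisson2", k = 4)
  expect_equal(unname(Xp[, "g.poisson2"]), 2^rowSums(crcsize:::patternMatrix(4)) - 1)

  expect_error(buildDesignMatrix("Mh", "cauchy", k = 3), "variant",
               class = "crcValidationError")
})

test_that("Mt with two lists reproduces the Petersen estimator exactly", {
  t2 <- suppressWarnings(
    CaptureHistoryTable(c("11" = 20, "10" = 80, "01" = 30)))
  expect_equal(popEstimate(fitLogLinear(t2, "Mt")), 250)

  sym <- suppressWarnings(
    CaptureHistoryTable(c("11" = 25, "10" = 25, "01" = 25)))
  expect_equal(popEstimate(fitLogLinear(sym, "M0")), 100)

  set.seed(19)
  for (i in 1:20) {
    cnt <- rpois(3, c(30, 25, 12)) + 1L
    tab <- suppressWarnings(CaptureHistoryTable(cnt, c("10", "01", "11")))
    expect_equal(popEstimate(fitLogLinear(tab, "Mt")), petersen(tab),
                 tolerance = 1e-8)
  }
})

test_that("no overlap makes the extrapolation unbounded, with a clear error", {
  t0 <- suppressWarnings(CaptureHistoryTable(c("10" = 50, "01" = 50)))
  expect_error(fitLogLinear(t0, "Mt"), "unbounded",
               class = "crcValidationError")
})

test_that("GLM estimates agree with brute-force likelihood grid search on toy tables", {
  set.seed(3)
  for (i in 1:5) {
    cnt <- rpois(7, c(8, 6, 7, 5, 4, 3, 2)) + c(rep(0L, 6), 1L)
    tab <- suppressWarnings(CaptureHistoryTable(
      cnt, c("100", "010", "001", "110", "101", "011", "111")))
    for (m in c("M0", "Mt")) {
      g <- popEstimate(fitLogLinear(tab, m))
      expect_equal(g, bruteForceN(tab, m), tolerance = 0.5 / g)
      # the exact unconditional multinomial MLE sits a little below
      exactN <- bruteForceN(tab, m, exact = TRUE)
      expect_lt(abs(g - exactN), 2)
      expect_gt(g, exactN)
    }
  }
})

test_that("Chao bound matches its closed forms, including the f2 = 0 correction", {
  # f1 = 110, f2 = 0: bias-corrected 120 + 110*109/2 = 6115
  expect_equal(popEstimate(chaoLowerBound(workedHistoryTable())), 6115)

  # f1 = 10, f2 = 5, n = 100: 100 + 100/10 = 110
  cnt <- c("100" = 4, "010" = 3, "001" = 3, "110" = 2, "101" = 2,
           "011" = 1, "111" = 85)
  tab <- CaptureHistoryTable(cnt)
  d <- descriptiveStats(tab)
  expect_identical(d@fi[1:2], c(10L, 5L))
  expect_identical(d@n, 100L)
  fit <- chaoLowerBound(tab)
  expect_equal(popEstimate(fit), 110)
  expect_true(fit@isLowerBound)
  r <- 10 / 5
  expect_equal(fit@se, sqrt(5 * (r^4 / 4 + r^3 + r^2 / 2)))

  # f1 = 0: bound collapses to n with a warning
  full <- suppressWarnings(CaptureHistoryTable(c("111" = 9, "110" = 4), k = 3))
  expect_warning(f0 <- chaoLowerBound(full), "f1 = 0|recaptured")
  expect_equal(popEstimate(f0), totalObserved(full))
  expect_equal(unname(confInt(f0)), rep(totalObserved(full), 2))
})

test_that("the log-linear Chao variant reproduces the closed-form bound", {
  set.seed(13)
  for (i in 1:10) {
    tab <- randomHistoryTable(3)
    closed <- popEstimate(chaoLowerBound(tab))
    glmFit <- popEstimate(fitLogLinear(tab, "Mh", "chao"))
    expect_lt(abs(closed - glmFit), 0.5)
  }
  tab4 <- randomHistoryTable(4)
  expect_lt(abs(popEstimate(chaoLowerBound(tab4)) -
                popEstimate(fitLogLinear(tab4, "Mh", "chao"))), 0.5)
})

test_that("model comparison obeys the identifiability rule and the N >= n invariant", {
  t2 <- suppressWarnings(
    CaptureHistoryTable(c("11" = 20, "10" = 80, "01" = 30)))
  d2 <- modelComparison(t2)
  expect_setequal(d2$model, c("M0", "Mt"))

  d3 <- modelComparison(indepTable())
  expect_identical(nrow(d3), 12L)  # M0, Mt, and 5 variants each of Mh/Mth
  ok <- !is.na(d3$Nhat)
  expect_true(all(d3$Nhat[ok] >= totalObserved(indepTable())))
  expect_false(is.unsorted(d3$aic[!is.na(d3$aic)]))
})

test_that("Mt attains the lowest mean AIC on data generated under Mt", {
  set.seed(101)
  R <- 300
  aics <- matrix(NA_real_, R, 2, dimnames = list(NULL, c("M0", "Mt")))
  for (r in 1:R) {
    tab <- simulateStudy(2000, probs = c(0.2, 0.3, 0.25))
    aics[r, "M0"] <- fitLogLinear(tab, "M0")@aic
    aics[r, "Mt"] <- fitLogLinear(tab, "Mt")@aic
  }
  expect_lt(mean(aics[, "Mt"]), mean(aics[, "M0"]))
})

test_that("M0 recovery: median relative bias below 2% on M0-simulated data", {
  set.seed(55)
  R <- 500
  est <- vapply(seq_len(R), function(r) {
    popEstimate(fitLogLinear(simulateStudy(1000, probs = rep(0.3, 3)), "M0"))
  }, numeric(1))
  expect_lt(abs(median(est) - 1000) / 1000, 0.02)
})

test_that("Darroch and Gamma corrections exceed Poisson2 on heterogeneous data", {
  set.seed(77)
  R <- 50
  wins <- matrix(NA, R, 2)
  for (r in 1:R) {
    tab <- simulateStudy(2000, probs = rep(0.25, 3), sigma = 1)
    p2 <- popEstimate(fitLogLinear(tab, "Mh", "poisson2"))
    wins[r, 1] <- popEstimate(fitLogLinear(tab, "Mh", "darroch")) >= p2
    wins[r, 2] <- popEstimate(fitLogLinear(tab, "Mh", "gamma3.5")) >= p2
  }
  expect_gte(mean(wins[, 1]), 0.9)
  expect_gte(mean(wins[, 2]), 0.9)
})

test_that("the Mth-normal conditional fit recovers heterogeneous populations", {
  set.seed(8)
  tab <- simulateStudy(5000, nj = c(1500, 1200, 1000), sigma = 0.8)
  fit <- fitLogLinear(tab, "Mth", "normal")
  expect_gt(fit@sigmah, 0.2)            # heterogeneity detected
  expect_gt(fit@Nhat, totalObserved(tab))
  expect_true(fit@ci[1] <= fit@Nhat && fit@Nhat <= fit@ci[2])
  # the normal model nests Mt: its conditional fit can only improve on the
  # sigma = 0 submodel, and on homogeneous data it stays near the Mt estimate
  hom <- simulateStudy(2000, probs = rep(0.3, 3))
  fn <- fitLogLinear(hom, "Mth", "normal")
  mt <- fitLogLinear(hom, "Mt")
  expect_gte(fn@loglik, mt@loglik - 1e-6)
  expect_gte(fn@Nhat, mt@Nhat - 1)       # extra mixing mass only adds escape
  expect_lt(abs(fn@Nhat - 2000) / 2000, 0.2)
})

test_that("heterogeneity fits are refused at k = 2", {
  t2 <- suppressWarnings(
    CaptureHistoryTable(c("11" = 20, "10" = 80, "01" = 30)))
  expect_error(fitLogLinear(t2, "Mh", "poisson2"), "unidentifiable",
               class = "crcValidationError")
})

test_that("profile-likelihood interval brackets the Wald interval sensibly", {
  tab <- indepTable()
  wald <- fitLogLinear(tab, "Mt")
  prof <- fitLogLinear(tab, "Mt", profileCI = TRUE)
  expect_equal(wald@Nhat, prof@Nhat)
  expect_lt(prof@ci[1], prof@Nhat)
  expect_gt(prof@ci[2], prof@Nhat)
  expect_lt(abs(prof@ci[1] - wald@ci[1]) / wald@Nhat, 0.1)
})

test_that("pairwise Chapman diagnostics match the closed forms", {
  # n_a = 100, n_b = 50, m = 20 -> 101*51/21 - 1
  tab <- suppressWarnings(CaptureHistoryTable(
    c("110" = 20, "100" = 80, "010" = 30, "001" = 5)))
  pw <- pairwiseAnalysis(tab)
  expect_identical(rownames(pw), c("pa12", "pa13", "pa23"))
  r12 <- pw["pa12", ]
  expect_identical(c(r12$nA, r12$nB, r12$m), c(100L, 50L, 20L))
  expect_equal(r12$Nhat, 101 * 51 / 21 - 1)
  expect_equal(r12$se,
               sqrt(101 * 51 * 80 * 30 / (21^2 * 22)))
  expect_gte(r12$ciLo, r12$nA + r12$nB - r12$m)

  # perfect overlap: Chapman gives exactly the common count
  po <- suppressWarnings(CaptureHistoryTable(c("11" = 50)))
  expect_equal(pairwiseAnalysis(po)["pa12", "Nhat"], 50)

  # no overlap is flagged rather than failing
  no <- suppressWarnings(CaptureHistoryTable(c("10" = 5, "01" = 5)))
  expect_match(pairwiseAnalysis(no)["pa12", "note"], "no overlap")
})
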