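# Independent hyper-Dirichlet marginal likelihood oracle: explicit margin
# tables built from pattern strings, plain lgamma sums, no shared code with
# the package internals.
oracleLML <- function(model, tab, N, delta) {
  k <- numEvents(tab)
  cnt <- historyCounts(tab)
  pat <- do.call(rbind, strsplit(names(cnt), ""))
  full <- rbind(pat, rep("0", k))
  counts <- c(unname(cnt), N - sum(cnt))
  abar <- delta * 2^k
  term <- function(A) {
    if (length(A) == 0L) {
      return(lgamma(abar + N) - lgamma(abar))
    }
    key <- apply(full[, A, drop = FALSE], 1L, paste0, collapse = "")
    marg <- tapply(counts, key, sum)
    w <- delta * 2^(k - length(A))
    ncells <- 2^length(A)
    present <- sum(lgamma(w + marg) - lgamma(w))
    present  # absent keys have count 0 and contribute lgamma(w)-lgamma(w)=0
  }
  lgamma(N + 1) - sum(lgamma(counts + 1)) +
    lgamma(abar) - lgamma(abar + N) +
    sum(vapply(model@cliques, term, numeric(1))) -
    sum(vapply(model@separators, term, numeric(1)))
}

test_that("all chordal graphs are enumerated: 8, 61, 822 for k = 3, 4, 5", {
  expect_length(enumerateDecomposableModels(3), 8L)
  expect_length(enumerateDecomposableModels(4), 61L)
  expect_length(enumerateDecomposableModels(5), 822L)
  expect_error(enumerateDecomposableModels(6), "between 3 and 5",
               class = "crcValidationError")
})

test_that("enumeration agrees with an independent chordality oracle on every k = 4 graph", {
  pairs <- combn(4, 2)
  chordalCount <- 0L
  for (code in 0:(2^6 - 1)) {
    sel <- which(bitwAnd(bitwShiftR(code, 0:5), 1L) == 1L)
    g <- igraph::make_empty_graph(4, directed = FALSE)
    if (length(sel)) {
      g <- igraph::add_edges(g, as.vector(pairs[, sel, drop = FALSE]))
    }
    if (igraph::is_chordal(g)$chordal) chordalCount <- chordalCount + 1L
  }
  expect_identical(chordalCount, 61L)
})

test_that("every enumerated model carries a valid clique/separator decomposition", {
  for (m in enumerateDecomposableModels(3)) {
    covered <- sort(unique(unlist(m@cliques)))
    expect_identical(covered, 1:3)         # cliques cover the vertices
    expect_length(m@separators, max(0L, length(m@cliques) - 1L))
    if (length(m@cliques) > 1L) {
      for (i in 2:length(m@cliques)) {
        hist <- unique(unlist(m@cliques[seq_len(i - 1L)]))
        expect_identical(sort(intersect(m@cliques[[i]], hist)),
                         m@separators[[i - 1L]])
      }
    }
  }
  indep <- enumerateDecomposableModels(3)[[1L]]
  expect_identical(nrow(indep@edges), 0L)
  expect_length(indep@cliques, 3L)         # k singleton cliques
})

test_that("saturated marginal likelihood matches a sequential Beta-integration oracle", {
  models <- enumerateDecomposableModels(3)
  sat <- models[[length(models)]]
  expect_length(sat@cliques, 1L)
  tab <- suppressWarnings(CaptureHistoryTable(
    setNames(rep(1L, 7), c("100", "010", "001", "110", "101", "011", "111"))))
  N <- 8; delta <- 2^-3
  got <- logMarginalLikelihood(sat, tab, N, delta)
  # integrate the 8-cell Dirichlet integral cell by cell via Beta functions
  x <- c(rep(1, 7), N - 7)
  a <- rep(delta, 8)
  dirIntegral <- 0
  for (i in 1:7) {
    dirIntegral <- dirIntegral +
      lbeta(a[i] + x[i], sum(a[(i + 1):8] + x[(i + 1):8])) -
      lbeta(a[i], sum(a[(i + 1):8]))
  }
  expected <- lgamma(N + 1) - sum(lgamma(x + 1)) + dirIntegral
  expect_equal(got, expected, tolerance = 1e-6)
})

test_that("the independence model factorizes into per-list beta-binomial margins", {
  tab <- indepTable()
  n <- totalObserved(tab)
  d <- descriptiveStats(tab)
  indep <- enumerateDecomposableModels(3)[[1L]]
  delta <- 2^-3
  for (N in c(n, n + 17, n + 200)) {
    got <- logMarginalLikelihood(indep, tab, N, delta)
    w <- delta * 2^2   # weight of each 2-cell margin cell
    perList <- sum(vapply(d@nj, function(nj)
      lbeta(w + nj, w + N - nj) - lbeta(w, w), numeric(1)))
    cnt <- c(unname(historyCounts(tab)), N - n)
    expected <- lgamma(N + 1) - sum(lgamma(cnt + 1)) + perList
    expect_equal(got, expected, tolerance = 1e-9)
  }
})

test_that("N = n is a finite boundary case for every model", {
  tab <- indepTable()
  for (m in enumerateDecomposableModels(3)) {
    v <- logMarginalLikelihood(m, tab, totalObserved(tab), 2^-3)
    expect_true(is.finite(v))
  }
  expect_error(
    logMarginalLikelihood(enumerateDecomposableModels(3)[[1L]], tab, 10),
    "at least", class = "crcValidationError")
})

test_that("log-normal prior elicitation reproduces its quantiles", {
  p <- lognormalPrior(20000, 80000)
  expect_equal(p@mu, log(20000), tolerance = 1e-6)
  expect_equal(p@sigma, log(4) / qnorm(0.9), tolerance = 1e-6)
  expect_equal(p@sigma, 1.0817, tolerance = 1e-4)

  pd <- lognormalPrior(7000, 10000)
  expect_equal(pd@sigma, log(10 / 7) / qnorm(0.9), tolerance = 1e-8)
  expect_equal(pd@sigma, 0.2783, tolerance = 1e-3)

  set.seed(31)
  draws <- rlnorm(1e6, p@mu, p@sigma)
  expect_lt(abs(median(draws) - 20000) / 20000, 0.01)
  expect_lt(abs(quantile(draws, 0.9, names = FALSE) - 80000) / 80000, 0.01)

  expect_error(lognormalPrior(10000, 8000), "exceed",
               class = "crcValidationError")
})

test_that("the grid posterior matches brute-force summation on a tiny table", {
  tab <- suppressWarnings(CaptureHistoryTable(
    c("100" = 4, "010" = 5, "001" = 3, "110" = 3, "101" = 2, "011" = 2,
      "111" = 1)))
  n <- totalObserved(tab)
  nMax <- n + 50
  models <- enumerateDecomposableModels(3)
  fit <- bmaPosterior(tab, gridStep = 1, nMax = nMax)

  # plain-arithmetic double loop with the independent oracle
  grid <- seq(n, nMax)
  lw <- matrix(NA_real_, length(models), length(grid))
  for (i in seq_along(models)) {
    for (j in seq_along(grid)) {
      lw[i, j] <- oracleLML(models[[i]], tab, grid[j], 2^-3) - log(grid[j])
    }
  }
  w <- exp(lw - max(lw))
  expect_equal(fit@posterior, colSums(w) / sum(w), tolerance = 1e-8)
  expect_equal(unname(modelProbabilities(fit)),
               unname(rowSums(w) / sum(w)), tolerance = 1e-8)
})

test_that("posterior masses and model probabilities normalize", {
  fit <- bmaPosterior(indepTable())
  expect_equal(sum(fit@posterior), 1, tolerance = 1e-9)
  expect_equal(sum(modelProbabilities(fit)), 1, tolerance = 1e-9)
  expect_gte(min(fit@posterior), 0)
  expect_identical(fit@Ngrid[1L], as.numeric(totalObserved(indepTable())))
})

test_that("independent-list data favor the independence model on average", {
  set.seed(121)
  R <- 40
  probs <- matrix(NA_real_, R, 8)
  for (r in 1:R) {
    tab <- simulateStudy(1000, probs = rep(0.3, 3))
    probs[r, ] <- modelProbabilities(bmaPosterior(tab, nMax = 5000))
  }
  mp <- colMeans(probs)
  labels <- vapply(enumerateDecomposableModels(3),
                   function(m) m@label, character(1))
  expect_identical(labels[which.max(mp)], "[1][2][3]")
})

test_that("relabeling the lists permutes the model probabilities consistently", {
  set.seed(91)
  tab <- randomHistoryTable(3)
  perm <- c(2L, 3L, 1L)          # event j of the new table = old event perm[j]
  tabP <- permuteEvents(tab, perm)
  p1 <- modelProbabilities(bmaPosterior(tab, gridStep = 1,
                                        nMax = totalObserved(tab) + 150))
  p2 <- modelProbabilities(bmaPosterior(tabP, gridStep = 1,
                                        nMax = totalObserved(tabP) + 150))
  # old event perm[j] becomes new event j, so old label v maps to match(v, perm)
  map <- match(seq_len(3), perm)
  models <- enumerateDecomposableModels(3)
  for (i in seq_along(models)) {
    newLabel <- relabelledModelLabel(models[[i]], map)
    j <- which(vapply(models, canonicalModelLabel, character(1)) == newLabel)
    expect_equal(unname(p1[i]), unname(p2[j]), tolerance = 1e-9)
  }
})

test_that("a point-mass prior forces a point-mass posterior", {
  tab <- indepTable()
  N0 <- totalObserved(tab) + 60
  fit <- bmaPosterior(tab, prior = pointPrior(N0), gridStep = 1)
  expect_equal(fit@posterior[fit@Ngrid == N0], 1, tolerance = 1e-12)
  expect_equal(popEstimate(fit), N0)
  expect_equal(unname(confInt(fit)), c(N0, N0))
})

test_that("noninformative and log-normal priors agree on well-identified data", {
  tab <- simulateStudy(1000, probs = rep(0.3, 3), seed = 2)
  e1 <- popEstimate(bmaPosterior(tab, nMax = 20000))
  e2 <- popEstimate(bmaPosterior(tab, prior = lognormalPrior(1000, 2500,
                                                            nMax = 20000)))
  expect_lt(abs(e1 - e2) / e1, 0.02)
})
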