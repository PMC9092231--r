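#' @include decomposable.R
NULL

.z90 <- stats::qnorm(0.90)

#' Priors on the population size
#'
#' \code{noninformativePrior} is the improper prior with density proportional
#' to \eqn{1/N} on \eqn{\{n, \dots, N_{max}\}}. \code{lognormalPrior} elicits
#' a log-normal prior from a believed median and 90th percentile:
#' \eqn{\mu = \ln(\mathrm{median})}, \eqn{\sigma = (\ln q_{90} -
#' \ln \mathrm{median}) / z_{0.90}}, truncated at \code{nMax}.
#' \code{pointPrior} puts all mass on a single value (degenerate-prior
#' checks).
#'
#' @param median,q90 elicited population-size quantiles; \code{q90} must
#'   exceed \code{median}.
#' @param nMax truncation bound (defaults to \code{10 * q90} for the
#'   log-normal prior; for the noninformative prior it may be left \code{NA}
#'   and defaults to \eqn{20 n} at analysis time).
#' @return A \linkS4class{PriorSpec}.
#' @examples
#' lognormalPrior(20000, 80000)
#' @export
lognormalPrior <- function(median, q90, nMax = 10 * q90) {
  if (!(median > 0)) crcStop("median must be positive")
  if (q90 <= median) crcStop("90th percentile must exceed median")
  if (nMax < q90) crcStop("nMax must be at least the 90th percentile")
  new("PriorSpec", kind = "lognormal", median = as.numeric(median),
      q90 = as.numeric(q90), nMax = as.numeric(nMax),
      mu = log(median), sigma = (log(q90) - log(median)) / .z90,
      value = NA_real_)
}

#' @rdname lognormalPrior
#' @export
noninformativePrior <- function(nMax = NA_real_) {
  new("PriorSpec", kind = "noninformative", median = NA_real_,
      q90 = NA_real_, nMax = as.numeric(nMax), mu = NA_real_,
      sigma = NA_real_, value = NA_real_)
}

#' @rdname lognormalPrior
#' @param value population size carrying all prior mass.
#' @export
pointPrior <- function(value) {
  new("PriorSpec", kind = "point", median = NA_real_, q90 = NA_real_,
      nMax = as.numeric(value), mu = NA_real_, sigma = NA_real_,
      value = as.numeric(value))
}

setMethod("show", "PriorSpec", function(object) {
  switch(object@kind,
    lognormal = cat(sprintf(
      "Log-normal prior on N: median %.0f, q90 %.0f (mu = %.4f, sigma = %.4f), truncated at %.0f\n",
      object@median, object@q90, object@mu, object@sigma, object@nMax)),
    noninformative = cat(sprintf(
      "Noninformative prior on N (density ~ 1/N)%s\n",
      if (is.na(object@nMax)) "" else sprintf(", truncated at %.0f", object@nMax))),
    point = cat(sprintf("Point-mass prior at N = %.0f\n", object@value)))
})

.logPriorN <- function(prior, N) {
  switch(prior@kind,
    noninformative = -log(N),
    lognormal = stats::dlnorm(N, prior@mu, prior@sigma, log = TRUE),
    point = ifelse(N == prior@value, 0, -Inf),
    crcStop(sprintf("unknown prior kind '%s'", prior@kind)))
}

## Marginal table of the completed 2^k table over the events in A: observed
## aggregated counts per cell of A (the all-zero cell of A additionally
## receives the unobserved count N - n). Cells are indexed by the code of the
## sub-pattern over A.
.marginCounts <- function(t, A) {
  if (length(A) == 0L) return(list(counts = sum(t@counts), zeroCell = 1L))
  sub <- t@patterns[, A, drop = FALSE]
  code <- as.integer(sub %*% 2^(rev(seq_along(A)) - 1)) + 1L
  counts <- numeric(2^length(A))
  for (i in seq_along(code)) counts[code[i]] <- counts[code[i]] + t@counts[i]
  list(counts = counts, zeroCell = 1L)
}

## log Dirichlet-ratio term of one margin, vectorized over the N grid. Each
## margin cell carries prior weight delta * 2^(k - |A|) (the number of full
## 2^k cells collapsing into it); the all-zero cell's count includes N - n.
.marginTerm <- function(t, A, Ngrid, delta) {
  k <- t@k
  n <- sum(t@counts)
  w <- delta * 2^(k - length(A))
  mc <- .marginCounts(t, A)
  cnt <- mc$counts
  fixed <- sum(lgamma(w + cnt[-mc$zeroCell]) - lgamma(w))
  fixed + lgamma(w + cnt[mc$zeroCell] + Ngrid - n) - lgamma(w)
}

#' Hyper-Dirichlet log marginal likelihood of a decomposable model
#'
#' Closed-form log marginal likelihood of the completed \eqn{2^k} table (the
#' unobserved cell holding \eqn{N - n}) under a decomposable dependence model
#' with a hyper-Dirichlet prior whose full-table cells carry weight
#' \code{delta} each: the multinomial coefficient in \eqn{N} plus a Dirichlet
#' ratio term per clique minus one per separator, each margin cell weighted
#' by \code{delta} times the number of full cells mapping into it.
#'
#' @param model a \linkS4class{DecomposableModel}.
#' @param t a \linkS4class{CaptureHistoryTable} on the same \eqn{k} events.
#' @param N population size (may be a vector; every value must be
#'   \eqn{\ge n}).
#' @param delta hyper-Dirichlet cell prior weight (default \eqn{2^{-k}};
#'   lower values put less prior weight on complex list interactions).
#' @return Numeric vector of log marginal likelihood values, one per
#'   \code{N}.
#' @export
logMarginalLikelihood <- function(model, t, N, delta = 2^-numEvents(t)) {
  stopifnot(is(model, "DecomposableModel"), is(t, "CaptureHistoryTable"))
  if (model@k != t@k) crcStop("model and table disagree on k")
  if (delta <= 0) crcStop("delta must be positive")
  n <- sum(t@counts)
  if (any(N < n)) crcStop("N must be at least the observed total n")
  k <- t@k
  abar <- delta * 2^k
  out <- lgamma(N + 1) - lgamma(N - n + 1) - sum(lgamma(t@counts + 1)) +
    lgamma(abar) - lgamma(abar + N)
  for (C in model@cliques) out <- out + .marginTerm(t, C, N, delta)
  for (S in model@separators) out <- out - .marginTerm(t, S, N, delta)
  out
}

#' Bayesian model averaging over decomposable dependence models
#'
#' Computes the posterior distribution of the population size by averaging
#' the hyper-Dirichlet marginal likelihoods of all decomposable dependence
#' models on the \eqn{k} lists (uniform prior across models; model complexity
#' is penalized through the \code{delta} cell weight) against a prior on
#' \eqn{N}, over an integer grid from \eqn{n} to \code{nMax}.
#'
#' @param t a \linkS4class{CaptureHistoryTable} with \eqn{3 \le k \le 5}.
#' @param prior a \linkS4class{PriorSpec} (default noninformative).
#' @param delta hyper-Dirichlet cell weight, default \eqn{2^{-k}}.
#' @param gridStep grid step over \eqn{N}; defaults to
#'   \code{max(1, floor((nMax - n)/50000))}.
#' @param level credible-interval level.
#' @param models model list, defaulting to the full enumeration of
#'   \code{\link{enumerateDecomposableModels}}.
#' @param nMax overrides the prior's truncation bound (defaults to the
#'   prior's bound, or \eqn{20 n} when the prior leaves it unset).
#' @return A \linkS4class{BMAPosterior}.
#' @examples
#' t3 <- CaptureHistoryTable(c("100" = 35, "010" = 31, "001" = 34,
#'                             "110" = 14, "101" = 16, "011" = 14,
#'                             "111" = 6))
#' fit <- bmaPosterior(t3)
#' popEstimate(fit)
#' @export
bmaPosterior <- function(t, prior = noninformativePrior(), delta = NULL,
                         gridStep = NULL, level = 0.95, models = NULL,
                         nMax = NULL) {
  stopifnot(is(t, "CaptureHistoryTable"), is(prior, "PriorSpec"))
  k <- t@k
  if (k < 3L || k > 5L) {
    crcStop("Bayesian model averaging requires between 3 and 5 events")
  }
  n <- totalObserved(t)
  if (n == 0L) crcStop("table has no observed individuals")
  delta <- delta %||% 2^-k
  if (delta <= 0) crcStop("delta must be positive")
  nMax <- nMax %||% (if (is.na(prior@nMax)) 20 * n else prior@nMax)
  if (nMax < n) crcStop("nMax must be at least the observed total")
  models <- models %||% enumerateDecomposableModels(k)
  gridStep <- gridStep %||% max(1, floor((nMax - n) / 50000))
  Ngrid <- seq(max(n, 1), nMax, by = gridStep)
  lp <- .logPriorN(prior, Ngrid)

  L <- matrix(NA_real_, length(models), length(Ngrid))
  for (i in seq_along(models)) {
    L[i, ] <- logMarginalLikelihood(models[[i]], t, Ngrid, delta) + lp
  }
  shift <- max(L[is.finite(L)])
  W <- exp(L - shift)
  total <- sum(W)
  if (!is.finite(total) || total <= 0) {
    crcStop("posterior is degenerate (no model/prior mass on the grid)")
  }
  postN <- colSums(W) / total
  modelProbs <- rowSums(W) / total
  names(modelProbs) <- vapply(models, function(m) m@label, character(1))
  meanN <- sum(Ngrid * postN)
  cdf <- cumsum(postN)
  qAt <- function(p) Ngrid[which(cdf >= p)[1L]]
  medianN <- qAt(0.5)
  ci <- c(qAt((1 - level) / 2), qAt(1 - (1 - level) / 2))
  conditional <- if (length(W) <= 2e6) {
    sweep(W, 1, rowSums(W), "/")
  } else {
    matrix(numeric(0), 0, 0)
  }
  new("BMAPosterior", Ngrid = Ngrid, posterior = postN,
      modelProbs = modelProbs, models = models, conditional = conditional,
      mean = meanN, median = as.numeric(medianN), ci = as.numeric(ci),
      ciLevel = level, delta = delta, prior = prior, n = as.integer(n))
}

#' @describeIn bmaPosterior posterior mean of the population size.
#' @param x a \code{BMAPosterior}.
#' @export
setMethod("popEstimate", "BMAPosterior", function(x) x@mean)

#' @describeIn bmaPosterior equal-tailed credible interval.
#' @export
setMethod("confInt", "BMAPosterior", function(x) {
  stats::setNames(x@ci, c("lower", "upper"))
})

#' @describeIn bmaPosterior posterior probability of each dependence model.
#' @export
setMethod("modelProbabilities", "BMAPosterior", function(x) x@modelProbs)

setMethod("show", "BMAPosterior", function(object) {
  cat(sprintf(
    "Bayesian model averaging over %d decomposable models (delta = %.4g)\n",
    length(object@models), object@delta))
  cat(sprintf("  posterior mean N = %.1f, median = %.0f, %g%% CrI [%.0f, %.0f]\n",
              object@mean, object@median, 100 * object@ciLevel,
              object@ci[1L], object@ci[2L]))
  top <- utils::head(sort(object@modelProbs, decreasing = TRUE), 3L)
  cat("  top models:",
      paste(sprintf("%s (%.3f)", names(top), top), collapse = ", "), "\n")
})
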