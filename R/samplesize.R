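#' @include normal-mixing.R
NULL

#' Logit-scale heterogeneity SD from an odds-ratio quantile
#'
#' Capture heterogeneity is parameterized by stating that a fraction \eqn{q}
#' of the population has capture odds less than \eqn{r} times those of the
#' average individual. Under a logit-normal random effect
#' \eqn{\epsilon \sim N(0, \sigma_h^2)} the odds multiplier is
#' \eqn{e^\epsilon}, so \eqn{\sigma_h = \ln(r) / \Phi^{-1}(q)}.
#'
#' @param r odds ratio at the quantile (\eqn{\ge 1}; \eqn{r = 1} is the
#'   homogeneous population).
#' @param q the quantile, in \eqn{(0.5, 1)}; default 0.90.
#' @return The logit-scale SD \eqn{\sigma_h}.
#' @examples
#' sigmaFromOddsQuantile(1.2)  # ~0.14226
#' @export
sigmaFromOddsQuantile <- function(r, q = 0.90) {
  if (r < 1) crcStop("odds ratio r must be at least 1")
  if (!(q > 0.5 && q < 1)) crcStop("quantile q must lie in (0.5, 1)")
  log(r) / stats::qnorm(q)
}

#' Calibrate per-event logit intercepts to target sample sizes
#'
#' Solves \eqn{E[\mathrm{expit}(\mu_j + \epsilon)] = n_j / N} for each event,
#' with \eqn{\epsilon \sim N(0, \sigma_h^2)} integrated by Gauss-Hermite
#' quadrature, so that simulated studies hit the stated expected per-event
#' sample sizes. With \eqn{\sigma_h = 0} this reduces to
#' \eqn{\mu_j = \mathrm{logit}(n_j / N)}.
#'
#' @param N true population size.
#' @param nj vector of expected per-event sample sizes, each in \eqn{(0, N)}.
#' @param sigma logit-scale heterogeneity SD.
#' @param nodes Gauss-Hermite node count.
#' @return Numeric vector of intercepts \eqn{\mu_j}.
#' @export
calibrateEventIntercepts <- function(N, nj, sigma = 0, nodes = 20L) {
  if (any(nj <= 0 | nj >= N)) {
    crcStop("target sample sizes must satisfy 0 < n_j < N")
  }
  target <- nj / N
  if (sigma == 0) return(logit(target))
  gh <- ghNormal(nodes)
  meanP <- function(mu) sum(gh$w * expit(mu + sigma * gh$x))
  vapply(target, function(p) {
    f <- function(mu) meanP(mu) - p
    if (f(-30) > 0 || f(30) < 0) {
      crcStop("no intercept in (-30, 30) attains the target capture fraction")
    }
    stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
  }, numeric(1))
}

#' Simulate a capture-recapture study
#'
#' Draws a closed population of \code{N} individuals with a shared
#' logit-normal random effect across events (the Mth-normal generating
#' model): individual \eqn{i} is captured at event \eqn{j} with probability
#' \eqn{\mathrm{expit}(\mu_j + \epsilon_i)}, \eqn{\epsilon_i \sim N(0,
#' \sigma_h^2)}. Observed individuals (captured at least once) are aggregated
#' into a capture-history table. Expected per-event totals equal the targets
#' \code{nj}; realized totals are binomial around them.
#'
#' @param N true population size.
#' @param nj expected per-event sample sizes (used to calibrate intercepts);
#'   give either \code{nj} or \code{probs}.
#' @param probs alternatively, per-event capture probabilities for the
#'   average (\eqn{\epsilon = 0}) individual.
#' @param sigma logit-scale heterogeneity SD (0 = homogeneous).
#' @param seed optional integer seed.
#' @return A \linkS4class{CaptureHistoryTable} of the observed individuals.
#' @export
simulateStudy <- function(N, nj = NULL, probs = NULL, sigma = 0,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(nj) == is.null(probs)) {
    crcStop("give exactly one of nj or probs")
  }
  mu <- if (!is.null(nj)) calibrateEventIntercepts(N, nj, sigma)
        else logit(probs)
  k <- length(mu)
  if (k < 2L) crcStop("at least 2 events are required")
  for (try in seq_len(10L)) {
    eps <- if (sigma > 0) stats::rnorm(N, 0, sigma) else numeric(N)
    caught <- matrix(0L, N, k)
    for (j in seq_len(k)) {
      caught[, j] <- as.integer(stats::runif(N) < expit(mu[j] + eps))
    }
    obs <- caught[rowSums(caught) > 0L, , drop = FALSE]
    if (nrow(obs) > 0L) return(aggregateIndividuals(obs, k = k))
    crcWarn("no individuals observed; resimulating")
  }
  crcStop("no individuals observed in 10 simulation attempts; capture probabilities too small")
}

#' Simulation-based precision calculator for study design
#'
#' Simulates \code{replicates} capture-recapture studies under the stated
#' design (true size \code{N}, expected per-event sample sizes \code{nj},
#' logit-normal heterogeneity given by \code{oddsRatio} at \code{quantile}),
#' fits the configured log-linear estimator to each, and tabulates the
#' distribution of the absolute relative error \eqn{|\hat N - N| / N}. The
#' estimator defaults to Mt for a homogeneous design and to the Mth model
#' with normally distributed capture probabilities when heterogeneity is
#' present.
#'
#' @param N assumed true population size.
#' @param nj expected per-event sample sizes.
#' @param oddsRatio heterogeneity: a fraction \code{quantile} of the
#'   population has capture odds below \code{oddsRatio} times the average
#'   individual's (1 = homogeneous).
#' @param quantile quantile at which the odds ratio is stated.
#' @param replicates number of simulated studies (100+ recommended).
#' @param estimator \code{"auto"} (Mt iff homogeneous), \code{"Mt"} or
#'   \code{"MthNormal"}.
#' @param seed optional integer seed.
#' @param tolerances accuracy tolerances, in percent, for the
#'   within-tolerance table.
#' @return A \linkS4class{PrecisionTable}. Replicates whose fit failed are
#'   excluded from the quantiles and reported in the \code{failed} slot; more
#'   than 20\% failures is an error advising larger samples.
#' @examples
#' pt <- precisionSimulation(2000, c(400, 400, 400), replicates = 50, seed = 1)
#' pt
#' @export
precisionSimulation <- function(N, nj, oddsRatio = 1, quantile = 0.90,
                                replicates = 1000L,
                                estimator = c("auto", "Mt", "MthNormal"),
                                seed = NULL,
                                tolerances = c(2.5, 5, 7.5, 10, 15, 20)) {
  estimator <- match.arg(estimator)
  if (replicates < 1L) crcStop("at least one replicate is required")
  sigma <- sigmaFromOddsQuantile(oddsRatio, quantile)
  if (estimator == "auto") {
    estimator <- if (sigma == 0) "Mt" else "MthNormal"
  }
  if (!is.null(seed)) set.seed(seed)
  est <- rep(NA_real_, replicates)
  for (r in seq_len(replicates)) {
    tab <- simulateStudy(N, nj = nj, sigma = sigma)
    fit <- tryCatch(
      if (estimator == "Mt") fitLogLinear(tab, "Mt")
      else fitNormalMixing(tab, "Mth", computeSE = FALSE),
      error = function(e) NULL)
    if (!is.null(fit)) est[r] <- fit@Nhat
  }
  failed <- sum(is.na(est))
  if (failed > 0.2 * replicates) {
    crcStop(sprintf(
      "%d of %d replicate fits failed; increase the sample sizes",
      failed, replicates))
  }
  ok <- est[!is.na(est)]
  relErr <- 100 * abs(ok - N) / N
  withinFraction <- vapply(tolerances, function(tol) mean(relErr <= tol),
                           numeric(1))
  qs <- stats::quantile(relErr, c(0.5, 0.8, 0.9, 0.95), names = FALSE)
  new("PrecisionTable",
      tolerances = tolerances, withinFraction = withinFraction,
      errorQuantiles = stats::setNames(qs, c("q50", "q80", "q90", "q95")),
      estimates = ok, relErrors = relErr, failed = as.integer(failed),
      config = list(N = N, nj = nj, oddsRatio = oddsRatio,
                    quantile = quantile, sigma = sigma,
                    replicates = replicates, estimator = estimator,
                    seed = seed))
}

setMethod("show", "PrecisionTable", function(object) {
  cfg <- object@config
  cat(sprintf(
    "Precision simulation: N = %s, samples (%s), %d replicates, %s estimator\n",
    format(cfg$N, big.mark = ","), paste(cfg$nj, collapse = ", "),
    cfg$replicates, cfg$estimator))
  if (cfg$oddsRatio > 1) {
    cat(sprintf("  heterogeneity: odds ratio %.3g at the %g%% quantile (sigma_h = %.4f)\n",
                cfg$oddsRatio, 100 * cfg$quantile, cfg$sigma))
  }
  cat("  fraction of estimates within tolerance of the true size:\n")
  for (i in seq_along(object@tolerances)) {
    cat(sprintf("    within %4.1f%%: %5.1f%%\n", object@tolerances[i],
                100 * object@withinFraction[i]))
  }
  q <- object@errorQuantiles
  cat(sprintf(
    "  relative error quantiles: 50%% = %.2f%%, 80%% = %.2f%%, 90%% = %.2f%%, 95%% = %.2f%%\n",
    q[1L], q[2L], q[3L], q[4L]))
  if (object@failed > 0L) {
    cat(sprintf("  failed fits: %d\n", object@failed))
  }
})
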