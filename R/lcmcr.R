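#' @include AllClasses.R
NULL

#' Named configuration presets for the latent-class sampler
#'
#' \code{"default"} carries the standard settings (10,000 samples, 10,000
#' burn-in, thinning 10, 10 classes); \code{"paper-fsw"} carries the heavier
#' settings used for the FSW worked analysis (100,000 samples, 100,000
#' burn-in, thinning 100), which trade run time for effective sample size.
#'
#' @param name preset name.
#' @return Named list of sampler settings.
#' @export
lcmcrPreset <- function(name = c("default", "paper-fsw")) {
  name <- match.arg(name)
  switch(name,
    "default" = list(samples = 10000L, burnin = 10000L, thinning = 10L,
                     maxClasses = 10L, shape = 0.25, scale = 0.25),
    "paper-fsw" = list(samples = 100000L, burnin = 100000L, thinning = 100L,
                       maxClasses = 10L, shape = 0.25, scale = 0.25))
}

#' Bayesian nonparametric latent-class capture-recapture sampler
#'
#' Gibbs sampler for a truncated stick-breaking Dirichlet-process mixture of
#' product-Bernoulli capture profiles. The population is modeled as a mixture
#' of latent classes; class \eqn{c} has per-event capture probabilities
#' \eqn{\lambda_{jc}} with Beta(1,1) priors, mixture weights come from stick
#' fractions \eqn{\nu_c \sim Beta(1, \alpha)} (truncated at
#' \code{maxClasses}), and the concentration \eqn{\alpha} carries a
#' Gamma(\code{shape}, \code{scale}) prior — shape/scale convention, prior
#' mean \code{shape * scale}. The prior on the population size is
#' proportional to \eqn{1/N}, implemented through the negative-binomial full
#' conditional of the unobserved count \eqn{n_0}: with escape probability
#' \eqn{p_0 = \sum_c \pi_c \prod_j (1 - \lambda_{jc})},
#' \eqn{n_0 \sim NegBin(n, 1 - p_0)}.
#'
#' Each sweep (1) reassigns observed individuals to classes (by history,
#' since individuals sharing a history are exchangeable), (2) draws
#' \eqn{\lambda_{jc}} from their Beta full conditionals including the imputed
#' unobserved individuals, (3) draws the sticks, (4) draws \eqn{\alpha}, and
#' (5) draws \eqn{n_0} and imputes its class memberships. \eqn{N = n + n_0}
#' is recorded every \code{thinning}-th sweep after \code{burnin}. The run is
#' deterministic given \code{seed}.
#'
#' @param t a \linkS4class{CaptureHistoryTable}; three or more events are
#'   recommended (a warning is issued at \eqn{k = 2}).
#' @param samples post-burn-in sweeps (kept draws = \code{samples /
#'   thinning}).
#' @param burnin sweeps discarded before recording.
#' @param thinning recording interval.
#' @param maxClasses truncation level \eqn{K^*} of the stick-breaking
#'   representation; a warning is issued if the occupied classes hit it in
#'   more than 5\% of kept sweeps.
#' @param shape,scale Gamma prior on \eqn{\alpha} (shape/scale, mean
#'   \code{shape * scale}).
#' @param seed integer seed for reproducibility.
#' @param preset optional preset name (see \code{\link{lcmcrPreset}});
#'   explicit arguments override preset entries.
#' @return A \linkS4class{PosteriorDraws}.
#' @examples
#' t3 <- CaptureHistoryTable(c("100" = 35, "010" = 31, "001" = 34,
#'                             "110" = 14, "101" = 16, "011" = 14,
#'                             "111" = 6))
#' d <- runLCMCR(t3, samples = 500, burnin = 200, thinning = 5, seed = 1)
#' posteriorSummary(d)
#' @export
runLCMCR <- function(t, samples = 10000L, burnin = 10000L, thinning = 10L,
                     maxClasses = 10L, shape = 0.25, scale = 0.25,
                     seed = NULL, preset = NULL) {
  stopifnot(is(t, "CaptureHistoryTable"))
  if (!is.null(preset)) {
    cfg <- lcmcrPreset(preset)
    call <- as.list(match.call())
    for (nm in names(cfg)) {
      if (!nm %in% names(call)) assign(nm, cfg[[nm]])
    }
  }
  if (maxClasses < 2L) crcStop("maxClasses must be at least 2")
  if (samples < 0L || burnin < 0L) crcStop("samples and burnin must be >= 0")
  if (thinning < 1L) crcStop("thinning must be >= 1")
  k <- t@k
  if (k == 2L) {
    crcWarn("only 2 encounter events: latent-class heterogeneity is weakly identified")
  }
  P <- t@patterns
  x <- t@counts
  n <- sum(x)
  if (n == 0L) crcStop("table has no observed individuals")
  if (sum(x > 0L) == 1L) {
    crcWarn("all individuals share a single history: the model is weakly identified")
  }
  if (!is.null(seed)) set.seed(seed)
  K <- as.integer(maxClasses)
  H <- nrow(P)
  rate0 <- 1 / scale

  lambda <- matrix(stats::rbeta(k * K, 1, 1), k, K)
  nu <- c(stats::rbeta(K - 1L, 1, 1), 1)
  alpha <- shape * scale
  n0 <- n

  nKeep <- floor(samples / thinning)
  drawsN <- numeric(nKeep)
  drawsAlpha <- numeric(nKeep)
  drawsOcc <- integer(nKeep)
  kept <- 0L
  total <- burnin + samples

  logpi <- function(nu) {
    l1m <- log1p(-pmin(nu, 1 - 1e-12))
    log(pmin(nu, 1 - 1e-12)) + c(0, cumsum(l1m[-K]))
  }

  for (it in seq_len(total)) {
    ## (1) class assignments per observed history
    lpi <- logpi(nu)
    lphi <- P %*% log(lambda) + (1 - P) %*% log1p(-lambda)   # H x K
    lw <- sweep(lphi, 2L, lpi, `+`)
    lw <- lw - apply(lw, 1L, max)
    wmat <- exp(lw)
    M <- matrix(0, H, K)
    for (h in seq_len(H)) {
      if (x[h] > 0L) M[h, ] <- stats::rmultinom(1L, x[h], wmat[h, ])
    }

    ## (5a) unobserved count given current weights/profiles
    pi_c <- exp(lpi)
    p0_c <- exp(colSums(log1p(-lambda)))
    p0 <- min(sum(pi_c * p0_c), 1 - 1e-12)
    n0 <- stats::rnbinom(1L, size = n, prob = 1 - p0)
    if (is.na(n0) || n0 > 1e9) {
      crcStop("unobserved count diverged (escape probability too close to 1)")
    }
    M0 <- as.vector(stats::rmultinom(1L, n0, pi_c * p0_c / sum(pi_c * p0_c)))

    ## (2) capture profiles
    mObs <- colSums(M)
    mc <- mObs + M0
    capt <- crossprod(P, M)                 # k x K captures per event/class
    miss <- matrix(mc, k, K, byrow = TRUE) - capt
    lambda <- matrix(stats::rbeta(k * K, 1 + capt, 1 + miss), k, K)

    ## (3) sticks
    tailCount <- rev(cumsum(rev(mc)))       # sum_{l >= c} m_l
    nu <- c(stats::rbeta(K - 1L, 1 + mc[-K], alpha + tailCount[-1L]), 1)

    ## (4) concentration
    alpha <- stats::rgamma(1L, shape + K - 1L,
                           rate = rate0 - sum(log1p(-pmin(nu[-K], 1 - 1e-12))))

    if (it > burnin && (it - burnin) %% thinning == 0L) {
      kept <- kept + 1L
      drawsN[kept] <- n + n0
      drawsAlpha[kept] <- alpha
      drawsOcc[kept] <- sum(mc > 0L)
    }
  }

  if (kept > 0L && mean(drawsOcc == K) > 0.05) {
    crcWarn(sprintf(
      "occupied classes hit maxClasses = %d in %.1f%% of kept sweeps; increase maxClasses",
      K, 100 * mean(drawsOcc == K)))
  }
  new("PosteriorDraws", draws = drawsN[seq_len(kept)],
      alpha = drawsAlpha[seq_len(kept)], occupied = drawsOcc[seq_len(kept)],
      n = as.integer(n), k = k,
      config = list(samples = samples, burnin = burnin, thinning = thinning,
                    maxClasses = K, shape = shape, scale = scale),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Posterior summary of population-size draws
#'
#' @param draws a \linkS4class{PosteriorDraws} or numeric vector of draws.
#' @param level equal-tailed interval level in \eqn{(0, 1)}.
#' @return Named list: \code{mean}, \code{median}, \code{lower},
#'   \code{upper}, \code{level}, \code{nDraws}.
#' @export
posteriorSummary <- function(draws, level = 0.95) {
  if (is(draws, "PosteriorDraws")) draws <- draws@draws
  if (!length(draws)) crcStop("no draws to summarize")
  if (!(level > 0 && level < 1)) crcStop("level must be in (0, 1)")
  q <- stats::quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE, type = 1)
  list(mean = mean(draws), median = stats::median(draws),
       lower = q[1L], upper = q[2L], level = level, nDraws = length(draws))
}

#' @describeIn runLCMCR thinned draws of \eqn{N}.
#' @param x a \code{PosteriorDraws}.
#' @export
setMethod("posteriorDraws", "PosteriorDraws", function(x) x@draws)

#' @describeIn runLCMCR posterior mean of \eqn{N}.
#' @export
setMethod("popEstimate", "PosteriorDraws", function(x) mean(x@draws))

#' @describeIn runLCMCR equal-tailed 95\% credible interval.
#' @export
setMethod("confInt", "PosteriorDraws", function(x) {
  s <- posteriorSummary(x)
  c(lower = s$lower, upper = s$upper)
})

#' @describeIn runLCMCR observed total.
#' @export
setMethod("totalObserved", "PosteriorDraws", function(x) x@n)

setMethod("show", "PosteriorDraws", function(object) {
  s <- posteriorSummary(object)
  cat(sprintf(
    "Latent-class posterior: %d thinned draws of N (n = %d, k = %d)\n",
    s$nDraws, object@n, object@k))
  cat(sprintf("  mean %.1f, median %.0f, 95%% CrI [%.0f, %.0f]\n",
              s$mean, s$median, s$lower, s$upper))
  cat(sprintf("  config: samples %d, burn-in %d, thinning %d, K* = %d, seed %s\n",
              object@config$samples, object@config$burnin,
              object@config$thinning, object@config$maxClasses,
              ifelse(is.na(object@seed), "none", object@seed)))
})
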