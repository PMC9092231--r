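#' @include lcmcr.R
NULL

.essGeyer <- function(x) {
  M <- length(x)
  if (M < 10L) crcStop("at least 10 draws are required")
  if (stats::var(x) < .Machine$double.eps) {
    crcWarn("constant chain: effective sample size reported as the number of draws")
    return(M)
  }
  maxLag <- min(M - 1L, max(10L, floor(10 * log10(M)) * 5L))
  rho <- as.vector(stats::acf(x, lag.max = maxLag, plot = FALSE,
                              demean = TRUE)$acf)
  ## Geyer initial positive sequence: sum consecutive pairs
  ## Gamma_m = rho_{2m} + rho_{2m+1} while they stay positive.
  tau <- 0
  m <- 0L
  repeat {
    i1 <- 2L * m + 1L
    i2 <- 2L * m + 2L
    if (i1 > length(rho)) break
    g <- rho[i1] + if (i2 <= length(rho)) rho[i2] else 0
    if (g <= 0) break
    tau <- tau + 2 * g
    m <- m + 1L
  }
  tau <- max(tau - 1, 1e-8)   # tau = -1 + 2 * sum Gamma_m; >= ~1 for iid
  min(M, M / tau)
}

#' @describeIn effectiveSampleSize ESS of a numeric chain.
#' @export
setMethod("effectiveSampleSize", "numeric", function(x) .essGeyer(x))

#' @describeIn effectiveSampleSize ESS of the population-size draws.
#' @export
setMethod("effectiveSampleSize", "PosteriorDraws", function(x) {
  .essGeyer(x@draws)
})

#' MCMC trace diagnostics
#'
#' Computes the lag-autocorrelation series, the Geyer effective sample size,
#' and an autocorrelation-adjusted z-statistic for a linear trend in the
#' chain (ordinary least-squares slope with its standard error inflated by
#' \eqn{\sqrt{M/ESS}}). A trend in the trace suggests the burn-in period was
#' too short; the chain is flagged when \eqn{|z| > 3}.
#'
#' @param draws a \linkS4class{PosteriorDraws} or numeric chain (at least 10
#'   draws).
#' @return An \linkS4class{MCMCDiagnostics}.
#' @export
traceSummary <- function(draws) {
  if (is(draws, "PosteriorDraws")) draws <- draws@draws
  M <- length(draws)
  if (M < 10L) crcStop("at least 10 draws are required")
  constant <- stats::var(draws) < .Machine$double.eps
  ess <- suppressWarnings(.essGeyer(draws))
  maxLag <- min(M - 1L, 50L)
  acfSeries <- if (constant) c(1, rep(0, maxLag)) else
    as.vector(stats::acf(draws, lag.max = maxLag, plot = FALSE)$acf)
  if (constant) {
    z <- 0
  } else {
    idx <- seq_len(M)
    fit <- stats::lm.fit(cbind(1, idx), draws)
    res <- fit$residuals
    s2 <- sum(res^2) / (M - 2L)
    seSlope <- sqrt(s2 / sum((idx - mean(idx))^2))
    z <- fit$coefficients[2L] / (seSlope * sqrt(M / ess))
  }
  new("MCMCDiagnostics", ess = ess, acfSeries = acfSeries,
      trace = as.numeric(draws), trendZ = unname(z),
      trendFlag = abs(z) > 3)
}

setMethod("show", "MCMCDiagnostics", function(object) {
  cat(sprintf("MCMC diagnostics: %d draws, ESS %.0f\n",
              length(object@trace), object@ess))
  cat(sprintf("  lag-1 autocorrelation %.3f; trend z = %.2f%s\n",
              if (length(object@acfSeries) > 1) object@acfSeries[2L] else NA,
              object@trendZ,
              if (object@trendFlag) " (TREND FLAGGED: increase burn-in)" else ""))
})
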