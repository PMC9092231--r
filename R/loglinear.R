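#' @include design-matrix.R
NULL

#' Fit a closed-population log-linear model
#'
#' Fits the Poisson regression of the \eqn{2^k - 1} observable cell counts on
#' the design of \code{\link{buildDesignMatrix}} (iteratively reweighted
#' least squares via \code{stats::glm}). The population size estimate is the
#' unobserved-cell extrapolation \eqn{\hat N = n + e^{\beta_0}} with
#' delta-method variance \eqn{e^{\beta_0} + e^{2\beta_0}\,Var(\beta_0)}
#' (the first term is the Poisson contribution of the unobserved cell) and a
#' Wald interval on the \eqn{\log(\hat N - n)} scale. For
#' \code{variant = "normal"} the model is instead fitted by conditional
#' likelihood with a logit-normal individual random effect integrated by
#' 20-node Gauss-Hermite quadrature, the mixing SD being profiled.
#'
#' Heterogeneity models (Mh/Mth) are unidentifiable with only two events and
#' are refused at \eqn{k = 2}.
#'
#' @param t a \linkS4class{CaptureHistoryTable} with \eqn{n > 0}.
#' @param model \code{"M0"}, \code{"Mt"}, \code{"Mh"} or \code{"Mth"}.
#' @param variant \code{"none"} for M0/Mt; one of \code{"normal"},
#'   \code{"poisson2"}, \code{"darroch"}, \code{"gamma3.5"}, \code{"chao"}
#'   for Mh/Mth.
#' @param ciLevel confidence level for the interval.
#' @param profileCI use a profile-likelihood interval for \eqn{\hat N}
#'   instead of the Wald default (design-matrix variants only).
#' @return A \linkS4class{LogLinearFit}.
#' @examples
#' t2 <- CaptureHistoryTable(c("11" = 20, "10" = 80, "01" = 30))
#' popEstimate(fitLogLinear(t2, "Mt"))  # Petersen: 100 * 50 / 20 = 250
#' @export
fitLogLinear <- function(t, model, variant = "none", ciLevel = 0.95,
                         profileCI = FALSE) {
  stopifnot(is(t, "CaptureHistoryTable"))
  model <- match.arg(model, .modelClasses)
  n <- totalObserved(t)
  if (n == 0L) crcStop("table has no observed individuals")
  k <- t@k
  if (model %in% c("Mh", "Mth")) {
    if (variant == "none") crcStop(sprintf("%s requires a variant", model))
    if (k == 2L) {
      crcStop("heterogeneity models are unidentifiable with only 2 events")
    }
  }
  if (variant == "normal") {
    return(fitNormalMixing(t, model, ciLevel = ciLevel))
  }

  X <- buildDesignMatrix(model, variant, k)
  off <- attr(X, "offset")
  y <- t@counts
  fit <- suppressWarnings(
    stats::glm(y ~ X - 1 + offset(off), family = stats::poisson())
  )
  beta <- stats::coef(fit)
  names(beta) <- colnames(X)
  if (!fit$converged) {
    crcStop(sprintf(
      "IRLS did not converge after %d iterations (deviance %.4g)",
      fit$iter, fit$deviance))
  }
  if (anyNA(beta)) {
    crcStop("design matrix is rank deficient for these data")
  }
  b0 <- beta[[1L]]
  if (abs(b0) > 30) {
    crcStop("estimate unbounded (no recaptures)")
  }
  N0 <- exp(b0)
  vb0 <- stats::vcov(fit)[1L, 1L]
  varN <- N0 + N0^2 * vb0
  se <- sqrt(varN)
  z <- stats::qnorm(1 - (1 - ciLevel) / 2)
  seLog <- sqrt(varN) / N0
  ci <- c(n + N0 * exp(-z * seLog), n + N0 * exp(z * seLog))
  if (profileCI) {
    ci <- .profileCI(y, X, off, n, ciLevel)
  }
  mu <- fit$fitted.values
  ll <- sum(stats::dpois(y, mu, log = TRUE))
  p <- ncol(X)
  new("LogLinearFit",
      modelClass = model, variant = variant, coefficients = unname(beta),
      Nhat = n + N0, se = se, ci = unname(ci), ciLevel = ciLevel,
      aic = -2 * ll + 2 * p, bic = -2 * ll + log(n) * p, loglik = ll,
      fitted = unname(mu), converged = fit$converged,
      isLowerBound = identical(variant, "chao"),
      n = as.integer(n), k = k, np = as.integer(p), sigmah = NA_real_,
      notes = character(0))
}

## Profile-likelihood interval for N0 = exp(beta0): fix beta0, refit the
## remaining coefficients, and invert the likelihood-ratio statistic.
.profileCI <- function(y, X, off, n, level) {
  full <- suppressWarnings(
    stats::glm(y ~ X - 1 + offset(off), family = stats::poisson()))
  ll0 <- stats::logLik(full)[1L]
  b0hat <- stats::coef(full)[[1L]]
  crit <- stats::qchisq(level, df = 1) / 2
  dev <- function(b0) {
    o <- off + b0 * X[, 1L]
    f <- suppressWarnings(
      stats::glm(y ~ X[, -1L, drop = FALSE] - 1 + offset(o),
                 family = stats::poisson()))
    ll0 - stats::logLik(f)[1L] - crit
  }
  lo <- tryCatch(stats::uniroot(dev, c(b0hat - 10, b0hat), tol = 1e-6)$root,
                 error = function(e) -Inf)
  hi <- tryCatch(stats::uniroot(dev, c(b0hat, b0hat + 10), tol = 1e-6)$root,
                 error = function(e) Inf)
  c(n + exp(lo), n + exp(hi))
}

#' Compare all applicable log-linear models
#'
#' Fits every applicable model/variant combination (heterogeneity variants
#' require \eqn{k \ge 3}) and tabulates the population size estimate,
#' standard error, confidence interval, AIC and BIC, sorted by AIC with ties
#' broken by BIC and then by the number of parameters. Individual model
#' failures are reported as flagged rows and never abort the table.
#'
#' @param t a \linkS4class{CaptureHistoryTable}.
#' @param ciLevel interval level passed to each fit.
#' @return A data frame with one row per model; the fitted
#'   \linkS4class{LogLinearFit} objects are attached as attribute
#'   \code{"fits"}.
#' @export
modelComparison <- function(t, ciLevel = 0.95) {
  stopifnot(is(t, "CaptureHistoryTable"))
  k <- t@k
  specs <- list(list("M0", "none"), list("Mt", "none"))
  if (k >= 3L) {
    for (m in c("Mh", "Mth")) {
      for (v in .hetVariants) specs <- c(specs, list(list(m, v)))
    }
  }
  fits <- lapply(specs, function(s) {
    tryCatch(fitLogLinear(t, s[[1L]], s[[2L]], ciLevel = ciLevel),
             error = function(e) e)
  })
  labels <- vapply(specs, function(s) {
    if (s[[2L]] == "none") s[[1L]] else paste0(s[[1L]], ".", s[[2L]])
  }, character(1))
  rows <- mapply(function(fit, s) {
    if (inherits(fit, "error")) {
      data.frame(model = s[[1L]], variant = s[[2L]], Nhat = NA_real_,
                 se = NA_real_, ciLo = NA_real_, ciHi = NA_real_,
                 aic = NA_real_, bic = NA_real_, np = NA_integer_,
                 lowerBound = identical(s[[2L]], "chao"),
                 note = conditionMessage(fit), stringsAsFactors = FALSE)
    } else {
      data.frame(model = fit@modelClass, variant = fit@variant,
                 Nhat = fit@Nhat, se = fit@se, ciLo = fit@ci[1L],
                 ciHi = fit@ci[2L], aic = fit@aic, bic = fit@bic,
                 np = fit@np, lowerBound = fit@isLowerBound,
                 note = paste(fit@notes, collapse = "; "),
                 stringsAsFactors = FALSE)
    }
  }, fits, specs, SIMPLIFY = FALSE)
  d <- do.call(rbind, rows)
  rownames(d) <- labels
  ord <- order(d$aic, d$bic, d$np, na.last = TRUE)
  d <- d[ord, , drop = FALSE]
  fits <- lapply(fits, function(f) if (inherits(f, "error")) NULL else f)
  names(fits) <- labels
  attr(d, "fits") <- fits[rownames(d)]
  d
}

#' @describeIn fitLogLinear population size estimate.
#' @param x a \code{LogLinearFit}.
#' @export
setMethod("popEstimate", "LogLinearFit", function(x) x@Nhat)

#' @describeIn fitLogLinear interval estimate.
#' @export
setMethod("confInt", "LogLinearFit", function(x) {
  stats::setNames(x@ci, c("lower", "upper"))
})

setMethod("show", "LogLinearFit", function(object) {
  lab <- if (object@variant == "none") object@modelClass else
    paste0(object@modelClass, " (", object@variant, ")")
  role <- if (object@isLowerBound) "lower bound" else "estimate"
  cat(sprintf("Log-linear %s: population size %s %.1f (SE %.1f)\n",
              lab, role, object@Nhat, object@se))
  cat(sprintf("  %g%% CI [%.1f, %.1f]   AIC %.2f  BIC %.2f  n = %d, k = %d\n",
              100 * object@ciLevel, object@ci[1L], object@ci[2L],
              object@aic, object@bic, object@n, object@k))
  if (!is.na(object@sigmah)) {
    cat(sprintf("  logit-normal mixing SD: %.4f\n", object@sigmah))
  }
  if (length(object@notes)) cat("  note:", object@notes, "\n")
})
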