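#' @include loglinear.R
NULL

#' Chao lower bound on the population size
#'
#' Moment-based lower bound from the singleton and doubleton capture
#' frequencies: \eqn{\hat N = n + f_1^2 / (2 f_2)} when \eqn{f_2 > 0}, and
#' the bias-corrected \eqn{n + f_1(f_1 - 1)/(2(f_2 + 1))} otherwise. The
#' standard error uses Chao's (1987) variance formula and the interval is the
#' usual log-transformed one, bounded below by \eqn{n}. This is a lower bound
#' on the population size rather than an estimate of it. The log-linear Chao
#' variant (\code{fitLogLinear(t, "Mh", "chao")}) reproduces the same value
#' through its unobserved-cell extrapolation.
#'
#' @param t a \linkS4class{CaptureHistoryTable}.
#' @param ciLevel interval level.
#' @return A \linkS4class{LogLinearFit} with \code{isLowerBound = TRUE}.
#' @examples
#' chaoLowerBound(CaptureHistoryTable(c("100" = 30, "010" = 80, "111" = 10)))
#' @export
chaoLowerBound <- function(t, ciLevel = 0.95) {
  stopifnot(is(t, "CaptureHistoryTable"))
  d <- descriptiveStats(t)
  n <- d@n
  f1 <- d@fi[1L]
  f2 <- if (d@k >= 2L) d@fi[2L] else 0L
  notes <- character(0)
  z <- stats::qnorm(1 - (1 - ciLevel) / 2)
  if (f1 == 0L) {
    crcWarn("no singletons (f1 = 0): every individual was recaptured; the lower bound equals n")
    return(new("LogLinearFit", modelClass = "Mh", variant = "chao",
               coefficients = numeric(0), Nhat = as.numeric(n), se = 0,
               ci = c(as.numeric(n), as.numeric(n)), ciLevel = ciLevel,
               aic = NA_real_, bic = NA_real_, loglik = NA_real_,
               fitted = as.numeric(t@counts), converged = TRUE,
               isLowerBound = TRUE, n = n, k = t@k, np = NA_integer_,
               sigmah = NA_real_, notes = "f1 = 0; zero-width bound"))
  }
  if (f2 > 0L) {
    N0 <- f1^2 / (2 * f2)
    r <- f1 / f2
    varN <- f2 * (r^4 / 4 + r^3 + r^2 / 2)
  } else {
    N0 <- f1 * (f1 - 1) / (2 * (f2 + 1))
    Nhat <- n + N0
    varN <- f1 * (f1 - 1) / 2 + f1 * (2 * f1 - 1)^2 / 4 - f1^4 / (4 * Nhat)
    notes <- c(notes, "f2 = 0: bias-corrected form used")
  }
  Nhat <- n + N0
  se <- sqrt(max(varN, 0))
  ## Chao's log-transformed interval on T = Nhat - n.
  if (N0 > 0) {
    K <- exp(z * sqrt(log(1 + varN / N0^2)))
    ci <- c(n + N0 / K, n + N0 * K)
  } else {
    ci <- c(as.numeric(n), as.numeric(n))
  }
  new("LogLinearFit", modelClass = "Mh", variant = "chao",
      coefficients = log(N0), Nhat = Nhat, se = se, ci = ci,
      ciLevel = ciLevel, aic = NA_real_, bic = NA_real_, loglik = NA_real_,
      fitted = as.numeric(t@counts), converged = TRUE, isLowerBound = TRUE,
      n = n, k = t@k, np = NA_integer_, sigmah = NA_real_, notes = notes)
}
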