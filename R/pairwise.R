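#' @include loglinear.R
NULL

#' Pairwise two-list diagnostics
#'
#' Marginalizes the capture-history table to each of the \eqn{{k \choose 2}}
#' pairs of events and applies the Chapman estimator
#' \eqn{\hat N = (n_a + 1)(n_b + 1)/(m + 1) - 1} with Seber's variance and a
#' normal 95\% interval truncated below at \eqn{n_a + n_b - m}. Similar
#' estimates across pairs are consistent with list independence; divergent
#' ones suggest the independence assumption is violated.
#'
#' @param t a \linkS4class{CaptureHistoryTable}.
#' @param level interval level.
#' @return Data frame with one row per pair (\code{pa12}, \code{pa13}, ...):
#'   marginal totals \code{nA}, \code{nB}, overlap \code{m}, the Chapman
#'   estimate, its SE and interval, and a note flagging pairs with no
#'   overlap (for which the estimate is only a lower bound).
#' @export
pairwiseAnalysis <- function(t, level = 0.95) {
  stopifnot(is(t, "CaptureHistoryTable"))
  k <- t@k
  P <- t@patterns
  x <- t@counts
  z <- stats::qnorm(1 - (1 - level) / 2)
  pairs <- utils::combn(k, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    na <- sum(x[P[, a] == 1L])
    nb <- sum(x[P[, b] == 1L])
    m <- sum(x[P[, a] == 1L & P[, b] == 1L])
    Nhat <- (na + 1) * (nb + 1) / (m + 1) - 1
    varN <- (na + 1) * (nb + 1) * (na - m) * (nb - m) / ((m + 1)^2 * (m + 2))
    se <- sqrt(varN)
    lo <- max(Nhat - z * se, na + nb - m)
    hi <- Nhat + z * se
    note <- if (m == 0L) "no overlap: lower bound only" else ""
    data.frame(pair = sprintf("pa%d%d", a, b),
               eventA = t@eventNames[a], eventB = t@eventNames[b],
               nA = na, nB = nb, m = m, Nhat = Nhat, se = se,
               ciLo = lo, ciHi = hi, note = note, stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  rownames(d) <- d$pair
  d
}
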