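#' @include AllClasses.R
NULL

#' Descriptive statistics for capture-recapture data
#'
#' Computes the classical closed-population descriptives: per-event totals
#' \eqn{n_j}, capture-frequency counts \eqn{f_i} (individuals captured
#' exactly \eqn{i} times), first-capture counts \eqn{u_j}, and the two
#' diagnostic series used to explore heterogeneity structure:
#' \eqn{(i, \log f_i - \log {k \choose i})}, which is roughly linear except
#' under Mth data, and \eqn{(j, u_j)}, linear under M0 and concave down under
#' Mh.
#'
#' @param t a \linkS4class{CaptureHistoryTable} with at least one observed
#'   individual.
#' @return A \linkS4class{CRCDescriptives} object.
#' @examples
#' t3 <- CaptureHistoryTable(c("100" = 30, "010" = 80, "111" = 10))
#' descriptiveStats(t3)
#' @export
descriptiveStats <- function(t) {
  stopifnot(is(t, "CaptureHistoryTable"))
  if (sum(t@counts) == 0L) {
    crcStop("table has no observed individuals; descriptives are undefined")
  }
  k <- t@k
  P <- t@patterns
  x <- t@counts
  n <- sum(x)
  nj <- as.integer(crossprod(P, x))
  caps <- rowSums(P)
  fi <- vapply(seq_len(k), function(i) sum(x[caps == i]), numeric(1))
  firstEvent <- apply(P == 1L, 1L, which.max)
  ui <- vapply(seq_len(k), function(j) sum(x[firstEvent == j]), numeric(1))
  keep <- fi > 0
  fiSeries <- cbind(i = seq_len(k)[keep],
                    value = log(fi[keep]) - lchoose(k, seq_len(k)[keep]))
  uiSeries <- cbind(j = seq_len(k), u = ui)
  stopifnot(sum(fi) == n, sum(ui) == n, sum(nj) >= n)
  new("CRCDescriptives", k = k, n = as.integer(n), nj = nj,
      fi = as.integer(fi), ui = as.integer(ui),
      fiSeries = fiSeries, uiSeries = uiSeries, eventNames = t@eventNames)
}

#' @describeIn descriptiveStats total observed individuals.
#' @param x a \code{CRCDescriptives} object.
#' @export
setMethod("totalObserved", "CRCDescriptives", function(x) x@n)

#' @describeIn descriptiveStats number of encounter events.
#' @export
setMethod("numEvents", "CRCDescriptives", function(x) x@k)

#' Per-event capture totals
#'
#' @param x a \linkS4class{CRCDescriptives}.
#' @return Named integer vector \eqn{n_j}.
#' @export
eventTotals <- function(x) {
  stopifnot(is(x, "CRCDescriptives"))
  stats::setNames(x@nj, x@eventNames)
}

#' Capture-frequency counts
#'
#' @param x a \linkS4class{CRCDescriptives}.
#' @return Integer vector \eqn{f_i}, \eqn{i = 1..k}.
#' @export
captureFrequencies <- function(x) {
  stopifnot(is(x, "CRCDescriptives"))
  stats::setNames(x@fi, paste0("f", seq_along(x@fi)))
}

#' First-capture counts
#'
#' @param x a \linkS4class{CRCDescriptives}.
#' @return Integer vector \eqn{u_j}, individuals first captured at event j.
#' @export
firstCaptures <- function(x) {
  stopifnot(is(x, "CRCDescriptives"))
  stats::setNames(x@ui, x@eventNames)
}

setMethod("show", "CRCDescriptives", function(object) {
  cat(sprintf("CRC descriptives: k = %d events, n = %d individuals\n",
              object@k, object@n))
  cat("  n_j:", paste(sprintf("%s=%d", object@eventNames, object@nj),
                      collapse = " "), "\n")
  cat("  f_i:", paste(sprintf("f%d=%d", seq_along(object@fi), object@fi),
                      collapse = " "), "\n")
  cat("  u_j:", paste(object@ui, collapse = " "), "\n")
})
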