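#' @include AllClasses.R
NULL

#' Build an aggregated event-count table
#'
#' The event-count format arises in field studies where no identifying
#' information is collected: at each event, observed individuals are tallied
#' only by which of the previous events' unique objects they hold.
#'
#' @param counts list with one element per event; element \eqn{j} holds the
#'   \eqn{2^{j-1}} cell counts named by prior-receipt pattern (binary strings
#'   over events \eqn{1..j-1}; the event-1 element is a single count and may
#'   be unnamed).
#' @param k number of events; defaults to \code{length(counts)}.
#' @param eventNames optional event labels.
#' @return An \linkS4class{EventCountTable}.
#' @examples
#' ec <- EventCountTable(list(40, c("0" = 80, "1" = 10),
#'                            c("00" = 0, "01" = 0, "10" = 0, "11" = 10)))
#' convertEventCounts(ec)
#' @export
EventCountTable <- function(counts, k = NULL, eventNames = NULL) {
  k <- as.integer(k %||% length(counts))
  if (length(counts) != k) crcStop("counts must have one element per event")
  norm <- vector("list", k)
  for (j in seq_len(k)) {
    cj <- counts[[j]]
    expected <- priorPatternStrings(j)
    if (j == 1L) {
      # single cell; the empty prior-receipt pattern needs no name
      if (length(cj) != 1L) {
        crcStop("event 1 must supply a single count (no previous events)")
      }
      cj <- stats::setNames(unname(cj), "")
    } else {
      if (is.null(names(cj)) || !setequal(names(cj), expected) ||
          anyDuplicated(names(cj))) {
        crcStop(sprintf(
          "event %d must supply exactly the %d prior-receipt cells (%s)",
          j, 2^(j - 1), paste(sprintf("'%s'", expected), collapse = ", ")))
      }
      cj <- cj[expected]
    }
    v <- asCount(unname(cj), sprintf("event %d", j))
    if (any(v < 0L)) {
      bad <- which(v < 0L)[1L]
      crcStop(sprintf("event %d, prior pattern '%s': negative count",
                      j, expected[bad]))
    }
    norm[[j]] <- stats::setNames(v, expected)
  }
  eventNames <- eventNames %||% paste0("e", seq_len(k))
  new("EventCountTable", k = k, counts = norm,
      eventNames = as.character(eventNames))
}

#' @describeIn EventCountTable number of encounter events.
#' @param x an \code{EventCountTable}.
#' @export
setMethod("numEvents", "EventCountTable", function(x) x@k)

#' @describeIn EventCountTable event labels.
#' @export
setMethod("eventNames", "EventCountTable", function(x) x@eventNames)

#' Per-event cell counts of an event-count table
#'
#' @param x an \linkS4class{EventCountTable}.
#' @return List of named integer vectors, one per event.
#' @export
eventCounts <- function(x) {
  stopifnot(is(x, "EventCountTable"))
  stats::setNames(x@counts, x@eventNames)
}

setMethod("show", "EventCountTable", function(object) {
  cat(sprintf("EventCountTable: %d events, %d cells\n",
              object@k, 2^object@k - 1))
  for (j in seq_len(object@k)) {
    cj <- object@counts[[j]]
    lab <- ifelse(names(cj) == "", "(none)", names(cj))
    cat(sprintf("  %s: %s\n", object@eventNames[j],
                paste(sprintf("%s=%d", lab, cj), collapse = " ")))
  }
})

## Integer code of the history whose 1s are exactly the events named by the
## prior-receipt string s (over events 1..j-1) plus event j itself.
.basePatternCode <- function(s, j, k) {
  code <- bitwShiftL(1L, k - j)
  if (nchar(s)) {
    bits <- as.integer(strsplit(s, "")[[1L]])
    code <- code + sum(bits * 2^(k - seq_len(j - 1L)))
  }
  as.integer(code)
}

#' Convert aggregated event counts to capture histories
#'
#' Inverts the event-count aggregation exactly by backward recursion over
#' events \eqn{j = k, \dots, 1}: the event-\eqn{j} cell for prior-receipt
#' pattern \eqn{S} totals every history that shows \eqn{S} before event
#' \eqn{j}, a capture at \eqn{j}, and anything afterwards, so subtracting the
#' already-resolved later histories isolates the history with 1s exactly at
#' \eqn{S \cup \{j\}}. The conversion is the exact inverse of
#' \code{\link{eventCountsFromHistories}}.
#'
#' @param ec an \linkS4class{EventCountTable}.
#' @return A \linkS4class{CaptureHistoryTable} over the same events.
#' @examples
#' ec <- EventCountTable(list(40, c("0" = 80, "1" = 10),
#'                            c("00" = 0, "01" = 0, "10" = 0, "11" = 10)))
#' historyCounts(convertEventCounts(ec))
#' @export
convertEventCounts <- function(ec) {
  stopifnot(is(ec, "EventCountTable"))
  k <- ec@k
  x <- integer(2^k - 1L)  # indexed by history code
  for (j in rev(seq_len(k))) {
    cj <- ec@counts[[j]]
    for (ci in seq_along(cj)) {
      s <- names(cj)[ci]
      base <- .basePatternCode(s, j, k)
      nFuture <- 2^(k - j) - 1L
      later <- if (nFuture > 0L) sum(x[base + seq_len(nFuture)]) else 0L
      val <- cj[[ci]] - later
      if (val < 0L) {
        crcStop(sprintf(
          paste0("inconsistent event counts at event %d, prior pattern '%s': ",
                 "derived history count %d is negative (recording error or ",
                 "identifier loss?)"),
          j, if (nzchar(s)) s else "(none)", val))
      }
      x[base] <- val
    }
  }
  ref <- patternMatrix(k)
  counts <- x[patternCode(ref)]
  suppressWarnings(
    tab <- CaptureHistoryTable(counts, patternToString(ref), k = k,
                               eventNames = ec@eventNames)
  )
  nj <- descriptiveStats(tab)@nj
  if (sum(nj) < totalObserved(tab)) {
    crcWarn("per-event totals sum to less than the number of individuals")
  }
  tab
}

#' Aggregate capture histories into event-count format
#'
#' Forward aggregation: the event-\eqn{j} cell for prior-receipt pattern
#' \eqn{S} is the total count of histories captured at \eqn{j}, matching
#' \eqn{S} on earlier events, with any future behaviour.
#'
#' @param t a \linkS4class{CaptureHistoryTable}.
#' @return An \linkS4class{EventCountTable}; round-trips exactly through
#'   \code{\link{convertEventCounts}}.
#' @export
eventCountsFromHistories <- function(t) {
  stopifnot(is(t, "CaptureHistoryTable"))
  k <- t@k
  x <- integer(2^k - 1L)
  x[patternCode(t@patterns)] <- t@counts
  counts <- vector("list", k)
  for (j in seq_len(k)) {
    cells <- priorPatternStrings(j)
    vals <- vapply(cells, function(s) {
      base <- .basePatternCode(s, j, k)
      sum(x[base + 0:(2^(k - j) - 1L)])
    }, integer(1))
    counts[[j]] <- stats::setNames(as.integer(vals), cells)
  }
  new("EventCountTable", k = k, counts = counts, eventNames = t@eventNames)
}
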