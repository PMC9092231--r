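#' @include AllClasses.R
NULL

#' Build and validate a capture-history table
#'
#' Constructs a \linkS4class{CaptureHistoryTable} from pattern/count records.
#' Analysis requires all \eqn{2^k - 1} observable histories to be present;
#' observable patterns absent from the input are filled with an explicit zero
#' count and reported in a warning (the data may contain observed zeros but
#' not missing values). The all-zero pattern is the unobservable cell and must
#' not appear.
#'
#' @param counts integer counts, one per supplied pattern. A named vector may
#'   be given, in which case \code{patterns} defaults to its names.
#' @param patterns character vector of length-\code{k} binary strings (e.g.
#'   \code{"100"}; leftmost character = event 1) or a 0/1 matrix with one row
#'   per pattern.
#' @param k number of encounter events; inferred from the patterns when
#'   omitted.
#' @param eventNames optional event labels (default \code{e1..ek}).
#' @return A validated \linkS4class{CaptureHistoryTable}.
#' @examples
#' t3 <- CaptureHistoryTable(c("100" = 30, "010" = 80, "111" = 10))
#' totalObserved(t3)
#' @export
CaptureHistoryTable <- function(counts, patterns = names(counts), k = NULL,
                                eventNames = NULL) {
  if (is.null(patterns)) {
    crcStop("patterns must be supplied (or counts must be named)")
  }
  if (is.matrix(patterns) || is.data.frame(patterns)) {
    patterns <- patternToString(as.matrix(patterns))
  }
  patterns <- as.character(patterns)
  if (length(patterns) != length(counts)) {
    crcStop("patterns and counts must have the same length")
  }
  if (length(patterns) == 0L && is.null(k)) {
    crcStop("k must be given when no rows are supplied")
  }
  if (any(grepl("[^01]", patterns))) {
    bad <- which(grepl("[^01]", patterns))[1L]
    crcStop(sprintf("row %d: pattern '%s' is not a binary string",
                    bad, patterns[bad]))
  }
  k <- as.integer(k %||% nchar(patterns[1L]))
  if (k < 2L) crcStop("at least 2 encounter events are required")
  if (length(patterns) && any(nchar(patterns) != k)) {
    bad <- which(nchar(patterns) != k)[1L]
    crcStop(sprintf("row %d: pattern '%s' does not have length k = %d",
                    bad, patterns[bad], k))
  }
  counts <- asCount(counts)
  if (any(counts < 0L)) {
    bad <- which(counts < 0L)[1L]
    crcStop(sprintf("row %d (pattern '%s'): negative count %d",
                    bad, patterns[bad], counts[bad]))
  }
  zero <- strrep("0", k)
  if (zero %in% patterns) {
    crcStop(paste0("the all-zero history '", zero, "' is the unobserved cell ",
                   "and must not appear in the data"))
  }
  if (anyDuplicated(patterns)) {
    dup <- patterns[duplicated(patterns)][1L]
    crcStop(sprintf("duplicate pattern '%s' supplied", dup))
  }
  ref <- patternMatrix(k)
  refStr <- patternToString(ref)
  full <- integer(length(refStr))
  names(full) <- refStr
  full[patterns] <- counts
  filled <- setdiff(refStr, patterns)
  if (length(filled)) {
    crcWarn(sprintf(
      "%d observable histories absent from input, filled with 0: %s",
      length(filled), paste(filled, collapse = ", ")))
  }
  if (sum(full) == 0L) {
    crcWarn("table has no observed individuals (all counts are zero)")
  }
  eventNames <- eventNames %||% paste0("e", seq_len(k))
  new("CaptureHistoryTable", k = k, patterns = ref, counts = unname(full),
      eventNames = as.character(eventNames), filled = filled)
}

#' Aggregate individual-level records into a capture-history table
#'
#' Individual-level data have one row per observed individual and one 0/1
#' column per encounter event. Individuals never captured are unobservable, so
#' an all-zero row is an error.
#'
#' @param records 0/1 matrix or data frame, one row per individual.
#' @param k number of events; defaults to \code{ncol(records)}.
#' @param eventNames optional event labels.
#' @return A \linkS4class{CaptureHistoryTable} whose counts are the pattern
#'   multiplicities; the total count equals \code{nrow(records)}.
#' @export
aggregateIndividuals <- function(records, k = NULL, eventNames = NULL) {
  records <- as.matrix(records)
  k <- as.integer(k %||% ncol(records))
  if (nrow(records) == 0L) {
    return(CaptureHistoryTable(integer(0), character(0), k = k,
                               eventNames = eventNames))
  }
  if (ncol(records) != k) crcStop("records must have one column per event")
  storage.mode(records) <- "integer"
  if (anyNA(records) || !all(records %in% c(0L, 1L))) {
    crcStop("records entries must be 0 or 1 with no missing values")
  }
  zeroRows <- which(rowSums(records) == 0L)
  if (length(zeroRows)) {
    crcStop(sprintf(
      "row %d is all zeros: individuals never captured are unobservable",
      zeroRows[1L]))
  }
  s <- patternToString(records)
  tab <- table(s)
  suppressWarnings(
    CaptureHistoryTable(as.integer(tab), names(tab), k = k,
                        eventNames = eventNames)
  )
}

#' @describeIn CaptureHistoryTable number of encounter events.
#' @param x a \code{CaptureHistoryTable}.
#' @export
setMethod("numEvents", "CaptureHistoryTable", function(x) x@k)

#' @describeIn CaptureHistoryTable event labels.
#' @export
setMethod("eventNames", "CaptureHistoryTable", function(x) x@eventNames)

#' @describeIn CaptureHistoryTable counts named by pattern string, canonical
#'   order.
#' @export
setMethod("historyCounts", "CaptureHistoryTable", function(x) {
  stats::setNames(x@counts, patternToString(x@patterns))
})

#' @describeIn CaptureHistoryTable total distinct observed individuals
#'   \eqn{n}.
#' @export
setMethod("totalObserved", "CaptureHistoryTable", function(x) sum(x@counts))

#' Pattern matrix of a capture-history table
#'
#' @param x a \linkS4class{CaptureHistoryTable}.
#' @return Integer 0/1 matrix of the observable histories, canonical order.
#' @export
historyPatterns <- function(x) {
  stopifnot(is(x, "CaptureHistoryTable"))
  p <- x@patterns
  dimnames(p) <- list(patternToString(p), x@eventNames)
  p
}

setMethod("show", "CaptureHistoryTable", function(object) {
  cat(sprintf("CaptureHistoryTable: %d events, %d observable histories, n = %d\n",
              object@k, nrow(object@patterns), sum(object@counts)))
  cat("events:", paste(object@eventNames, collapse = ", "), "\n")
  cnt <- historyCounts(object)
  show <- utils::head(cnt[order(-cnt)], 8L)
  cat("top cells:", paste(sprintf("%s=%d", names(show), show), collapse = " "), "\n")
  if (length(object@filled)) {
    cat(sprintf("(%d absent histories filled with 0)\n", length(object@filled)))
  }
})
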