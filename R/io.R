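#' @include AllClasses.R
NULL

## Sniff comma vs tab; both dialects are accepted by every reader.
.readDelimited <- function(file, colClasses = NA) {
  if (!file.exists(file)) {
    crcStop(sprintf("cannot read input file '%s'", file), "crcIOError")
  }
  first <- readLines(file, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(file, header = TRUE, sep = sep, colClasses = colClasses,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read capture-recapture data from a delimited file
#'
#' Three dialects are supported. \code{"history"}: header
#' \code{e1,...,ek,count}, one row per capture history. \code{"individual"}:
#' header \code{e1,...,ek}, one 0/1 row per observed individual.
#' \code{"eventcount"}: header \code{event,pattern,count} where
#' \code{pattern} is the prior-receipt pattern as a binary string over the
#' previous events (empty for event 1). Comma and tab delimiters are both
#' accepted.
#'
#' @param file path to a CSV/TSV file.
#' @param format input dialect.
#' @param eventNames optional event labels (defaults to the file's headers
#'   where available).
#' @return A \linkS4class{CaptureHistoryTable} (an
#'   \linkS4class{EventCountTable} for \code{format = "eventcount"} when
#'   \code{convert = FALSE}).
#' @param convert for \code{"eventcount"} input, convert to a capture-history
#'   table (default) or return the \linkS4class{EventCountTable}.
#' @export
readCaptureData <- function(file,
                            format = c("history", "individual", "eventcount"),
                            eventNames = NULL, convert = TRUE) {
  format <- match.arg(format)
  d <- .readDelimited(file, colClasses = if (format == "eventcount")
    c("integer", "character", "integer") else NA)
  if (format == "history") {
    if (ncol(d) < 3L || !"count" %in% names(d)) {
      crcStop("history input needs k event columns plus a 'count' column")
    }
    ev <- setdiff(names(d), "count")
    pat <- patternToString(as.matrix(d[ev]))
    CaptureHistoryTable(d$count, pat, k = length(ev),
                        eventNames = eventNames %||% ev)
  } else if (format == "individual") {
    aggregateIndividuals(as.matrix(d), eventNames = eventNames %||% names(d))
  } else {
    need <- c("event", "pattern", "count")
    if (!all(need %in% names(d))) {
      crcStop("eventcount input needs columns event, pattern, count")
    }
    d$pattern[is.na(d$pattern)] <- ""
    k <- max(d$event)
    counts <- lapply(seq_len(k), function(j) {
      rows <- d[d$event == j, , drop = FALSE]
      stats::setNames(rows$count, rows$pattern)
    })
    ec <- EventCountTable(counts, k = k, eventNames = eventNames)
    if (convert) convertEventCounts(ec) else ec
  }
}

#' Write a capture-history table as CSV
#'
#' Always writes the full \eqn{2^k - 1} observable histories (explicit zeros,
#' never missing rows), in lexicographic pattern order.
#'
#' @param t a \linkS4class{CaptureHistoryTable}.
#' @param file output path.
#' @param sep field separator.
#' @return \code{file}, invisibly.
#' @export
writeHistoryCSV <- function(t, file, sep = ",") {
  stopifnot(is(t, "CaptureHistoryTable"))
  cnt <- historyCounts(t)
  cnt <- cnt[order(names(cnt))]
  pat <- stringToPattern(names(cnt))
  d <- as.data.frame(pat)
  names(d) <- t@eventNames
  d$count <- unname(cnt)
  utils::write.table(d, file, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write an event-count table as CSV
#'
#' Columns \code{event,pattern,count}; patterns in lexicographic order within
#' each event.
#'
#' @param ec an \linkS4class{EventCountTable}.
#' @param file output path.
#' @param sep field separator.
#' @return \code{file}, invisibly.
#' @export
writeEventCountCSV <- function(ec, file, sep = ",") {
  stopifnot(is(ec, "EventCountTable"))
  rows <- do.call(rbind, lapply(seq_len(ec@k), function(j) {
    cj <- ec@counts[[j]]
    data.frame(event = j, pattern = names(cj), count = unname(cj),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, file, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @describeIn exportJSON JSON mirror of a capture-history table.
#' @export
setMethod("exportJSON", "CaptureHistoryTable", function(x, file = NULL) {
  obj <- list(type = "history", k = x@k, eventNames = x@eventNames,
              patterns = patternToString(x@patterns), counts = x@counts)
  .emitJSON(obj, file)
})

#' @describeIn exportJSON JSON mirror of an event-count table.
#' @export
setMethod("exportJSON", "EventCountTable", function(x, file = NULL) {
  obj <- list(type = "eventcount", k = x@k, eventNames = x@eventNames,
              events = lapply(x@counts, function(cj)
                list(patterns = names(cj), counts = unname(cj))))
  .emitJSON(obj, file)
})

.emitJSON <- function(obj, file) {
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(js)
}

#' Read a JSON mirror of a capture-recapture table
#'
#' Accepts the JSON written by \code{\link{exportJSON}} for either table type
#' (field \code{type} of \code{"history"} or \code{"eventcount"}).
#'
#' @param file path to a JSON file.
#' @return A \linkS4class{CaptureHistoryTable} or
#'   \linkS4class{EventCountTable}.
#' @export
importCaptureJSON <- function(file) {
  if (!file.exists(file)) {
    crcStop(sprintf("cannot read input file '%s'", file), "crcIOError")
  }
  obj <- jsonlite::fromJSON(file, simplifyVector = TRUE)
  if (identical(obj$type, "history")) {
    CaptureHistoryTable(obj$counts, obj$patterns, k = obj$k,
                        eventNames = obj$eventNames)
  } else if (identical(obj$type, "eventcount")) {
    ev <- obj$events
    counts <- lapply(seq_len(obj$k), function(j)
      stats::setNames(ev$counts[[j]], ev$patterns[[j]]))
    EventCountTable(counts, k = obj$k, eventNames = obj$eventNames)
  } else {
    crcStop("JSON input must carry type 'history' or 'eventcount'")
  }
}
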