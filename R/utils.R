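## Internal helpers shared across the package.

expit <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p) - log1p(-p)

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Classed conditions so the CLI can map failures to distinct exit codes.
crcStop <- function(msg, class = "crcValidationError", call. = FALSE) {
  stop(structure(
    class = c(class, "crcError", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

crcWarn <- function(msg, class = "crcWarning") {
  warning(structure(
    class = c(class, "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

## Canonical enumeration of the 2^k - 1 observable capture histories.
## Patterns are 0/1 vectors, leftmost entry = event 1. Internal order is by
## number of captures, then by the pattern read as a binary number, descending
## (so for k = 3: 100, 010, 001, 110, 101, 011, 111).
patternMatrix <- function(k) {
  stopifnot(k >= 1, k <= 16)
  v <- seq_len(2^k - 1)
  m <- matrix(0L, length(v), k)
  for (j in seq_len(k)) {
    m[, j] <- bitwAnd(bitwShiftR(v, k - j), 1L)
  }
  ord <- order(rowSums(m), -v)
  m[ord, , drop = FALSE]
}

patternToString <- function(m) {
  apply(m, 1L, paste0, collapse = "")
}

stringToPattern <- function(s) {
  t(vapply(strsplit(s, ""), function(ch) as.integer(ch), integer(nchar(s[[1]]))))
}

## Integer code of a pattern: event j contributes bit (k - j), so the code is
## the pattern string read as a binary number.
patternCode <- function(m) {
  k <- ncol(m)
  as.integer(m %*% 2^((k - 1):0))
}

## Gauss-Hermite nodes/weights rescaled for E[f(eps)], eps ~ N(0, sigma^2):
## E f = sum(w * f(sigma * x)).
ghNormal <- local({
  cache <- list()
  function(nodes = 20L) {
    key <- as.character(nodes)
    if (is.null(cache[[key]])) {
      gh <- pracma::gaussHermite(nodes)
      cache[[key]] <<- list(x = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
    }
    cache[[key]]
  }
})

## Strict integer coercion for count data: floats are rejected, counts of
## people cannot be fractional.
asCount <- function(x, what = "count") {
  if (is.character(x)) {
    xn <- suppressWarnings(as.numeric(x))
    if (anyNA(xn) && !anyNA(x)) {
      crcStop(sprintf("%s values must be parseable as integers", what))
    }
    x <- xn
  }
  if (anyNA(x)) crcStop(sprintf("%s values must not be missing", what))
  if (any(x != round(x))) {
    crcStop(sprintf("%s values must be whole numbers (got non-integer)", what))
  }
  as.integer(round(x))
}
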