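# Fixtures are built in code; nothing is read from disk unless a test writes
# it first.

# The worked 3-event example: 30 seen only at event 1, 80 only at event 2,
# 10 at all three.
workedHistoryTable <- function() {
  suppressWarnings(
    CaptureHistoryTable(c("100" = 30, "010" = 80, "111" = 10))
  )
}

# The same study in aggregated event-count form: 40 at event 1; at event 2,
# 10 holding the event-1 object and 80 not; at event 3, 10 holding both
# prior objects and none in the other cells.
workedEventCounts <- function() {
  EventCountTable(list(
    40,
    c("0" = 80, "1" = 10),
    c("00" = 0, "01" = 0, "10" = 0, "11" = 10)
  ))
}

# A well-behaved near-independent 3-list table (n = 150).
indepTable <- function() {
  suppressWarnings(CaptureHistoryTable(c(
    "100" = 35, "010" = 31, "001" = 34, "110" = 14, "101" = 16,
    "011" = 14, "111" = 6)))
}

# Random complete table with strictly positive overlap structure.
randomHistoryTable <- function(k, lambda = 8) {
  pat <- apply(crcsize:::patternMatrix(k), 1L, paste0, collapse = "")
  counts <- rpois(length(pat), lambda) + 1L
  suppressWarnings(CaptureHistoryTable(counts, pat, k = k))
}

# Permute the events of a table (event j of the result is event perm[j] of
# the input).
permuteEvents <- function(t, perm) {
  cnt <- historyCounts(t)
  pat <- do.call(rbind, strsplit(names(cnt), ""))[, perm, drop = FALSE]
  suppressWarnings(
    CaptureHistoryTable(unname(cnt), apply(pat, 1L, paste0, collapse = ""))
  )
}

# Canonical form of a decomposable-model label under an event relabeling:
# apply the map to each clique, sort within and across cliques.
relabelledModelLabel <- function(model, map) {
  cl <- lapply(model@cliques, function(C) sort(map[C]))
  cl <- cl[order(vapply(cl, paste, character(1), collapse = ","))]
  paste0(vapply(cl, function(C)
    paste0("[", paste(C, collapse = ","), "]"), character(1)), collapse = "")
}

canonicalModelLabel <- function(model) {
  relabelledModelLabel(model, seq_len(model@k))
}
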