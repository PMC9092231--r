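test_that("sparse input is zero-filled with a warning naming the absent cells", {
  w <- capture_warnings(
    tab <- CaptureHistoryTable(c("100" = 30, "010" = 80, "111" = 10))
  )
  expect_match(w, "4 observable histories absent", all = FALSE)
  expect_length(historyCounts(tab), 7L)
  expect_identical(sum(historyCounts(tab) == 0L), 4L)
  expect_identical(unname(historyCounts(tab)["100"]), 30L)
  expect_setequal(tab@filled, c("001", "110", "101", "011"))
})

test_that("invalid pattern/count records are rejected with informative errors", {
  expect_error(CaptureHistoryTable(c("000" = 5)), "all-zero history",
               class = "crcValidationError")
  expect_error(CaptureHistoryTable(c(1, 2), c("10", "10")), "duplicate",
               class = "crcValidationError")
  expect_error(suppressWarnings(CaptureHistoryTable(c("10" = -1))),
               "row 1.*negative", class = "crcValidationError")
  expect_error(CaptureHistoryTable(c("1001" = 2), k = 3), "length k",
               class = "crcValidationError")
  expect_error(CaptureHistoryTable(c("10x" = 2)), "binary",
               class = "crcValidationError")
  expect_error(suppressWarnings(CaptureHistoryTable(c("10" = 1.5))),
               "whole numbers", class = "crcValidationError")
})

test_that("a table on k events exposes exactly 2^k - 1 observable histories", {
  for (k in 2:5) {
    tab <- randomHistoryTable(k)
    expect_identical(nrow(historyPatterns(tab)), as.integer(2^k - 1))
    expect_false(any(duplicated(rownames(historyPatterns(tab)))))
    expect_true(all(rowSums(historyPatterns(tab)) >= 1L))
  }
})

test_that("individual records aggregate to pattern multiplicities", {
  rec <- rbind(
    matrix(rep(c(1L, 0L, 0L), 30), ncol = 3, byrow = TRUE),
    matrix(rep(c(0L, 1L, 0L), 80), ncol = 3, byrow = TRUE),
    matrix(rep(c(1L, 1L, 1L), 10), ncol = 3, byrow = TRUE))
  tab <- aggregateIndividuals(rec)
  expect_identical(unname(historyCounts(tab)[c("100", "010", "111")]),
                   c(30L, 80L, 10L))
  expect_identical(totalObserved(tab), 120L)

  expect_error(aggregateIndividuals(rbind(c(1L, 0L), c(0L, 0L))),
               "row 2 is all zeros", class = "crcValidationError")

  w <- capture_warnings(empty <- aggregateIndividuals(matrix(0L, 0, 3), k = 3))
  expect_match(w, "absent|no observed", all = FALSE)
  expect_identical(totalObserved(empty), 0L)
})

test_that("aggregation of random records conserves the row total (enumeration oracle)", {
  set.seed(42)
  rec <- matrix(rbinom(1000 * 4, 1, 0.4), ncol = 4)
  rec <- rec[rowSums(rec) > 0, , drop = FALSE]
  rec <- rec[rep(seq_len(nrow(rec)), length.out = 1000), ]  # exactly 1000 rows
  tab <- aggregateIndividuals(rec)
  expect_identical(totalObserved(tab), 1000L)
  # independent enumeration: count each pattern string directly
  direct <- table(apply(rec, 1L, paste0, collapse = ""))
  for (p in names(direct)) {
    expect_identical(unname(historyCounts(tab)[p]), as.integer(direct[[p]]))
  }
})

test_that("descriptives match direct counting and satisfy their identities", {
  d <- descriptiveStats(workedHistoryTable())
  expect_identical(d@n, 120L)
  expect_identical(d@fi, c(110L, 0L, 10L))
  expect_identical(d@ui, c(40L, 80L, 0L))
  expect_identical(d@nj, c(40L, 90L, 10L))
  # f_i = 0 rows are dropped from the log-frequency series (log undefined)
  expect_identical(d@fiSeries[, "i"], c(1, 3))

  d2 <- descriptiveStats(suppressWarnings(CaptureHistoryTable(c("11" = 5))))
  expect_identical(d2@n, 5L)
  expect_identical(d2@fi, c(0L, 5L))
  expect_identical(d2@ui, c(5L, 0L))

  set.seed(7)
  for (k in 2:4) {
    tab <- randomHistoryTable(k)
    dd <- descriptiveStats(tab)
    expect_identical(sum(dd@fi), dd@n)
    expect_identical(sum(dd@ui), dd@n)
    expect_identical(sum(dd@nj), sum(seq_len(k) * dd@fi))
    expect_gte(sum(dd@nj), dd@n)
  }
  # equality of sum(n_j) and n holds exactly when nobody is recaptured
  one <- suppressWarnings(CaptureHistoryTable(c("100" = 3, "010" = 2), k = 3))
  do <- descriptiveStats(one)
  expect_identical(sum(do@nj), do@n)

  expect_error(descriptiveStats(
    suppressWarnings(CaptureHistoryTable(integer(0), character(0), k = 3))),
    "no observed", class = "crcValidationError")
})
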