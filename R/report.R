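#' @include samplesize.R
#' @include bma.R
#' @include diagnostics.R
NULL

#' Run every analysis and collect a reproducible report
#'
#' Applies the full analysis battery to a capture-history table: descriptive
#' statistics, the log-linear model comparison, pairwise Chapman diagnostics,
#' Bayesian model averaging (for \eqn{3 \le k \le 5}) and the latent-class
#' sampler. The returned report echoes the configuration (including the
#' seed) needed to reproduce every stochastic step.
#'
#' @param t a \linkS4class{CaptureHistoryTable}.
#' @param level confidence/credible level used throughout.
#' @param seed integer seed for the stochastic components.
#' @param prior \linkS4class{PriorSpec} for the model-averaged posterior.
#' @param lcmcr named list of overrides for \code{\link{runLCMCR}} settings.
#' @return A list of class \code{"crcReport"}; see
#'   \code{\link{writeReport}}.
#' @export
analysisReport <- function(t, level = 0.95, seed = 1L,
                           prior = noninformativePrior(), lcmcr = list()) {
  stopifnot(is(t, "CaptureHistoryTable"))
  d <- descriptiveStats(t)
  comparison <- modelComparison(t, ciLevel = level)
  pairwise <- pairwiseAnalysis(t, level = level)
  bma <- NULL
  if (t@k >= 3L && t@k <= 5L) {
    b <- bmaPosterior(t, prior = prior, level = level)
    bma <- list(mean = b@mean, median = b@median,
                lower = b@ci[1L], upper = b@ci[2L], level = level,
                delta = b@delta, prior = b@prior@kind,
                topModels = utils::head(sort(modelProbabilities(b),
                                             decreasing = TRUE), 5L))
  }
  lcArgs <- utils::modifyList(
    list(samples = 5000L, burnin = 5000L, thinning = 5L, maxClasses = 10L,
         shape = 0.25, scale = 0.25),
    lcmcr)
  lc <- do.call(runLCMCR, c(list(t = t, seed = seed), lcArgs))
  lcSummary <- posteriorSummary(lc, level = level)
  lcSummary$ess <- effectiveSampleSize(lc)
  report <- list(
    tool = list(package = "crcsize",
                version = as.character(utils::packageVersion("crcsize"))),
    input = list(k = t@k, eventNames = t@eventNames,
                 n = totalObserved(t),
                 histories = as.list(historyCounts(t))),
    descriptives = list(nj = as.list(eventTotals(d)),
                        fi = as.list(captureFrequencies(d)),
                        ui = unname(firstCaptures(d))),
    loglinear = cbind(spec = rownames(comparison), comparison),
    pairwise = pairwise,
    bma = bma,
    lcmcr = c(lcSummary, list(config = lc@config)),
    config = list(level = level, seed = seed, lcmcr = lcArgs)
  )
  class(report) <- "crcReport"
  report
}

#' Write an analysis report
#'
#' Serializes a report from \code{\link{analysisReport}} as JSON (machine
#' readable, validating against the schema shipped in
#' \code{inst/schema/analysis-report.schema.json}) or markdown (human
#' readable tables).
#'
#' @param report a \code{"crcReport"}.
#' @param file output path; when \code{NULL} the text is returned.
#' @param format \code{"json"} or \code{"markdown"}.
#' @return The serialized text, invisibly when written to \code{file}.
#' @export
writeReport <- function(report, file = NULL, format = c("json", "markdown")) {
  stopifnot(inherits(report, "crcReport"))
  format <- match.arg(format)
  txt <- if (format == "json") {
    jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                     pretty = TRUE, dataframe = "rows", na = "null")
  } else {
    .reportMarkdown(report)
  }
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

.mdTable <- function(d, digits = 2) {
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], function(x) round(x, digits))
  header <- paste0("| ", paste(names(d), collapse = " | "), " |")
  rule <- paste0("|", paste(rep("---", ncol(d)), collapse = "|"), "|")
  body <- apply(d, 1L, function(r)
    paste0("| ", paste(trimws(as.character(r)), collapse = " | "), " |"))
  c(header, rule, unname(body))
}

.reportMarkdown <- function(report) {
  out <- c(
    sprintf("# Capture-recapture analysis report (crcsize %s)",
            report$tool$version),
    "",
    sprintf("Input: %d events (%s), n = %d observed individuals.",
            report$input$k, paste(report$input$eventNames, collapse = ", "),
            report$input$n),
    sprintf("Seed: %s. Interval level: %g%%.",
            report$config$seed, 100 * report$config$level),
    "",
    "## Descriptives",
    "",
    sprintf("- per-event totals: %s",
            paste(sprintf("%s=%s", names(report$descriptives$nj),
                          report$descriptives$nj), collapse = ", ")),
    sprintf("- capture frequencies: %s",
            paste(sprintf("%s=%s", names(report$descriptives$fi),
                          report$descriptives$fi), collapse = ", ")),
    "",
    "## Log-linear models",
    "",
    .mdTable(report$loglinear),
    "",
    "## Pairwise diagnostics",
    "",
    .mdTable(report$pairwise)
  )
  if (!is.null(report$bma)) {
    out <- c(out, "",
      "## Bayesian model averaging",
      "",
      sprintf("Posterior mean %.1f, median %.0f, %g%% CrI [%.0f, %.0f] (%s prior, delta %.4g).",
              report$bma$mean, report$bma$median, 100 * report$bma$level,
              report$bma$lower, report$bma$upper, report$bma$prior,
              report$bma$delta),
      sprintf("Top models: %s.",
              paste(sprintf("%s (%.3f)", names(report$bma$topModels),
                            report$bma$topModels), collapse = ", ")))
  }
  out <- c(out, "",
    "## Latent-class model",
    "",
    sprintf("Posterior mean %.1f, median %.0f, %g%% CrI [%.0f, %.0f]; ESS %.0f.",
            report$lcmcr$mean, report$lcmcr$median, 100 * report$lcmcr$level,
            report$lcmcr$lower, report$lcmcr$upper, report$lcmcr$ess),
    sprintf("Sampler: %d samples, %d burn-in, thinning %d, K* = %d.",
            report$lcmcr$config$samples, report$lcmcr$config$burnin,
            report$lcmcr$config$thinning, report$lcmcr$config$maxClasses))
  out
}
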