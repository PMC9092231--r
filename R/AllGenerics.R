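#' @include utils.R
NULL

#' Number of encounter events
#'
#' @param x a capture-recapture object.
#' @return Integer number of encounter events (lists) \code{k}.
#' @export
setGeneric("numEvents", function(x) standardGeneric("numEvents"))

#' Event names
#'
#' @param x a capture-recapture object.
#' @return Character vector of event labels.
#' @export
setGeneric("eventNames", function(x) standardGeneric("eventNames"))

#' Capture-history counts
#'
#' @param x a \linkS4class{CaptureHistoryTable}.
#' @return Integer vector of counts, named by pattern string, over all
#'   \eqn{2^k - 1} observable histories.
#' @export
setGeneric("historyCounts", function(x) standardGeneric("historyCounts"))

#' Total number of distinct observed individuals
#'
#' @param x a capture-recapture object.
#' @return Integer \eqn{n}, the number of individuals seen at least once.
#' @export
setGeneric("totalObserved", function(x) standardGeneric("totalObserved"))

#' Population size estimate
#'
#' @param x a fitted object.
#' @return Numeric point estimate of the population size \eqn{\hat N}.
#' @export
setGeneric("popEstimate", function(x) standardGeneric("popEstimate"))

#' Interval estimate for the population size
#'
#' Confidence interval for likelihood-based fits, equal-tailed credible
#' interval for Bayesian posteriors.
#'
#' @param x a fitted object.
#' @return Named numeric vector \code{c(lower, upper)}; the level is stored in
#'   the object.
#' @export
setGeneric("confInt", function(x) standardGeneric("confInt"))

#' Posterior model probabilities
#'
#' @param x a \linkS4class{BMAPosterior}.
#' @return Named numeric vector of posterior probabilities, one per
#'   decomposable dependence model.
#' @export
setGeneric("modelProbabilities", function(x) standardGeneric("modelProbabilities"))

#' Posterior draws of the population size
#'
#' @param x a \linkS4class{PosteriorDraws}.
#' @return Numeric vector of thinned post-burn-in MCMC draws of \eqn{N}.
#' @export
setGeneric("posteriorDraws", function(x) standardGeneric("posteriorDraws"))

#' Effective sample size of an MCMC chain
#'
#' ESS is \eqn{M / (1 + 2\sum_t \rho_t)} with the autocorrelation sum
#' truncated by Geyer's initial positive sequence rule.
#'
#' @param x numeric chain or a \linkS4class{PosteriorDraws} object.
#' @return A single numeric value in \eqn{(0, M]}.
#' @export
setGeneric("effectiveSampleSize", function(x) standardGeneric("effectiveSampleSize"))

#' Export an object as JSON
#'
#' @param x object to serialize.
#' @param file optional path; when omitted the JSON string is returned.
#' @return The JSON string, invisibly when written to \code{file}.
#' @export
setGeneric("exportJSON", function(x, file = NULL) standardGeneric("exportJSON"))
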