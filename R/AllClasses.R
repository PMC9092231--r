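#' @include AllGenerics.R
NULL

#' Capture-history table
#'
#' Counts over the \eqn{2^k - 1} observable capture histories of \eqn{k}
#' encounter events. The all-zero history (individuals never encountered) is
#' unobservable and is never stored. Patterns are 0/1 vectors with the
#' leftmost position corresponding to event 1 (capture-round order).
#'
#' @slot k integer, number of encounter events (\eqn{\ge 2}).
#' @slot patterns integer matrix, \eqn{(2^k - 1) \times k}, one row per
#'   observable history in canonical order (by number of captures, then by the
#'   pattern read as a binary number, descending).
#' @slot counts integer vector of nonnegative cell counts \eqn{x_h}.
#' @slot eventNames character labels for the events.
#' @slot filled character vector of pattern strings that were absent from the
#'   input and filled with an explicit zero.
#' @export
setClass("CaptureHistoryTable",
  representation(
    k = "integer",
    patterns = "matrix",
    counts = "integer",
    eventNames = "character",
    filled = "character"
  )
)

setValidity("CaptureHistoryTable", function(object) {
  k <- object@k
  if (length(k) != 1L || is.na(k) || k < 2L) {
    return("k must be a single integer >= 2")
  }
  ref <- patternMatrix(k)
  if (!identical(dim(object@patterns), dim(ref))) {
    return(sprintf("patterns must enumerate all %d observable histories", 2^k - 1))
  }
  if (!identical(unname(object@patterns), unname(ref))) {
    return("patterns must be the canonical enumeration of observable histories")
  }
  if (length(object@counts) != nrow(ref)) {
    return("counts must have one entry per observable history")
  }
  if (anyNA(object@counts) || any(object@counts < 0L)) {
    return("counts must be nonnegative and non-missing")
  }
  if (length(object@eventNames) != k) {
    return("eventNames must have length k")
  }
  TRUE
})

#' Aggregated event-count table
#'
#' The aggregate field format for capture-recapture data without individual
#' identifiers: at event \eqn{j}, observed individuals are cross-tabulated by
#' which of the \eqn{j - 1} previous events' identifiers they hold, so event
#' \eqn{j} carries \eqn{2^{j-1}} counts and the whole table carries
#' \eqn{2^k - 1}.
#'
#' @slot k integer number of encounter events.
#' @slot counts list of length \eqn{k}; element \eqn{j} is a named integer
#'   vector of length \eqn{2^{j-1}} whose names are the prior-receipt patterns
#'   as \eqn{(j-1)}-character binary strings over events \eqn{1..j-1} (the
#'   single empty-string cell for event 1).
#' @slot eventNames character labels for the events.
#' @export
setClass("EventCountTable",
  representation(
    k = "integer",
    counts = "list",
    eventNames = "character"
  )
)

setValidity("EventCountTable", function(object) {
  k <- object@k
  if (length(k) != 1L || is.na(k) || k < 2L) {
    return("k must be a single integer >= 2")
  }
  if (length(object@counts) != k) {
    return("counts must be a list with one element per event")
  }
  for (j in seq_len(k)) {
    cj <- object@counts[[j]]
    expected <- priorPatternStrings(j)
    if (length(cj) != 2^(j - 1)) {
      return(sprintf("event %d must have exactly %d cells", j, 2^(j - 1)))
    }
    if (!identical(names(cj), expected)) {
      return(sprintf("event %d cell names must be the prior-receipt patterns %s",
                     j, paste(sprintf("'%s'", expected), collapse = ", ")))
    }
    if (anyNA(cj) || any(cj < 0)) {
      return(sprintf("event %d has negative or missing counts", j))
    }
  }
  if (length(object@eventNames) != k) {
    return("eventNames must have length k")
  }
  TRUE
})

#' Descriptive statistics of a capture-history table
#'
#' @slot k integer number of events.
#' @slot n integer, total distinct individuals observed.
#' @slot nj integer vector, per-event totals \eqn{n_j}.
#' @slot fi integer vector, \eqn{f_i} = number of individuals captured exactly
#'   \eqn{i} times.
#' @slot ui integer vector, \eqn{u_j} = number captured for the first time at
#'   event \eqn{j}.
#' @slot fiSeries two-column matrix of \eqn{(i, \log f_i - \log {k \choose i})}
#'   pairs (rows with \eqn{f_i = 0} omitted); roughly linear unless the data
#'   arose from an Mth model.
#' @slot uiSeries two-column matrix of \eqn{(j, u_j)} pairs.
#' @slot eventNames character labels.
#' @export
setClass("CRCDescriptives",
  representation(
    k = "integer",
    n = "integer",
    nj = "integer",
    fi = "integer",
    ui = "integer",
    fiSeries = "matrix",
    uiSeries = "matrix",
    eventNames = "character"
  )
)

#' Fitted closed-population log-linear model
#'
#' @slot modelClass one of \code{"M0"}, \code{"Mt"}, \code{"Mh"}, \code{"Mth"}.
#' @slot variant heterogeneity variant: \code{"none"}, \code{"normal"},
#'   \code{"poisson2"}, \code{"darroch"}, \code{"gamma3.5"} or \code{"chao"}.
#' @slot coefficients fitted log-linear coefficients (intercept first).
#' @slot Nhat population size estimate \eqn{\hat N = n + e^{\beta_0}}.
#' @slot se delta-method standard error of \eqn{\hat N}.
#' @slot ci numeric \code{c(lower, upper)} Wald interval on the
#'   \eqn{\log(\hat N - n)} scale.
#' @slot ciLevel interval level.
#' @slot aic,bic,loglik model fit statistics from the Poisson likelihood of
#'   the observed cells.
#' @slot fitted fitted cell means in canonical pattern order.
#' @slot converged logical convergence flag.
#' @slot isLowerBound \code{TRUE} for Chao-type fits, which bound the
#'   population size from below rather than estimate it.
#' @slot n,k observed total and number of events.
#' @slot np number of estimated parameters.
#' @slot sigmah fitted logit-scale mixing SD (normal variant only, else NA).
#' @slot notes character diagnostics accumulated during fitting.
#' @export
setClass("LogLinearFit",
  representation(
    modelClass = "character",
    variant = "character",
    coefficients = "numeric",
    Nhat = "numeric",
    se = "numeric",
    ci = "numeric",
    ciLevel = "numeric",
    aic = "numeric",
    bic = "numeric",
    loglik = "numeric",
    fitted = "numeric",
    converged = "logical",
    isLowerBound = "logical",
    n = "integer",
    k = "integer",
    np = "integer",
    sigmah = "numeric",
    notes = "character"
  )
)

setValidity("LogLinearFit", function(object) {
  if (is.finite(object@Nhat) && object@Nhat < object@n - 1e-8) {
    return("Nhat must be at least the number of observed individuals")
  }
  TRUE
})

#' Decomposable (chordal) dependence model
#'
#' A model of dependence between encounter events whose hyper-Dirichlet
#' marginal likelihood factorizes over cliques and separators of a junction
#' tree.
#'
#' @slot k number of events (graph vertices).
#' @slot edges two-column integer matrix of edges (zero rows for the
#'   independence model).
#' @slot cliques list of integer vectors: the maximal cliques, ordered so the
#'   running-intersection property holds.
#' @slot separators list of integer vectors (possibly empty vectors), one per
#'   clique after the first, with multiplicity.
#' @slot label compact display label, e.g. \code{"[1,2][3]"}.
#' @export
setClass("DecomposableModel",
  representation(
    k = "integer",
    edges = "matrix",
    cliques = "list",
    separators = "list",
    label = "character"
  )
)

#' Prior on the population size
#'
#' Either the noninformative improper prior proportional to \eqn{1/N}, a
#' log-normal prior elicited from a median and 90th percentile (truncated at
#' \code{nMax}), or a point mass (used for degenerate-prior checks).
#'
#' @slot kind \code{"noninformative"}, \code{"lognormal"} or \code{"point"}.
#' @slot median,q90 elicited quantiles (log-normal only).
#' @slot nMax truncation bound for the prior support.
#' @slot mu,sigma derived log-scale parameters (log-normal only).
#' @slot value point-mass location (point only).
#' @export
setClass("PriorSpec",
  representation(
    kind = "character",
    median = "numeric",
    q90 = "numeric",
    nMax = "numeric",
    mu = "numeric",
    sigma = "numeric",
    value = "numeric"
  )
)

#' Bayesian-model-averaged posterior over the population size
#'
#' @slot Ngrid integer grid of population sizes starting at \eqn{n}.
#' @slot posterior posterior mass per grid point (sums to 1).
#' @slot modelProbs named posterior probability per decomposable model.
#' @slot models list of \linkS4class{DecomposableModel}.
#' @slot conditional per-model conditional posterior over the grid (rows =
#'   models); empty matrix when the grid is too large to keep.
#' @slot mean,median posterior point estimates.
#' @slot ci equal-tailed credible interval.
#' @slot ciLevel interval level.
#' @slot delta hyper-Dirichlet cell prior weight used.
#' @slot prior the \linkS4class{PriorSpec} used.
#' @slot n observed total.
#' @export
setClass("BMAPosterior",
  representation(
    Ngrid = "numeric",
    posterior = "numeric",
    modelProbs = "numeric",
    models = "list",
    conditional = "matrix",
    mean = "numeric",
    median = "numeric",
    ci = "numeric",
    ciLevel = "numeric",
    delta = "numeric",
    prior = "PriorSpec",
    n = "integer"
  )
)

setValidity("BMAPosterior", function(object) {
  if (abs(sum(object@posterior) - 1) > 1e-9) {
    return("posterior masses must sum to 1")
  }
  if (abs(sum(object@modelProbs) - 1) > 1e-9) {
    return("model probabilities must sum to 1")
  }
  TRUE
})

#' Thinned MCMC draws from the latent-class sampler
#'
#' @slot draws thinned post-burn-in draws of \eqn{N}.
#' @slot alpha matching draws of the Dirichlet-process concentration.
#' @slot occupied matching draws of the number of occupied latent classes.
#' @slot n,k observed total and number of events.
#' @slot config list echoing the sampler configuration.
#' @slot seed integer seed used (NA if none was supplied).
#' @export
setClass("PosteriorDraws",
  representation(
    draws = "numeric",
    alpha = "numeric",
    occupied = "integer",
    n = "integer",
    k = "integer",
    config = "list",
    seed = "integer"
  )
)

setValidity("PosteriorDraws", function(object) {
  if (length(object@draws) && any(object@draws < object@n)) {
    return("all draws of N must be at least the observed total n")
  }
  TRUE
})

#' MCMC chain diagnostics
#'
#' @slot ess effective sample size.
#' @slot acfSeries lag-autocorrelation series (lag 0 first).
#' @slot trace the chain itself, in order.
#' @slot trendZ autocorrelation-adjusted z-statistic for a linear trend; a
#'   large value suggests the burn-in was too short.
#' @slot trendFlag \code{TRUE} when \code{|trendZ| > 3}.
#' @export
setClass("MCMCDiagnostics",
  representation(
    ess = "numeric",
    acfSeries = "numeric",
    trace = "numeric",
    trendZ = "numeric",
    trendFlag = "logical"
  )
)

#' Precision table from a study-design simulation
#'
#' @slot tolerances relative-error tolerances, in percent.
#' @slot withinFraction fraction of replicates whose estimate fell within each
#'   tolerance of the true size (nondecreasing).
#' @slot errorQuantiles quantiles (50/80/90/95) of the absolute relative
#'   error, in percent.
#' @slot estimates the replicate estimates.
#' @slot relErrors absolute relative errors, in percent.
#' @slot failed number of replicates whose fit failed.
#' @slot config list echoing the simulation configuration.
#' @export
setClass("PrecisionTable",
  representation(
    tolerances = "numeric",
    withinFraction = "numeric",
    errorQuantiles = "numeric",
    estimates = "numeric",
    relErrors = "numeric",
    failed = "integer",
    config = "list"
  )
)

setValidity("PrecisionTable", function(object) {
  if (is.unsorted(object@withinFraction)) {
    return("withinFraction must be nondecreasing in the tolerance")
  }
  if (any(object@withinFraction < 0 | object@withinFraction > 1)) {
    return("withinFraction entries must lie in [0, 1]")
  }
  TRUE
})

## Prior-receipt pattern cell names for event j: all binary strings of length
## j - 1 over events 1..j-1, lexicographic ("" for event 1).
priorPatternStrings <- function(j) {
  if (j == 1L) return("")
  g <- expand.grid(rep(list(c("0", "1")), j - 1L), stringsAsFactors = FALSE)
  ## expand.grid varies the first factor fastest; build strings so the
  ## leftmost character (event 1) is the slowest, giving lexicographic order.
  s <- do.call(paste0, rev(g))
  sort(s)
}
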