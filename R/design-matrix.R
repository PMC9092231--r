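#' @include AllClasses.R
NULL

.modelClasses <- c("M0", "Mt", "Mh", "Mth")
.hetVariants <- c("normal", "poisson2", "darroch", "gamma3.5", "chao")

## Heterogeneity correction column g(c) as a function of the number of
## captures c in a history. All three satisfy g(0) = 0, so the unobserved-cell
## extrapolation exp(beta0) needs no further anchoring. Constants: Poisson
## base 2, Gamma shape 3.5 (hence the conventional names Poisson2, Gamma3.5).
.hetFunction <- function(variant, base = 2, shape = 3.5) {
  switch(variant,
    poisson2 = function(c) base^c - 1,
    darroch  = function(c) c^2 / 2,
    gamma3.5 = function(c) -log(c + shape) + log(shape),
    crcStop(sprintf("unsupported heterogeneity variant '%s'", variant))
  )
}

#' Design matrix of a closed-population log-linear model
#'
#' Builds the model matrix over the \eqn{2^k - 1} observable histories (in
#' canonical order) for the Poisson regression of cell counts. Columns:
#' intercept; M0 adds the number of captures \eqn{c_h}; Mt adds one indicator
#' per event; Mh adds \eqn{c_h} plus a heterogeneity column \eqn{g(c_h)}; Mth
#' combines the event indicators with \eqn{g(c_h)}. The variants use
#' \eqn{g(c) = 2^c - 1} (Poisson2), \eqn{c^2/2} (Darroch) and
#' \eqn{-\log(c + 3.5) + \log 3.5} (Gamma3.5); all vanish at \eqn{c = 0} so
#' the intercept extrapolates to the unobserved cell. The Chao variant
#' replaces \eqn{g} with saturation indicators for \eqn{c = 3..k} together
#' with a fixed offset \eqn{\log(k/(k-1))} on the doubleton cells, chosen so
#' that the Mh-Chao extrapolation reproduces the moment-based Chao lower
#' bound exactly. The Normal variant has no design column; it is fitted by
#' conditional likelihood (see \code{\link{fitLogLinear}}).
#'
#' @param model model class: \code{"M0"}, \code{"Mt"}, \code{"Mh"} or
#'   \code{"Mth"}.
#' @param variant heterogeneity variant for Mh/Mth (\code{"poisson2"},
#'   \code{"darroch"}, \code{"gamma3.5"} or \code{"chao"}); must be
#'   \code{"none"} for M0/Mt.
#' @param k number of encounter events (\eqn{\ge 2}).
#' @return Numeric matrix with \eqn{2^k - 1} rows; an \code{"offset"}
#'   attribute carries the fixed offset vector (all zeros except for the Chao
#'   variant).
#' @examples
#' buildDesignMatrix("Mh", "darroch", k = 3)
#' @export
buildDesignMatrix <- function(model, variant = "none", k) {
  k <- as.integer(k)
  if (k < 2L) crcStop("k must be at least 2")
  model <- match.arg(model, .modelClasses)
  if (model %in% c("M0", "Mt")) {
    if (variant != "none") {
      crcStop(sprintf("%s takes no heterogeneity variant", model))
    }
  } else {
    if (!variant %in% setdiff(.hetVariants, "normal")) {
      crcStop(sprintf(
        "variant '%s' has no design-matrix form (valid: %s)", variant,
        paste(setdiff(.hetVariants, "normal"), collapse = ", ")))
    }
  }
  P <- patternMatrix(k)
  caps <- rowSums(P)
  X <- cbind(intercept = rep(1, nrow(P)))
  if (model %in% c("M0", "Mh")) {
    X <- cbind(X, c = caps)
  } else {
    E <- P
    colnames(E) <- paste0("e", seq_len(k))
    X <- cbind(X, E)
  }
  offset <- rep(0, nrow(P))
  if (model %in% c("Mh", "Mth")) {
    if (variant == "chao") {
      if (k >= 3L) {
        for (cc in 3:k) {
          X <- cbind(X, as.numeric(caps == cc))
          colnames(X)[ncol(X)] <- paste0("sat", cc)
        }
      }
      offset <- ifelse(caps == 2, log(k / (k - 1)), 0)
    } else {
      g <- .hetFunction(variant)
      X <- cbind(X, g = g(caps))
      colnames(X)[ncol(X)] <- paste0("g.", variant)
    }
  }
  rownames(X) <- patternToString(P)
  attr(X, "offset") <- offset
  X
}
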