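#' @include loglinear.R
NULL

## Mh/Mth with a logit-normal (Gaussian mixing) individual random effect:
## capture probability at event j is expit(mu_j + eps), eps ~ N(0, sigma^2)
## shared across events (mu_j common to all events under Mh). Cell
## probabilities are integrated by Gauss-Hermite quadrature; the parameters
## are fitted by conditional (on capture) multinomial likelihood and the
## population size recovered as N = n / (1 - p0).

## Cell probabilities pi_h and escape probability p0 for given intercepts.
.normalCellProbs <- function(mu, sigma, P, gh) {
  k <- ncol(P)
  if (length(mu) == 1L) mu <- rep(mu, k)
  ## nodes x events capture probabilities
  eta <- outer(gh$x * sigma, mu, `+`)
  lp <- stats::plogis(eta, log.p = TRUE)        # log p_j(eps)
  lq <- stats::plogis(-eta, log.p = TRUE)       # log (1 - p_j(eps))
  ## log Prob(history h | eps_i): nodes x histories
  lh <- tcrossprod(lp, P) + tcrossprod(lq, 1 - P)
  pi_h <- as.vector(crossprod(exp(lh), gh$w))
  p0 <- sum(exp(rowSums(lq)) * gh$w)
  list(pi = pi_h, p0 = p0)
}

.normalCondLoglik <- function(mu, sigma, P, x, gh) {
  pr <- .normalCellProbs(mu, sigma, P, gh)
  if (any(pr$pi <= 0) || pr$p0 >= 1) return(-Inf)
  sum(x * (log(pr$pi) - log1p(-pr$p0)))
}

.fitMuGivenSigma <- function(sigma, P, x, gh, start) {
  opt <- stats::optim(start, function(mu)
    -.normalCondLoglik(mu, sigma, P, x, gh), method = "BFGS",
    control = list(maxit = 200, reltol = 1e-12))
  opt
}

fitNormalMixing <- function(t, model = c("Mh", "Mth"), ciLevel = 0.95,
                            computeSE = TRUE, nodes = 20L) {
  model <- match.arg(model)
  P <- t@patterns
  x <- t@counts
  n <- sum(x)
  k <- t@k
  gh <- ghNormal(nodes)
  nmu <- if (model == "Mth") k else 1L
  d <- descriptiveStats(t)
  start <- if (model == "Mth") logit(pmin(pmax(d@nj / (2 * n), 0.02), 0.98))
           else rep(logit(min(max(mean(d@nj) / (2 * n), 0.02), 0.98)), 1L)
  notes <- character(0)

  ## Profile the mixing SD on a log grid, then refine by golden section.
  sigmaGrid <- c(1e-4, exp(seq(log(0.05), log(2.5), length.out = 8)))
  best <- NULL
  prof <- vapply(sigmaGrid, function(s) {
    opt <- .fitMuGivenSigma(s, P, x, gh, start)
    start <<- opt$par
    if (is.null(best) || -opt$value > best$ll) {
      best <<- list(sigma = s, mu = opt$par, ll = -opt$value)
    }
    -opt$value
  }, numeric(1))
  iBest <- which.max(prof)
  lo <- log(sigmaGrid[max(1L, iBest - 1L)])
  hi <- log(sigmaGrid[min(length(sigmaGrid), iBest + 1L)])
  if (hi > lo) {
    phi <- (sqrt(5) - 1) / 2
    a <- lo; b <- hi
    evalAt <- function(ls) {
      opt <- .fitMuGivenSigma(exp(ls), P, x, gh, best$mu)
      list(sigma = exp(ls), mu = opt$par, ll = -opt$value)
    }
    c1 <- b - phi * (b - a); c2 <- a + phi * (b - a)
    f1 <- evalAt(c1); f2 <- evalAt(c2)
    for (it in seq_len(40)) {
      if (b - a < 1e-4) break
      if (f1$ll > f2$ll) {
        b <- c2; c2 <- c1; f2 <- f1
        c1 <- b - phi * (b - a); f1 <- evalAt(c1)
      } else {
        a <- c1; c1 <- c2; f1 <- f2
        c2 <- a + phi * (b - a); f2 <- evalAt(c2)
      }
      if (f1$ll > best$ll) best <- f1
      if (f2$ll > best$ll) best <- f2
    }
  }

  sigma <- best$sigma
  mu <- best$mu
  pr <- .normalCellProbs(mu, sigma, P, gh)
  if (pr$p0 >= 1 - 1e-12) crcStop("estimate unbounded (no recaptures)")
  N0 <- n * pr$p0 / (1 - pr$p0)
  Nhat <- n + N0
  if (sigma <= 2e-4) {
    notes <- c(notes, "mixing SD at boundary (no detectable heterogeneity)")
  }

  se <- NA_real_
  z <- stats::qnorm(1 - (1 - ciLevel) / 2)
  ci <- c(NA_real_, NA_real_)
  if (computeSE) {
    ## Observed information of the unconditional likelihood over
    ## (log N0, mu, log sigma), continuous in N via lgamma.
    useSigma <- sigma > 2e-4
    par <- c(log(max(N0, 1e-8)), mu, if (useSigma) log(sigma))
    negll <- function(p) {
      n0 <- exp(p[1L])
      m <- p[1L + seq_len(nmu)]
      s <- if (useSigma) exp(p[length(p)]) else sigma
      prb <- .normalCellProbs(m, s, P, gh)
      if (any(prb$pi <= 0) || prb$p0 <= 0 || prb$p0 >= 1) return(1e10)
      -(lgamma(n + n0 + 1) - lgamma(n0 + 1) + n0 * log(prb$p0) +
          sum(x * log(prb$pi)))
    }
    H <- tryCatch(stats::optimHess(par, negll), error = function(e) NULL)
    V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
    if (!is.null(V) && is.finite(V[1L, 1L]) && V[1L, 1L] > 0) {
      seLog <- sqrt(V[1L, 1L])          # SD of log N0
      se <- N0 * seLog
      ci <- c(n + N0 * exp(-z * seLog), n + N0 * exp(z * seLog))
    } else {
      notes <- c(notes, "observed information singular; SE unavailable")
    }
  }

  mufit <- pr$pi * Nhat
  ll <- sum(stats::dpois(x, mufit, log = TRUE))
  p <- nmu + 2L  # intercept-equivalent (N0) + mixing SD
  new("LogLinearFit",
      modelClass = model, variant = "normal",
      coefficients = c(log(max(N0, 1e-300)), mu),
      Nhat = Nhat, se = se, ci = unname(ci), ciLevel = ciLevel,
      aic = -2 * ll + 2 * p, bic = -2 * ll + log(n) * p, loglik = ll,
      fitted = unname(mufit), converged = TRUE, isLowerBound = FALSE,
      n = as.integer(n), k = k, np = as.integer(p), sigmah = sigma,
      notes = notes)
}
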