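---
title: "Multi-source capture-recapture population size estimation with crcsize"
author: "crcsize authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-source capture-recapture population size estimation with crcsize}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcsize)
```

## The problem

Capture-recapture (CRC) estimates the size of a closed population that can
never be enumerated directly — in our motivating setting, key populations
for HIV surveillance such as female sex workers — from $k \ge 2$ encounter
events ("lists", "captures"). Each observed individual carries a binary
capture history over the $k$ events; of the $2^k$ possible histories, the
all-zero one is unobservable, and the statistical task is to infer the count
of that missing cell. With two lists this requires list independence and
homogeneous capture probabilities; with three or more lists both assumptions
can be relaxed by modeling list dependence and individual heterogeneity,
which is why the package focuses on $k \ge 3$ designs while still supporting
$k = 2$.

`crcsize` covers the full workflow: study design (a simulation-based
precision calculator), data formatting (including the aggregated
"event-count" field format), and estimation by three model families —
log-linear models, Bayesian model averaging over decomposable dependence
models, and a Bayesian nonparametric latent-class sampler — plus MCMC and
pairwise diagnostics and a report/CLI surface.

## Data model

`CaptureHistoryTable` stores the counts $x_h$ of all $2^k - 1$ observable
histories. Patterns are written leftmost = event 1, matching how field teams
tabulate capture rounds. Sparse input is legal but incomplete input is not:
absent observable patterns are filled with an explicit zero and reported in
a warning, because downstream models need the full table and a missing row
is more often a recording error than a true structural zero. The all-zero
pattern is always rejected — it is the estimand, not data. Counts are
strictly integer (counts of people); floats are rejected rather than
rounded.

`EventCountTable` holds the aggregate format used when no identifying
information is collected: event $j$'s attendees are cross-tabulated only by
which of the $j-1$ previous events' unique objects they hold, giving
$2^{j-1}$ cells per event and $2^k - 1$ cells overall. `convertEventCounts`
inverts this aggregation *exactly* by backward recursion over events
$j = k, \dots, 1$: the cell $(j, S)$ totals every history with prior-receipt
pattern $S$, a capture at $j$, and arbitrary later behaviour, so subtracting
the already-resolved later histories isolates the history with 1s exactly at
$S \cup \{j\}$. A negative value during the recursion means the event counts
are mutually inconsistent (identifier loss or a recording error) and is
reported as an error naming the offending cell. The forward map
`eventCountsFromHistories` makes the pair a bijection, which the test suite
property-checks on random tables for $k = 2..5$.

## Log-linear models

The expected counts of the observable cells are modeled as
$\log \mu_h = \beta_0 + x_h^\top \beta$, fitted by Poisson regression (IRLS
via `stats::glm`). Model classes: M0 (single capture-count column), Mt (one
indicator per event), Mh (capture count plus a heterogeneity column
$g(c)$), Mth (event indicators plus $g(c)$). The heterogeneity columns are

* Poisson2: $g(c) = 2^c - 1$,
* Darroch: $g(c) = c^2/2$,
* Gamma3.5: $g(c) = -\log(c + 3.5) + \log 3.5$,

all vanishing at $c = 0$ so that the fitted intercept extrapolates to the
unobserved cell: $\hat N = n + e^{\hat\beta_0}$. The constants (Poisson base
2, Gamma shape 3.5) are the conventional defaults and are named in the
output ("poisson2", "gamma3.5") so the functional form is never ambiguous.
The Darroch and especially the Gamma columns grow the correction faster in
$c$, and on heterogeneous data they systematically produce larger estimates
than Poisson2 — a tendency the suite verifies on simulated logit-normal
populations.

The delta-method variance $\widehat{Var}(\hat N) = e^{\beta_0} +
e^{2\beta_0} Var(\hat\beta_0)$ adds the Poisson variance of the unobserved
cell itself to the parameter uncertainty; intervals are Wald on the
$\log(\hat N - n)$ scale, which keeps the lower limit above $n$. A
profile-likelihood interval is available (`profileCI = TRUE`) but is not the
default: the two agree closely away from boundary cases and the Wald-log
form is what practitioners in this area usually report. AIC and BIC use the
Poisson likelihood of the observable cells with $p$ the number of fitted
parameters and the BIC penalty $\log(n)$; the literature offers no single
convention here, and this one makes all rows of the comparison table
directly comparable, including the Normal variant below.

**Identifiability.** With $k = 2$ the heterogeneity models are not
identifiable, so `fitLogLinear` refuses Mh/Mth at $k = 2$ outright rather
than fitting and warning: a silently meaningless estimate is worse than an
error. `modelComparison` therefore shows only M0 and Mt for two lists.

**The Normal (Gaussian mixing) variant** has no design column. Capture
probability is $\mathrm{expit}(\mu_j + \varepsilon)$ with
$\varepsilon \sim N(0, \sigma^2)$ shared across events. The observable-cell
probabilities are integrated by 20-node Gauss–Hermite quadrature; the
parameters are fitted by conditional (on capture) multinomial likelihood,
with $\sigma$ profiled on a log-spaced grid (plus the boundary
$\sigma \approx 0$) and refined by golden-section search — the conditional
surface in $\sigma$ can be flat or bimodal, and the grid-then-refine
strategy is more robust than joint quasi-Newton from one start. The
population size is recovered as $\hat N = n/(1 - \hat p_0)$ and the standard
error comes from the observed information of the unconditional likelihood
over $(\log(\hat N - n), \mu, \log\sigma)$, evaluated by finite differences.
When $\hat\sigma$ sits at the boundary the fit notes that no heterogeneity
was detectable.

**Estimand note.** The Poisson log-linear estimate equals the *conditional*
multinomial MLE (the multinomial–Poisson transformation); the exact
unconditional multinomial MLE sits a systematic $O(1)$ — in practice about
1–1.5 individuals — below it, regardless of scale. The test suite therefore
checks the fit against a brute-force grid search over $N$ of the multinomial
profile likelihood in its continuous-$N$ (Stirling-coefficient) form, which
is the estimand the extrapolation targets, and separately documents the
small offset to the exact-coefficient argmax. Neither is a defect; they are
two long-established, asymptotically equivalent conventions.

**Chao lower bound.** `chaoLowerBound` implements the moment bound
$\hat N = n + f_1^2/(2 f_2)$ from the singleton/doubleton frequencies, the
bias-corrected $n + f_1(f_1-1)/(2(f_2+1))$ when $f_2 = 0$, Chao's (1987)
variance and the standard log-transformed interval. It bounds the population
size from below rather than estimating it, and is flagged as such
(`isLowerBound`). The log-linear "chao" variant uses saturation indicators
for $c \ge 3$ together with a fixed offset $\log(k/(k-1))$ on the doubleton
cells; without the offset, a per-cell extrapolation yields
$\frac{k-1}{2k} f_1^2 / f_2$ (the incidence-style factor), and the offset is
exactly the adjustment that makes the design-matrix route reproduce the
moment bound, so the two agree to numerical precision. This equivalence is
a design choice of this package — the Chao column construction is not
standardized in the literature — and is covered by a dedicated test.

**Pairwise diagnostics.** For every pair of events the table is marginalized
and the Chapman estimator $(n_a+1)(n_b+1)/(m+1) - 1$ applied with Seber's
variance, the interval truncated below at $n_a + n_b - m$. Pairs with no
overlap are flagged as lower-bound-only rather than failing. Discordant
pairwise estimates are the classic symptom of list dependence.

## Bayesian model averaging

List dependence is modeled by decomposable (chordal) graphical models on the
$k$ lists: exactly those dependence structures whose hyper-Dirichlet
marginal likelihood factorizes in closed form over the cliques and
separators of a junction tree. `enumerateDecomposableModels` lists all of
them (8, 61 and 822 labeled models for $k = 3, 4, 5$; the enumeration is
refused outside that range because the model space explodes), using maximum
cardinality search for chordality and the running-intersection clique
ordering for the decomposition. Disconnected graphs are handled by empty
separators, whose margin term is the total-count Dirichlet factor — this is
what makes the single global $\Gamma(\bar\alpha)/\Gamma(\bar\alpha + N)$
normalization come out right for every graph, as the factorization and
sequential-integration oracles in the tests confirm.

For a completed table (unobserved cell $= N - n$) the log marginal
likelihood is the multinomial coefficient in $N$ plus one Dirichlet-ratio
term per clique minus one per separator; each margin cell carries prior
weight $\delta$ times the number of full-table cells collapsing into it,
with $\delta = 2^{-k}$ by default. Smaller $\delta$ places less prior weight
on complex interaction structure; it is the single complexity-control knob,
and the prior across models themselves is uniform (a pluggable model-prior
hook was considered and rejected: the cell-weight mechanism already encodes
the parsimony preference, and a second knob would be redundant and harder
to elicit).

The posterior over $N$ is computed on an integer grid from $n$ to `nMax`
(the prior's truncation, or $20n$ when the noninformative prior leaves it
unset), with the grid step capped so the grid never exceeds 50,000 points;
accumulation is in log space with a max shift. Priors: the noninformative
improper $1/N$; a log-normal elicited from a believed median and 90th
percentile, $\mu = \ln(\mathrm{median})$, $\sigma = \ln(q_{90}/\mathrm{
median})/z_{0.90}$, truncated at `nMax`; and a point mass (used for
degenerate-prior checks). The posterior mean is the headline estimate, with
the median and an equal-tailed credible interval alongside.

## Bayesian nonparametric latent-class model

Heterogeneity is modeled nonparametrically: the population is a mixture of
latent classes, class $c$ capturing at event $j$ with probability
$\lambda_{jc} \sim \mathrm{Beta}(1,1)$, and mixture weights from truncated
stick-breaking, $\nu_c \sim \mathrm{Beta}(1, \alpha)$,
$\pi_c = \nu_c \prod_{l<c}(1 - \nu_l)$, truncated at $K^*$ classes
(`maxClasses`, default 10). The Dirichlet-process concentration $\alpha$
carries a Gamma prior in the **shape/scale** convention — prior mean
$= \mathrm{shape} \times \mathrm{scale} = 0.0625$ at the 0.25/0.25 defaults
— a convention worth stating loudly because shape/rate confusion silently
changes the prior by a factor of 16 here. The prior on $N$ is proportional
to $1/N$, implemented through the negative-binomial full conditional of the
unobserved count: with escape probability
$p_0 = \sum_c \pi_c \prod_j (1 - \lambda_{jc})$,
$n_0 \sim \mathrm{NegBin}(n, 1 - p_0)$.

The Gibbs sweep exploits that individuals sharing a capture history are
exchangeable: class assignments are drawn as multinomial splits of the $\le
2^k - 1$ history counts, so the per-sweep cost is independent of $n$. A run
records $N = n + n_0$ every `thinning`-th sweep after `burnin`; defaults are
10,000 kept-phase sweeps, 10,000 burn-in, thinning 10 (the heavier
100,000/100,000/100 configuration used for the FSW worked analysis ships as
the `"paper-fsw"` preset). Runs are deterministic given `seed`. If the
occupied classes hit $K^*$ in more than 5% of kept sweeps the sampler warns
to raise `maxClasses` — the truncation level must be large enough to be
inert, and 5% is a pragmatic alarm threshold, not a statistical bound.

Diagnostics: `effectiveSampleSize` implements Geyer's initial positive
sequence truncation of the autocorrelation sum (a constant chain reports
ESS $= M$ with a degenerate-chain warning); `traceSummary` adds an
autocorrelation-adjusted linear-trend $z$ statistic, flagging $|z| > 3$ as a
sign the burn-in was too short. The $z > 3$ rule is a numerical stand-in for
what is usually a visual judgement; it is deliberately conservative.

Two behaviours of this model are worth knowing. First, with $K^* = 2$ on
homogeneous data the posterior mean tracks the M0 log-linear estimate — the
truncation floor is $K^* \ge 2$, and the reduction to the homogeneous model
shows up as the extra class staying effectively empty. Second, with almost
no data the stationary distribution of $\alpha$ is close to its Gamma prior
but not equal to it: even one observed individual constrains the sticks, so
the suite checks agreement within a small multiplicative factor rather than
equality.

## Study design by simulation

The precision calculator simulates the design before any data are
collected. Heterogeneity is elicited as "a fraction $q$ of the population
has capture odds below $r$ times the average individual's", which under a
shared logit-normal random effect maps to
$\sigma_h = \ln(r)/\Phi^{-1}(q)$ — for the FSW design, $r = 1.2$ at
$q = 0.9$ gives $\sigma_h \approx 0.1423$. The stated per-event sample
sizes are treated as *expected* counts (Bernoulli capture is what the
estimators assume), and the per-event intercepts $\mu_j$ are calibrated by
Gauss–Hermite quadrature and root-finding so that
$E[\mathrm{expit}(\mu_j + \varepsilon)] = n_j/N$ exactly.

`precisionSimulation` generates `replicates` studies, fits Mt (homogeneous
designs) or the Mth-normal model (heterogeneous designs) to each, and
tabulates the absolute relative error: the fraction of replicates within
each tolerance of the default grid {2.5, 5, 7.5, 10, 15, 20}%, and the
50/80/90/95 error percentiles. Failed fits (e.g. a replicate with no
recaptures) are counted and excluded; more than 20% failures aborts with
advice to enlarge the samples. This generator doubles as the package's
synthetic-data source in the test suite.

**What the generator does and does not emulate.** It produces closed
populations with logit-normal individual heterogeneity shared across
events and conditionally independent captures. It does not emulate list
dependence, identifier loss or misreporting, population turnover, or
event-specific heterogeneity — so passing simulation tests demonstrates
correct behaviour under the models' own assumptions, not robustness to
their violation on real field data.

## Numerical choices and problem sizes

* IRLS convergence is `stats::glm`'s default (relative deviance change
  $< 10^{-8}$); an intercept beyond $\pm 30$ is reported as "estimate
  unbounded (no recaptures)".
* Gauss–Hermite: 20 nodes everywhere; the logit-normal integrands are
  smooth and 20 nodes are accurate to well below the Monte-Carlo noise of
  any simulation here.
* BMA grid: integer step where feasible, capped at 50,000 points; log-space
  accumulation with max shift.
* Ties in `modelComparison` are broken by BIC, then by fewer parameters.
* The test suite runs its heavier checks at reduced but still informative
  sizes chosen as a deliberate compromise between statistical resolution
  and a test run measured in minutes: 1000 design-simulation replicates for
  the FSW precision check, 500 replicates for estimator-bias checks, 15
  (10 in the consolidated acceptance block) seeded latent-class recovery
  replicates at $N = 1000$, and MCMC runs of a few thousand sweeps. Each
  stochastic check fixes its seed, and every tolerance was set from the
  statistical variability of the quantity, not tuned to a particular draw.

## Limitations

* Behavioural-response (Mb) and covariate models are out of scope, as are
  open-population models; the closure assumption is taken as given.
* BMA is limited to $3 \le k \le 5$ lists by the decomposable-model
  enumeration; the latent-class model warns at $k = 2$, where heterogeneity
  is essentially unidentified.
* The latent-class sampler is single-chain (multi-chain $\hat R$ is not
  provided); the trace/ESS diagnostics are the intended convergence checks.
* Record linkage and identifier-loss modeling are upstream of this package:
  the data are assumed correctly deduplicated and tallied.
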