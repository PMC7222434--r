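---
title: "Bayesian age-period-cohort modelling and incidence projection with apcProj"
author: "apcProj authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian age-period-cohort modelling and incidence projection with apcProj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apcProj)
```

## The problem

Cancer registries publish incidence as case counts and person-years on an
age × calendar-year grid. Planning questions — how many cases to expect a
decade ahead, whether age-standardized incidence is rising or falling —
require a model that (i) separates the three classical time scales of
descriptive epidemiology (age at diagnosis, calendar period, birth cohort),
(ii) smooths them enough to extrapolate, and (iii) propagates uncertainty
into the projections. `apcProj` implements this workflow as a Bayesian
age-period-cohort (APC) model with second-order random-walk (RW2) smoothing
priors, sampled by MCMC, together with the descriptive layer built on top of
it: age-standardized rates (ASR), average annual percentage change (AAPC)
with trend labels, and a forecaster benchmark based on prediction error
rates.

## The observation model

Counts are modelled per cell of an `APCGrid` (a `SummarizedExperiment` with
`cases` and `personYears` assays):

$$y_{ij} \sim \mathrm{Poisson}(n_{ij}\, e^{\eta_{ij}} / 10^5), \qquad
\eta_{ij} = \mu + a_i + p_j + c_{k(i,j)},$$

a log link with person-years offset, rates on the per-100,000 scale. With
age classes wider than periods (5-year ages, annual periods) the cohort
index uses the width ratio $M$: $k = M(I-i) + j$, so a 17 × 28 grid carries
$K = 5\cdot16 + 28 = 108$ cohort diagonals. The Poisson likelihood is a
modelling completion: registry-style inputs are point counts, and
overdispersion beyond Poisson can be emulated (and stress-tested) through
the generator's negative-binomial switch.

## RW2 smoothing priors and their conjugate hyperpriors

Each effect vector carries the RW2 prior
$$f(a \mid \kappa_a) \propto \kappa_a^{(I-2)/2}
  \exp\!\Big(-\tfrac{\kappa_a}{2}\sum_{i=3}^{I}(a_i - 2a_{i-1} + a_{i-2})^2\Big)
  = \kappa_a^{(I-2)/2} \exp\!\big(-\tfrac12\, \kappa_a\, a^\top Q a\big),$$
with $Q = D^\top D$ for the second-difference operator $D$. $Q$ has rank
$I-2$, rows summing to zero, interior band $(1, -4, 6, -4, 1)$, and
annihilates constant and linear vectors — which is exactly why RW2
extrapolation continues the local linear trend. Published displays of $Q$
occasionally contain corner-row sign slips; any matrix whose rows do not sum
to zero cannot be an RW2 structure matrix, so the package always constructs
$D^\top D$ (first row $(1, -2, 1)$) and tests it against the
second-difference oracle.

Precisions carry conjugate hyperpriors $\kappa \sim
\mathrm{Gamma}(\alpha, \lambda)$ (shape–rate on the precision, equivalently
inverse-gamma on the variance), giving the exact full conditional
$$\kappa \mid a \sim \mathrm{Gamma}\big(\alpha + \tfrac12\,\mathrm{rank}(Q),\;
\lambda + \tfrac12\, a^\top Q a\big).$$
Defaults are $\alpha = (0.5, 1, 1)$ and
$\lambda = (5\cdot10^{-4}, 5\cdot10^{-5}, 5\cdot10^{-5})$ for age, period
and cohort: weakly informative, favouring smooth curves. For $I = 17$ and
$\alpha = 0.5$ the full-conditional shape is $0.5 + 15/2 = 8$.

## Identifiability

Because $k = M(I-i)+j$, one linear combination of the age, period and
cohort slopes can be moved between blocks without changing any fitted rate.
`applyIdentifiability()` fixes the package's canonical form: all three
vectors are centered, and the cohort vector's linear component is removed
(compensated exactly through the period effect, the age effect and the
intercept). The period block then carries the entire identifiable
per-calendar-year secular trend. This choice is forced by the projection
mechanism — forecasts extend the period walk, so the drift must live there —
and it is a reporting convention, not a claim about the data. Note that a
pure linear-in-age component cannot be moved out of the age block at all
(no combination of period and cohort terms reproduces it once the cohort
drift is fixed), so the age curve keeps its own slope. The map is
idempotent, preserves fitted rates to $10^{-10}$ relative, and sends any
two drift-shifted equivalent states to the same canonical state; all three
properties are tested.

## Sampling

`runChain()` runs Metropolis-within-Gibbs: per sweep, the intercept and
every component of the age, period and cohort blocks are updated by
single-component Gaussian random-walk Metropolis–Hastings steps targeting
the Poisson log-likelihood plus the block's RW2 log prior (flat prior on
the intercept), then the three precisions are drawn exactly from their
conjugate Gamma full conditionals. Proposal scales adapt during burn-in
towards roughly 40% acceptance and are frozen afterwards, so retained draws
target the exact posterior. The sweep is implemented in C++ for speed but
uses R's RNG stream, making every chain bit-reproducible from the config
seed; `updateEffectBlock()` is the plain-R reference implementation of the
same kernel and is held to a fine-grid quadrature oracle in the tests.
Defaults are 50,000 iterations, 10,000 burn-in, thinning 10; the seed has
no default. Retained states are canonicalized with `applyIdentifiability()`.

## Projection and intervals

`projectIncidence()` extends, per retained draw, the period walk by the RW2
predictive $x_{T+h} \sim N(2x_{T+h-1} - x_{T+h-2}, 1/\kappa_p)$ (mean path:
linear continuation; variance growing with horizon), and likewise the
cohort walk for cohorts newly entering the grid (option: pin new cohort
effects at zero). Future rates and expected cases $\lambda n / 10^5$ are
summarized per year by the posterior mean and the 95% highest-density
interval. The HDI is the empirical shortest window containing
$\lceil 0.95\,n\rceil$ sorted samples — deterministic given the draws, no
density smoothing; ties break to the lowest window. Because ASR draws are
weighted sums of rate draws, case and ASR intervals come from the same
posterior sample and are internally coherent.

## Trends: ASR, AAPC, labels

ASR is $\sum_i w_i r_i$ with standard-population weights $w$; the embedded
`"world2000"` standard is the WHO World Standard 2000 age distribution,
renormalized over the grid's age range (the 17 five-year classes 0–84 by
default). AAPC fits $\ln(\mathrm{ASR}) = \alpha + \beta\,\mathrm{year}$ and
reports $100(e^{\beta}-1)$ with the normal-theory CI
$100(e^{\beta \pm 1.96\,\mathrm{se}_\beta}-1)$. For projected series the
regression is weighted by $1/\mathrm{se}$ of the log rate, with
$\mathrm{se} = (\log u - \log l)/(2\cdot1.96)$ derived from the HDI
$(l, u)$ — the weighting follows the stated $1/se$ convention literally
rather than the variance-reciprocal $1/se^2$ WLS convention. Labels are
"increase" when the CI lies above zero, "decrease" below, "stable"
otherwise; this CI-against-zero rule is a convention, stated as such.
Significance is two-sided at $\alpha = 0.05$ throughout.

## Forecaster benchmark

`evaluateModels()` reproduces the model-selection design: split the series
by calendar year (e.g. train 1990–2012, test 2013–2017), train each
forecaster on the training interval only — the interface physically
withholds test years — and score test-interval predictions by the error
rate $(\hat y - y)/y$, reported per point (signed) and summarized by the
mean absolute value (plus the signed mean, since either summary convention
is defensible). Built-in forecasters: the Bayesian APC model, a global
log-linear baseline, and a natural-cubic-spline baseline on log-ASR whose
natural boundary condition makes extrapolation linear. Power-link drift
models (Nordpred) and segmented joinpoint regressions are deliberately
plugin slots, not re-implementations: their full specifications are
external, and here they would only serve as additional comparators.
Scoring defaults to the all-age ASR series; a case-count switch exists, in
which future person-years are treated as known population exposures.

## The synthetic registry

`simConfig()` defines the ground truth the generator realizes: a
log-quadratic age curve peaking at 72.5 years (width 30 years) — the
old-age incidence peak typical of kidney-cancer-like sites; a period effect
with log-linear drift 0.02/year plus RW2 noise; an RW2 cohort effect; base
rate 5 per 100,000 (a realistic global-ASR scale for such a site); 17
five-year age groups, years 1990–2017, a 13-year horizon, and person-years
of $10^7$ per cell, which puts expected counts at roughly 50–1500 per cell
— a large national registry. The truth is realized directly in the
canonical parameterization (cohort noise detrended, period noise detrended
around its drift), so the configured drift *is* the identifiable drift and
recovery can be judged without post-hoc reparameterization.

The wiggle parameters are standard deviations of *second differences*;
after double integration the defaults ($10^{-3}$ period, $5\cdot10^{-4}$
cohort) produce maximum log-scale deviations of about 0.02–0.06 — smooth,
few-percent departures from log-linearity, matching how registry ASR series
actually behave. Counts are independent Poisson draws given the truth
(negative-binomial optional, default off, because the model itself is fit
to point counts). What the generator does *not* emulate: estimation
uncertainty of modelled (non-surveillance) inputs, registry coverage
changes, coding-revision discontinuities, or correlated errors across
cells. Passing recovery and coverage tests therefore demonstrates
correctness of the inferential machinery under the model's own assumptions,
not robustness to those real-data artifacts — the fluctuation screen
(`screenFluctuations()`, year-over-year total-case ratio above 3 by
default) exists precisely because sharp discontinuities violate the
smoothing assumptions.

## Numerical and design choices

* **Degenerate inputs.** Grids need $I, J \ge 3$ (RW2 is undefined below
  3 points); age spans must tile exactly (no ragged last class); every
  (year, age) cell must be present, and missing cells are enumerated in the
  error. Effects of length < 3, non-positive precisions, non-positive
  observed values in error rates, and series shorter than 3 years for AAPC
  all fail fast with named causes.
* **Determinism.** One master seed drives everything through named streams
  (`deriveSeed()`), so stages are independently re-runnable; chains,
  projections and benchmarks are bit-reproducible; draws persist to text at
  full precision (`%.17g`).
* **Problem sizes in the test suite.** Parameter recovery runs the default
  17 × 28 scenario at 20,000 iterations; coverage uses 100 replicates of a
  17 × 20 drift-free scenario at 3,000 iterations; the benchmark uses 20
  replicates with period-wiggle sd 0.005 (the regime where local-trend
  extrapolation visibly beats a global line). These sizes are the package's
  chosen compromise between Monte-Carlo error and a test suite that runs in
  minutes; the quantities they estimate are insensitive to further
  enlargement.
* **Exclusion screening** operates on case counts only (not rates): counts
  are what registries report directly and what the Poisson likelihood
  consumes.
* **Cohort bins** are annual by construction ($M = 5$); passing
  `periodWidth = 5` to `toAPCGrid()` gives the classical equal-interval
  layout ($M = 1$) for comparison.

## Known limitations

* Single-chain inference: convergence diagnostics beyond the log-posterior
  trace (e.g. multi-chain R-hat) are left to external tooling.
* The period/cohort extension inherits RW2's linear-trend continuation;
  structural breaks after the observation window are outside the model.
* AAPC summarizes a possibly non-linear trend by one slope; segmented
  alternatives are intentionally out of scope.
* The HDI estimator assumes a unimodal enough posterior for a contiguous
  interval to be meaningful.

## A worked example

```{r example, eval = FALSE}
cfg <- simConfig(seed = 1)                      # 1990-2017 + 13 future years
truth <- makeTrueEffects(cfg)
tab <- simulateIncidence(truth, cfg)
grid <- toAPCGrid(tab[tab$year <= 2017, ], "synthetic", "both",
                  buildAgeGrid(0, 84, 5))
draws <- runChain(grid, mcmcConfig(seed = 1, iterations = 20000,
                                   burnIn = 5000, thin = 10))
std <- loadStandardPopulation("world2000", ageGrid(grid))
proj <- projectIncidence(draws, matrix(1e7, 17, 13), std)
proj                                            # cases and ASR with 95% HDI
aapc(observedASR(grid, std))                    # past trend
aapc(asrSeries(proj), weighted = TRUE)          # future trend, 1/se weights
```
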