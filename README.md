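# apcProj

Bayesian age-period-cohort (APC) modelling and projection of cancer
incidence, for epidemiologists and biostatisticians working with
registry-style data: case counts and person-years on an age × calendar-year
grid, split by location and sex.

## What it does

Log incidence rates are decomposed into age, period and birth-cohort
effects,

    y_ij ~ Poisson(n_ij · exp(mu + a_i + p_j + c_k(i,j)) / 1e5),
    k = M(I - i) + j,

each effect smoothed by a second-order random-walk (RW2) prior
`f(a|κ) ∝ κ^((I-2)/2) exp(-κ/2 · aᵀQa)` with structure matrix `Q = DᵀD`
(second differences; interior band 1 −4 6 −4 1) and a conjugate
`Gamma(α, λ)` hyperprior on each precision, so that
`κ | a ~ Gamma(α + rank(Q)/2, λ + aᵀQa/2)` is drawn exactly inside a
Metropolis-within-Gibbs sampler. Projections extend the period and cohort
walks by their RW2 predictive distributions per posterior draw; future case
counts and age-standardized rates (ASR, WHO World Standard 2000 weights)
are reported with 95% highest-density intervals (HDI). Trends are
quantified by the average annual percentage change,
`AAPC = 100(exp(β) − 1)` from a (optionally 1/se-weighted) regression of
log ASR on year, and labelled increase/stable/decrease by the CI against
zero. A benchmark harness scores competing forecasters by the prediction
error rate `(ŷ − y)/y` on a train/test split of the years. A
synthetic-registry generator with known ground truth makes the whole
pipeline testable end to end; see the methods vignette
(`vignettes/bayesian-apc-projection.Rmd`) for the model, conventions and
design choices.

## A worked example

Simulate a registry-scale series (17 five-year age groups, 1990–2017, true
period drift 2%/year), fit, project 13 years, and quantify trends:

```r
library(apcProj)

cfg   <- simConfig(seed = 1)
truth <- makeTrueEffects(cfg)
tab   <- simulateIncidence(truth, cfg)
grid  <- toAPCGrid(tab[tab$year <= 2017, ], "synthetic", "both",
                   buildAgeGrid(0, 84, 5))
grid
#> APCGrid: 17 age groups x 28 periods (1990-2017), M = 5, 323,482 cases

draws <- runChain(grid, mcmcConfig(seed = 1, iterations = 20000,
                                   burnIn = 5000, thin = 10))
std   <- loadStandardPopulation("world2000", ageGrid(grid))
proj  <- projectIncidence(draws, matrix(1e7, 17, 13), std)
proj
#> ProjectionResult: 13 future years (2018-2030), 95% HDI
#>   final year: 17135.7 cases (10455.1, 23671.9); ASR 7.40 (4.55, 10.26)

aapc(observedASR(grid, std))           # past trend, 1990-2017
#> TrendEstimate: AAPC 2.06% (1.98, 2.14) over 28 years -> increase
aapc(asrSeries(proj), weighted = TRUE) # projected trend, 2018-2030
#> TrendEstimate: AAPC 1.04% (1.04, 1.05) over 13 years -> increase
```

The past trend recovers the simulated 2%/year drift; the projected trend
continues the local slope at the observation boundary (about 1%/year for
this realization, reported with a tight CI because the 1/se weighting
concentrates on the least uncertain projected years), and the final-year
HDI shows how predictive uncertainty accumulates over a 13-year horizon.
Benchmarking forecasters on a 1990–2012 / 2013–2017 split:

```r
bench <- evaluateModels(
  list(forecastModelSpec("bayesian_apc", "bayesian_apc"),
       forecastModelSpec("loglinear", "loglinear"),
       forecastModelSpec("natural_spline", "natural_spline")),
  tab[tab$year <= 2017, ], trainEnd = 2012, testEnd = 2017,
  ageGrid = buildAgeGrid(0, 84, 5), standard = std, seed = 1)
bench$summary
#>            model meanAbsErrorRate meanSignedErrorRate rank
#> 1   bayesian_apc       0.01180330          0.01180330    1
#> 2      loglinear       0.03145512          0.03145512    2
#> 3 natural_spline       0.04493658          0.04493658    3
```

Mean absolute error rates of roughly 1–4% separate the forecasters on this
series; the Bayesian APC model ranks first here, which is the rationale for
using it as the projection engine.

The same workflow is scriptable through `runPipeline()` (YAML config,
per-stage derived seeds, manifests, `run.log`) or the thin CLI wrapper in
`inst/scripts/apc-pipeline.R`.

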