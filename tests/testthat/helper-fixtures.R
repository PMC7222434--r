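## Shared fixtures, all generated in code.

theAgeGrid <- buildAgeGrid(0, 84, 5)
theStandard <- loadStandardPopulation("world2000", theAgeGrid)

## a tiny hand-written long-format table (2 years x 3 age groups)
tinyTable <- function() {
  data.frame(location = "X", sex = "both",
             year = rep(2000:2001, each = 3),
             age_group = rep(1:3, 2),
             cases = c(5, 7, 9, 6, 8, 10),
             person_years = rep(1e5, 6))
}

## small synthetic scenario for fast end-to-end fits
smallScenario <- function(seed, years = 1990:2004, horizon = 5,
                          personYears = 1e6, ...) {
  cfg <- simConfig(seed = seed, years = years, horizon = horizon,
                   personYears = personYears, ...)
  truth <- makeTrueEffects(cfg)
  tab <- simulateIncidence(truth, cfg)
  grid <- toAPCGrid(tab[tab$year <= max(years), ], "synthetic", "both",
                    theAgeGrid)
  list(cfg = cfg, truth = truth, tab = tab, grid = grid)
}

fastMCMC <- function(seed, iterations = 3000, burnIn = 1000, thin = 5)
  mcmcConfig(seed = seed, iterations = iterations, burnIn = burnIn,
             thin = thin)

## true ASR of future periods of a scenario
trueFutureASR <- function(truth, standard = theStandard) {
  J <- truth@nPast
  H <- ncol(truth@lambda) - J
  as.numeric(crossprod(standardWeights(standard),
                       truth@lambda[, J + seq_len(H), drop = FALSE]))
}

## per-draw log-rate surfaces, for posterior-sd computations
etaDrawsOf <- function(draws) {
  g <- draws@grid
  kmap <- cohortIndexMap(g)
  R <- nDraws(draws)
  out <- array(0, dim = c(R, nrow(g), ncol(g)))
  for (r in seq_len(R))
    out[r, , ] <- draws@mu[r] +
      outer(draws@age[r, ], draws@period[r, ], "+") +
      matrix(draws@cohort[r, kmap], nrow(g), ncol(g))
  out
}
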