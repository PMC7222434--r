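test_that("the year split is a disjoint exhaustive partition", {
  s <- smallScenario(seed = 71, years = 1990:2017, horizon = 0)
  tab <- s$tab
  sp <- splitIntervals(tab, 2012, 2017)
  expect_equal(sort(unique(sp$train$year)), 1990:2012)
  expect_equal(sort(unique(sp$test$year)), 2013:2017)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(tab))
  recombined <- rbind(sp$train, sp$test)
  expect_equal(recombined[order(recombined$year, recombined$age_group), ],
               tab[order(tab$year, tab$age_group), ], ignore_attr = TRUE)
  expect_error(splitIntervals(tab, 2017, 2020), "outside the data span")
  expect_error(splitIntervals(tab, 2018, 2017), "trainEnd < testEnd")
})

test_that("the log-linear forecaster continues an exponential exactly", {
  yrs <- 2000:2012
  train <- data.frame(year = yrs, asr = 4 * exp(-0.03 * (yrs - 2000)))
  fc <- loglinearForecast(train, 4)
  expect_equal(fc$year, 2013:2016)
  expect_equal(fc$asr, 4 * exp(-0.03 * (2013:2016 - 2000)),
               tolerance = 1e-10)
  const <- loglinearForecast(data.frame(year = yrs, asr = rep(3, 13)), 2)
  expect_equal(const$asr, c(3, 3), tolerance = 1e-10)
})

test_that("the log-linear forecast matches by-hand OLS on 5 points", {
  yrs <- 2001:2005
  asr <- c(5.0, 5.6, 5.3, 6.1, 6.4)
  x <- yrs - mean(yrs); y <- log(asr)
  beta <- sum(x * (y - mean(y))) / sum(x^2)
  alpha <- mean(y) - beta * mean(yrs)
  fc <- loglinearForecast(data.frame(year = yrs, asr = asr), 2)
  expect_equal(fc$asr, exp(alpha + beta * (2006:2007)), tolerance = 1e-10)
})

test_that("the natural-spline forecaster is linear beyond the boundary", {
  yrs <- 2000:2014
  lin <- data.frame(year = yrs, asr = 2 * exp(0.015 * (yrs - 2000)))
  expect_equal(splineForecast(lin, 5, df = 3)$asr,
               loglinearForecast(lin, 5)$asr, tolerance = 1e-8)
  ## extrapolation continues at a constant log-slope (natural boundary)
  set.seed(72)
  wig <- data.frame(year = yrs,
                    asr = exp(log(5) + 0.02 * (yrs - 2000) +
                                0.1 * sin((yrs - 2000) / 3)))
  fc <- splineForecast(wig, 4, df = 4)
  slopes <- diff(log(fc$asr))
  expect_lt(max(abs(slopes - slopes[1])), 1e-10)
  expect_error(splineForecast(wig[1:4, ], 2, df = 4), "df \\+ 2")
})

test_that("more spline flexibility reduces in-sample error", {
  set.seed(73)
  yrs <- 1995:2014
  asr <- exp(log(6) + 0.1 * sin((yrs - 1995) / 2.5) +
               rnorm(20, sd = 0.02))
  rss <- sapply(c(2, 4, 8), function(df) {
    fit <- lm(log(asr) ~ splines::ns(yrs, df = df))
    sum(residuals(fit)^2)
  })
  expect_true(all(diff(rss) < 0))
})

test_that("an oracle plugin scores zero error and is ranked first", {
  s <- smallScenario(seed = 74, years = 1990:2009, horizon = 0)
  sp <- splitIntervals(s$tab, 2004, 2009)
  testGrid <- toAPCGrid(sp$test, "synthetic", "both", theAgeGrid)
  observed <- observedASR(testGrid, theStandard)
  oracle <- forecastModelSpec("oracle", "plugin",
                              settings = list(fun = function(train, horizon)
                                observed))
  specs <- list(oracle,
                forecastModelSpec("loglinear", "loglinear"),
                forecastModelSpec("spline", "natural_spline",
                                  settings = list(df = 3)))
  bench <- evaluateModels(specs, s$tab, 2004, 2009, theAgeGrid, theStandard,
                          seed = 74)
  summ <- bench$summary
  expect_equal(summ$meanAbsErrorRate[summ$model == "oracle"], 0,
               tolerance = 1e-12)
  expect_identical(bench$ranking[1], "oracle")
  expect_false(any(bench$results$failed))
})

test_that("rankings do not depend on the order models are listed", {
  s <- smallScenario(seed = 75, years = 1990:2009, horizon = 0)
  specs <- list(forecastModelSpec("loglinear", "loglinear"),
                forecastModelSpec("spline", "natural_spline"))
  b1 <- evaluateModels(specs, s$tab, 2004, 2009, theAgeGrid, theStandard,
                       seed = 75)
  b2 <- evaluateModels(rev(specs), s$tab, 2004, 2009, theAgeGrid,
                       theStandard, seed = 75)
  expect_identical(b1$ranking, b2$ranking)
  expect_equal(b1$summary, b2$summary)
})

test_that("a single-model benchmark yields a length-1 ranking", {
  s <- smallScenario(seed = 76, years = 1990:2009, horizon = 0)
  b <- evaluateModels(forecastModelSpec("loglinear", "loglinear"),
                      s$tab, 2004, 2009, theAgeGrid, theStandard, seed = 76)
  expect_length(b$ranking, 1L)
  expect_identical(b$summary$rank, 1L)
})

test_that("a failing model is marked failed without aborting the others", {
  s <- smallScenario(seed = 77, years = 1990:2009, horizon = 0)
  boom <- forecastModelSpec("boom", "plugin",
                            settings = list(fun = function(train, horizon)
                              stop("nope")))
  b <- evaluateModels(list(boom, forecastModelSpec("loglinear", "loglinear")),
                      s$tab, 2004, 2009, theAgeGrid, theStandard, seed = 77)
  expect_true(all(b$results$failed[b$results$model == "boom"]))
  expect_false(any(b$results$failed[b$results$model == "loglinear"]))
})

test_that("the Bayesian APC forecaster runs inside the harness", {
  s <- smallScenario(seed = 78, years = 1990:2004, horizon = 0,
                     personYears = 1e6)
  b <- evaluateModels(
    list(forecastModelSpec("bayesian_apc", "bayesian_apc"),
         forecastModelSpec("loglinear", "loglinear")),
    s$tab, 2000, 2004, theAgeGrid, theStandard, seed = 78,
    mcmc = fastMCMC(seed = 1, iterations = 1500, burnIn = 500))
  expect_false(any(b$results$failed))
  expect_true(all(is.finite(b$summary$meanAbsErrorRate)))
  ## scoring agrees with the shared error-rate implementation
  r1 <- b$results[b$results$model == "loglinear", ]
  expect_equal(r1$errorRate,
               predictionErrorRate(r1$predicted, r1$observed)$rates,
               tolerance = 1e-12)
})
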