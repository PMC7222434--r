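## Forecaster benchmark: train/test split, baseline forecasters, and the
## error-rate scoring harness that motivates choosing the Bayesian APC
## model.

#' Split an incidence table into train and test intervals by year
#'
#' Disjoint, exhaustive partition: train covers years <= trainEnd, test
#' covers trainEnd+1 .. testEnd. No leakage: forecasters only ever see the
#' train table.
#'
#' @param table incidence data.frame
#' @param trainEnd last training year
#' @param testEnd last test year (> trainEnd)
#' @return list with \code{train} and \code{test} data.frames
#' @examples
#' cfg <- simConfig(seed = 1, years = 1990:2017, horizon = 0)
#' tab <- simulateIncidence(makeTrueEffects(cfg), cfg)
#' sp <- splitIntervals(tab, 2012, 2017)
#' range(sp$train$year); range(sp$test$year)
#' @export
splitIntervals <- function(table, trainEnd, testEnd) {
  table <- .validate_incidence(table)
  yrs <- range(table$year)
  if (trainEnd >= testEnd) stop("need trainEnd < testEnd")
  if (trainEnd < yrs[1L] || testEnd > yrs[2L])
    stop(sprintf("split (%d, %d] outside the data span %d-%d",
                 trainEnd, testEnd, yrs[1L], yrs[2L]))
  train <- table[table$year <= trainEnd, , drop = FALSE]
  test <- table[table$year > trainEnd & table$year <= testEnd, , drop = FALSE]
  if (!nrow(test)) stop("empty test interval")
  list(train = train, test = test)
}

#' Log-linear baseline forecast
#'
#' Fits ln(ASR) = alpha + beta * year by OLS on the training series and
#' extrapolates the line \code{horizon} years forward.
#'
#' @param train data.frame with columns \code{year}, \code{asr} (>= 3
#'   years, positive)
#' @param horizon number of future years
#' @return data.frame with columns \code{year}, \code{asr}
#' @export
loglinearForecast <- function(train, horizon) {
  stopifnot(all(c("year", "asr") %in% names(train)), nrow(train) >= 3L)
  if (any(train$asr <= 0)) stop("ASRs must be positive")
  fit <- lm(log(asr) ~ year, data = train)
  years <- max(train$year) + seq_len(horizon)
  data.frame(year = years,
             asr = exp(predict(fit, newdata = data.frame(year = years))))
}

#' Natural-spline baseline forecast
#'
#' Fits a natural cubic spline (df interior degrees of freedom) to ln(ASR)
#' over year and extrapolates; beyond the boundary knot the natural-spline
#' boundary condition makes the continuation linear, continuous with the
#' fitted curve at the boundary year.
#'
#' @param train data.frame with columns \code{year}, \code{asr}
#' @param horizon number of future years
#' @param df spline degrees of freedom (default 3; needs >= df + 2 years)
#' @return data.frame with columns \code{year}, \code{asr}
#' @export
splineForecast <- function(train, horizon, df = 3) {
  stopifnot(all(c("year", "asr") %in% names(train)))
  if (nrow(train) < df + 2L) stop("need at least df + 2 training years")
  if (any(train$asr <= 0)) stop("ASRs must be positive")
  basis <- splines::ns(train$year, df = df)
  fit <- lm(log(asr) ~ splines::ns(year, df = df,
                                   knots = attr(basis, "knots"),
                                   Boundary.knots =
                                     attr(basis, "Boundary.knots")),
            data = train)
  years <- max(train$year) + seq_len(horizon)
  data.frame(year = years,
             asr = exp(predict(fit, newdata = data.frame(year = years))))
}

#' Bayesian APC forecast of an ASR series
#'
#' Fits the train grid with [runChain()] and projects the ASR
#' \code{horizon} years with [projectIncidence()]; returns the posterior
#' mean path.
#'
#' @param trainGrid an \linkS4class{APCGrid} built from training years only
#' @param horizon number of future years
#' @param standard a \linkS4class{StandardPopulation}
#' @param config an \linkS4class{MCMCConfig}
#' @return data.frame with columns \code{year}, \code{asr}, \code{seLog}
#' @export
bayesianAPCForecast <- function(trainGrid, horizon, standard, config) {
  draws <- runChain(trainGrid, config)
  proj <- projectIncidence(draws, futureN = matrix(1, nrow(trainGrid),
                                                   horizon),
                           standard = standard, horizon = horizon)
  asrSeries(proj)
}

#' Describe a forecaster for the benchmark
#'
#' Kinds: "bayesian_apc" (the package's model), "loglinear" and
#' "natural_spline" (baselines), and "plugin" — a slot for external
#' forecasters such as power-link drift models (Nordpred) or segmented
#' (joinpoint) regressions, supplied as
#' \code{settings$fun(train, horizon)} returning a data.frame
#' (year, asr).
#'
#' @param name unique model label
#' @param kind one of "bayesian_apc", "loglinear", "natural_spline",
#'   "plugin"
#' @param settings named list of model settings (e.g. \code{df} for the
#'   spline, \code{mcmc} for the APC model, \code{fun} for plugins)
#' @return a ForecastModelSpec (list with class attribute)
#' @export
forecastModelSpec <- function(name, kind = c("bayesian_apc", "loglinear",
                                             "natural_spline", "plugin"),
                              settings = list()) {
  kind <- match.arg(kind)
  if (kind == "plugin" && !is.function(settings$fun))
    stop("plugin models need settings$fun(train, horizon)")
  structure(list(name = name, kind = kind, settings = settings),
            class = "ForecastModelSpec")
}

#' Benchmark forecasters by prediction error rate
#'
#' For every (location, sex) series in the table and every model spec:
#' train on years <= trainEnd only, predict the test-interval ASRs, and
#' score with [predictionErrorRate()]. Observed test ASRs are crude
#' age-standardized rates. A model failure marks its cells failed without
#' aborting the benchmark; rankings (by mean absolute error rate over
#' scored cells) are independent of the order models are listed in.
#'
#' @param specs list of [forecastModelSpec()] objects (unique names)
#' @param table incidence data.frame covering train and test years
#' @param trainEnd,testEnd split years (see [splitIntervals()])
#' @param ageGrid an \linkS4class{AgeGrid}
#' @param standard a \linkS4class{StandardPopulation}
#' @param seed integer seed; each (model, series) fit gets a derived
#'   sub-seed so the benchmark is deterministic
#' @param mcmc \linkS4class{MCMCConfig} template for "bayesian_apc" specs
#'   (its seed slot is overridden per series)
#' @param score "asr" (default) or "cases" — score the age-standardized
#'   rate series or the total case counts (future person-years are
#'   population exposures, taken as known)
#' @return list with \code{results} (model, series, year, predicted,
#'   observed, errorRate, failed), \code{summary} (model, meanAbsErrorRate,
#'   meanSignedErrorRate, rank) and \code{ranking} (model names, best
#'   first)
#' @export
evaluateModels <- function(specs, table, trainEnd, testEnd, ageGrid,
                           standard, seed,
                           mcmc = mcmcConfig(seed = 1, iterations = 6000,
                                             burnIn = 2000, thin = 5),
                           score = c("asr", "cases")) {
  score <- match.arg(score)
  if (!length(specs)) stop("need at least one model spec")
  if (inherits(specs, "ForecastModelSpec")) specs <- list(specs)
  nms <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("model names must be unique")
  sp <- splitIntervals(table, trainEnd, testEnd)
  keys <- unique(sp$train[c("location", "sex")])
  res <- list()
  for (r in seq_len(nrow(keys))) {
    loc <- keys$location[r]; sx <- keys$sex[r]
    series_id <- paste(loc, sx, sep = "/")
    trainGrid <- toAPCGrid(sp$train, loc, sx, ageGrid)
    testGrid <- toAPCGrid(sp$test, loc, sx, ageGrid)
    horizon <- ncol(testGrid)
    ## the scored series: age-standardized rates or yearly case totals
    trainSeries <- if (score == "asr") observedASR(trainGrid, standard)
    else data.frame(year = gridYears(trainGrid),
                    asr = colSums(cases(trainGrid)))
    observed <- if (score == "asr") observedASR(testGrid, standard)$asr
    else colSums(cases(testGrid))
    for (spec in specs) {
      sub_seed <- deriveSeed(seed, paste("bench", spec$name, series_id))
      pred <- tryCatch({
        fc <- switch(
          spec$kind,
          loglinear = loglinearForecast(trainSeries, horizon),
          natural_spline = splineForecast(
            trainSeries, horizon,
            df = if (is.null(spec$settings$df)) 3 else spec$settings$df),
          bayesian_apc = {
            cfg <- if (is.null(spec$settings$mcmc)) mcmc
            else spec$settings$mcmc
            cfg@seed <- sub_seed
            if (score == "asr")
              bayesianAPCForecast(trainGrid, horizon, standard, cfg)
            else {
              draws <- runChain(trainGrid, cfg)
              proj <- projectIncidence(draws, personYears(testGrid),
                                       standard, horizon)
              data.frame(year = proj@years, asr = proj@casesMean)
            }
          },
          plugin = {
            set.seed(sub_seed)
            spec$settings$fun(trainSeries, horizon)
          })
        fc$asr[match(gridYears(testGrid), fc$year)]
      }, error = function(e) rep(NA_real_, horizon))
      failed <- anyNA(pred)
      er <- if (failed) rep(NA_real_, horizon)
      else predictionErrorRate(pred, observed)$rates
      res[[length(res) + 1L]] <- data.frame(
        model = spec$name, series = series_id, year = gridYears(testGrid),
        predicted = pred, observed = observed, errorRate = er,
        failed = failed)
    }
  }
  results <- do.call(rbind, res)
  agg <- lapply(split(results, results$model), function(d) data.frame(
    model = d$model[1L],
    meanAbsErrorRate = mean(abs(d$errorRate)),
    meanSignedErrorRate = mean(d$errorRate)))
  summary <- do.call(rbind, agg)
  ord <- order(summary$meanAbsErrorRate)
  summary$rank <- NA_integer_
  summary$rank[ord] <- seq_len(nrow(summary))
  rownames(summary) <- NULL
  list(results = results, summary = summary,
       ranking = summary$model[order(summary$rank)])
}
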