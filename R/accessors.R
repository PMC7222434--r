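#' @describeIn AgeGrid-class number of age groups I
#' @param x an object
#' @export
setMethod("nAgeGroups", "AgeGrid", function(x) length(x@lowerBounds))

#' @describeIn AgeGrid-class lower bounds of the age classes (years)
#' @export
setMethod("ageLowerBounds", "AgeGrid", function(x) x@lowerBounds)

#' @describeIn AgeGrid-class labels like "0-4", "5-9", ...
#' @export
setMethod("ageLabels", "AgeGrid", function(x)
  sprintf("%d-%d", x@lowerBounds, x@lowerBounds + x@width - 1L))

setMethod("show", "AgeGrid", function(object) {
  cat(sprintf("AgeGrid: %d groups of width %d covering ages %d-%d\n",
              nAgeGroups(object), object@width, min(object@lowerBounds),
              max(object@lowerBounds) + object@width - 1L))
})

#' @describeIn StandardPopulation-class normalized weights, named by age label
#' @param x an object
#' @export
setMethod("standardWeights", "StandardPopulation", function(x)
  setNames(x@weights, sprintf("%d+", x@lowerBounds)))

setMethod("show", "StandardPopulation", function(object) {
  cat(sprintf("StandardPopulation '%s': %d age groups, weights sum %.6f\n",
              object@name, length(object@weights), sum(object@weights)))
})

## direct SimpleAssays access: assay() dispatch is too slow for the MCMC
## inner loops; falls back to the generic accessor for other Assays classes
.fast_assay <- function(x, name) {
  d <- tryCatch(x@assays@data, error = function(e) NULL)
  if (!is.null(d) && !is.null(d[[name]])) d[[name]] else assay(x, name)
}

#' @describeIn APCGrid-class I x J matrix of case counts
#' @param x an object
#' @export
setMethod("cases", "APCGrid", function(x) .fast_assay(x, "cases"))

#' @describeIn APCGrid-class I x J matrix of person-years
#' @export
setMethod("personYears", "APCGrid",
          function(x) .fast_assay(x, "personYears"))

#' @describeIn APCGrid-class calendar years of the columns
#' @export
setMethod("gridYears", "APCGrid", function(x) colData(x)$year)

#' @describeIn APCGrid-class the AgeGrid of the rows
#' @export
setMethod("ageGrid", "APCGrid", function(x) x@ageGrid)

#' @describeIn APCGrid-class the width ratio M (age width / period width)
#' @export
setMethod("widthRatio", "APCGrid", function(x) x@widthRatio)

#' @describeIn APCGrid-class I x J matrix of cohort indices k = M(I-i)+j
#' @export
setMethod("cohortIndexMap", "APCGrid", function(x) {
  I <- nrow(x); J <- ncol(x); M <- x@widthRatio
  outer(seq_len(I), seq_len(J), function(i, j) M * (I - i) + j)
})

setMethod("show", "APCGrid", function(object) {
  yr <- gridYears(object)
  cat(sprintf(
    "APCGrid: %d age groups x %d periods (%d-%d), M = %d, %s cases\n",
    nrow(object), ncol(object), min(yr), max(yr), object@widthRatio,
    format(sum(cases(object)), big.mark = ",")))
})

setMethod("show", "RW2Prior", function(object) {
  cat(sprintf("RW2Prior: dim %d, kappa ~ Gamma(shape %.4g, rate %.4g)\n",
              object@dim, object@shape, object@rate))
})

setMethod("show", "APCState", function(object) {
  cat(sprintf(
    "APCState: mu %.4f; I = %d, J = %d, K = %d; kappa (a, p, c) = (%.3g, %.3g, %.3g)\n",
    object@mu, length(object@age), length(object@period),
    length(object@cohort), object@kappaAge, object@kappaPeriod,
    object@kappaCohort))
})

setMethod("show", "MCMCConfig", function(object) {
  cat(sprintf(
    "MCMCConfig: %d iterations, burn-in %d, thin %d, seed %d, adapt %s\n",
    object@iterations, object@burnIn, object@thin, object@seed,
    object@adapt))
})

#' @describeIn PosteriorDraws-class number of retained draws
#' @param x an object
#' @export
setMethod("nDraws", "PosteriorDraws", function(x) length(x@mu))

#' @describeIn PosteriorDraws-class draws of one effect block; \code{block}
#'   is "intercept", "age", "period" or "cohort"
#' @param block effect block name
#' @export
setMethod("effectDraws", "PosteriorDraws", function(x, block) {
  switch(match.arg(block, c("intercept", "age", "period", "cohort")),
         intercept = x@mu, age = x@age, period = x@period, cohort = x@cohort)
})

#' @describeIn PosteriorDraws-class draws x 3 matrix of precisions
#' @export
setMethod("precisionDraws", "PosteriorDraws", function(x) x@kappa)

setMethod("show", "PosteriorDraws", function(object) {
  cat(sprintf(
    "PosteriorDraws: %d retained draws (of %d iterations, burn-in %d, thin %d)\n",
    nDraws(object), object@config@iterations, object@config@burnIn,
    object@config@thin))
  ar <- object@acceptanceRates
  cat("  acceptance:", paste(sprintf("%s %.2f", names(ar), ar),
                             collapse = ", "), "\n")
})

setMethod("show", "ProjectionResult", function(object) {
  H <- length(object@years)
  cat(sprintf(
    "ProjectionResult: %d future years (%d-%d), %.0f%% HDI\n",
    H, min(object@years), max(object@years), 100 * object@mass))
  cat(sprintf("  final year: %.1f cases (%.1f, %.1f); ASR %.2f (%.2f, %.2f)\n",
              object@casesMean[H], object@casesLower[H], object@casesUpper[H],
              object@asrMean[H], object@asrLower[H], object@asrUpper[H]))
})

setMethod("show", "TrendEstimate", function(object) {
  cat(sprintf("TrendEstimate: AAPC %.2f%% (%.2f, %.2f) over %d years -> %s\n",
              object@aapc, object@ciLower, object@ciUpper, object@nYears,
              object@label))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d ages x %d years (%d-%d) + %d future, base rate %.3g/1e5, drift %.3g, seed %d\n",
    nAgeGroups(object@ageGrid), length(object@years), min(object@years),
    max(object@years), object@horizon, object@baseRate, object@periodDrift,
    object@seed))
})

#' @describeIn TrueEffects-class true rate matrix (per 100,000) over observed
#'   and future periods
#' @param x an object
#' @export
setMethod("trueLambda", "TrueEffects", function(x) x@lambda)

setMethod("show", "TrueEffects", function(object) {
  cat(sprintf(
    "TrueEffects: %d ages x %d periods (%d observed), rate range %.3g-%.3g per 1e5\n",
    nrow(object@lambda), ncol(object@lambda), object@nPast,
    min(object@lambda), max(object@lambda)))
})
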