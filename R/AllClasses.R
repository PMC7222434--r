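## Central S4 classes. APCGrid extends SummarizedExperiment: the age x period
## case and person-years matrices are assays, age groups are rows, calendar
## periods are columns.

#' AgeGrid: a contiguous uniform grid of age classes
#'
#' Lower bounds of consecutive age classes of equal width, e.g. the default
#' epidemiological grid of ages 0--84 in 5-year classes (17 groups).
#'
#' @slot lowerBounds integer vector of class lower bounds (years), strictly
#'   increasing with uniform spacing equal to \code{width}
#' @slot width integer class width in years
#'
#' @seealso [buildAgeGrid()]
#' @aliases nAgeGroups ageLowerBounds ageLabels
#' @export
setClass("AgeGrid", representation(lowerBounds = "integer", width = "integer"))

setValidity("AgeGrid", function(object) {
  lb <- object@lowerBounds
  w <- object@width
  if (length(w) != 1L || is.na(w) || w < 1L)
    return("width must be a single integer >= 1")
  if (length(lb) < 1L || anyNA(lb))
    return("lowerBounds must be a non-empty integer vector")
  if (length(lb) > 1L && !all(diff(lb) == w))
    return("lowerBounds must be strictly increasing with uniform spacing = width")
  TRUE
})

#' StandardPopulation: age-standardization weights
#'
#' One non-negative weight per age group, summing to one; used to compute
#' age-standardized rates as the weighted mean of age-specific rates.
#'
#' @slot weights numeric vector of weights (sums to 1 within 1e-9)
#' @slot lowerBounds integer vector of the matching age-class lower bounds
#' @slot name character label of the standard (e.g. "world2000")
#'
#' @seealso [loadStandardPopulation()], [ageStandardizedRate()]
#' @aliases standardWeights
#' @export
setClass("StandardPopulation",
         representation(weights = "numeric", lowerBounds = "integer",
                        name = "character"))

setValidity("StandardPopulation", function(object) {
  w <- object@weights
  if (length(w) < 1L || anyNA(w) || any(w < 0))
    return("weights must be non-negative and non-missing")
  if (abs(sum(w) - 1) > 1e-9)
    return("weights must sum to 1 within 1e-9")
  if (length(object@lowerBounds) != length(w))
    return("lowerBounds and weights lengths differ")
  TRUE
})

#' APCGrid: age x period incidence grid
#'
#' A \linkS4class{SummarizedExperiment} with assays \code{cases} (I x J
#' non-negative case counts) and \code{personYears} (strictly positive
#' exposures), rows indexed by an \linkS4class{AgeGrid} and columns by
#' contiguous calendar periods. \code{widthRatio} is M, the age-class width
#' divided by the period width; with 5-year age classes and annual periods
#' M = 5 and birth cohorts are indexed k = M(I - i) + j.
#'
#' @slot ageGrid the \linkS4class{AgeGrid} of the rows
#' @slot widthRatio integer M >= 1
#'
#' @seealso [toAPCGrid()], [cohortIndex()]
#' @aliases cases personYears gridYears ageGrid widthRatio cohortIndexMap
#' @export
setClass("APCGrid",
         contains = "SummarizedExperiment",
         representation(ageGrid = "AgeGrid", widthRatio = "integer"))

setValidity("APCGrid", function(object) {
  an <- names(assays(object))
  if (!all(c("cases", "personYears") %in% an))
    return("assays 'cases' and 'personYears' are required")
  y <- assay(object, "cases")
  n <- assay(object, "personYears")
  if (nrow(y) < 3L) return("need at least 3 age groups (RW2 requires I >= 3)")
  if (ncol(y) < 3L) return("need at least 3 periods (RW2 requires J >= 3)")
  if (nrow(y) != nAgeGroups(object@ageGrid))
    return("row count does not match the age grid")
  if (any(!is.finite(n)) || any(n <= 0))
    return("personYears must be finite and > 0 everywhere")
  if (any(!is.finite(y)) || any(y < 0))
    return("cases must be finite and >= 0")
  if (any(y > n)) return("cases exceed person-years")
  yr <- colData(object)$year
  if (is.null(yr)) return("colData must carry a 'year' column")
  if (length(yr) > 1L && !all(diff(yr) == diff(yr)[1L]))
    return("years must be equally spaced")
  if (length(object@widthRatio) != 1L || object@widthRatio < 1L)
    return("widthRatio must be a single integer >= 1")
  TRUE
})

#' RW2Prior: second-order random-walk smoothing prior
#'
#' The RW2 prior on an effect vector a of length \code{dim} has unnormalized
#' density kappa^((dim-2)/2) * exp(-kappa/2 * a'Qa) with structure matrix
#' Q = D'D for the second-difference operator D, and a conjugate
#' Gamma(\code{shape}, \code{rate}) hyperprior on the precision kappa.
#'
#' @slot dim integer effect length (>= 3)
#' @slot Q the dim x dim structure matrix (symmetric PSD, rank dim - 2)
#' @slot shape,rate Gamma hyperprior parameters for the precision
#'
#' @seealso [rw2Prior()], [buildStructureMatrix()], [samplePrecision()]
#' @export
setClass("RW2Prior",
         representation(dim = "integer", Q = "matrix",
                        shape = "numeric", rate = "numeric"))

setValidity("RW2Prior", function(object) {
  d <- object@dim
  if (d < 3L) return("dim must be >= 3")
  Q <- object@Q
  if (!all(dim(Q) == c(d, d))) return("Q must be dim x dim")
  if (max(abs(Q - t(Q))) > 1e-10) return("Q must be symmetric")
  if (max(abs(rowSums(Q))) > 1e-9) return("Q row sums must be zero")
  if (object@shape <= 0 || object@rate <= 0)
    return("shape and rate must be positive")
  TRUE
})

#' APCState: one configuration of the APC model parameters
#'
#' Intercept (log-rate scale, rates per 100,000 person-years), age, period
#' and cohort effect vectors, and the three RW2 precisions.
#'
#' @slot mu numeric intercept
#' @slot age,period,cohort numeric effect vectors (lengths I, J, K)
#' @slot kappaAge,kappaPeriod,kappaCohort positive precisions
#'
#' @seealso [apcState()], [applyIdentifiability()], [poissonLogLik()]
#' @export
setClass("APCState",
         representation(mu = "numeric", age = "numeric", period = "numeric",
                        cohort = "numeric", kappaAge = "numeric",
                        kappaPeriod = "numeric", kappaCohort = "numeric"))

setValidity("APCState", function(object) {
  if (length(object@mu) != 1L || !is.finite(object@mu))
    return("mu must be a single finite number")
  for (nm in c("age", "period", "cohort")) {
    v <- slot(object, nm)
    if (length(v) < 3L || any(!is.finite(v)))
      return(sprintf("%s effects must be finite with length >= 3", nm))
  }
  for (nm in c("kappaAge", "kappaPeriod", "kappaCohort")) {
    k <- slot(object, nm)
    if (length(k) != 1L || is.na(k) || k <= 0)
      return(sprintf("%s must be a single positive number", nm))
  }
  TRUE
})

#' MCMCConfig: sampler settings
#'
#' @slot iterations,burnIn,thin integers with iterations > burnIn >= 0,
#'   thin >= 1
#' @slot seed integer RNG seed (mandatory; no silent default)
#' @slot proposalScale initial Gaussian random-walk proposal sd
#' @slot adapt logical; adapt proposal scales during burn-in
#'
#' @seealso [mcmcConfig()], [runChain()]
#' @export
setClass("MCMCConfig",
         representation(iterations = "integer", burnIn = "integer",
                        thin = "integer", seed = "integer",
                        proposalScale = "numeric", adapt = "logical"))

setValidity("MCMCConfig", function(object) {
  if (object@iterations <= object@burnIn || object@burnIn < 0L)
    return("need iterations > burnIn >= 0")
  if (object@thin < 1L) return("thin must be >= 1")
  if (length(object@seed) != 1L || is.na(object@seed))
    return("seed is mandatory")
  if (object@proposalScale <= 0) return("proposalScale must be > 0")
  TRUE
})

#' PosteriorDraws: retained MCMC states
#'
#' Post burn-in, thinned draws of the APC model parameters, stored one draw
#' per row and canonicalized by [applyIdentifiability()] so every retained
#' state has centered effects and period-attributed drift.
#'
#' @slot mu numeric vector, one intercept per draw
#' @slot age,period,cohort matrices (draws x effect length)
#' @slot kappa matrix (draws x 3) of precisions, columns age/period/cohort
#' @slot logPosterior unnormalized log posterior per draw
#' @slot acceptanceRates named post burn-in MH acceptance fractions per block
#' @slot grid the \linkS4class{APCGrid} the chain was run on
#' @slot config the \linkS4class{MCMCConfig} used
#'
#' @seealso [runChain()], [projectIncidence()], [fittedRates()]
#' @aliases nDraws effectDraws precisionDraws
#' @export
setClass("PosteriorDraws",
         representation(mu = "numeric", age = "matrix", period = "matrix",
                        cohort = "matrix", kappa = "matrix",
                        logPosterior = "numeric",
                        acceptanceRates = "numeric", grid = "APCGrid",
                        config = "MCMCConfig"))

setValidity("PosteriorDraws", function(object) {
  R <- length(object@mu)
  if (R < 1L) return("no retained draws")
  if (nrow(object@age) != R || nrow(object@period) != R ||
      nrow(object@cohort) != R || nrow(object@kappa) != R)
    return("draw matrices must have one row per retained draw")
  if (any(object@kappa <= 0)) return("all precisions must be positive")
  TRUE
})

#' ProjectionResult: projected cases and ASR with 95% HDIs
#'
#' Per future year: posterior mean and highest-density-interval bounds of
#' the total case count and of the age-standardized rate (per 100,000), plus
#' the underlying per-draw ASR/case totals and per-age rate draws retained
#' for downstream AAPC weighting.
#'
#' @slot years integer future calendar years
#' @slot casesMean,casesLower,casesUpper numeric per-year case summaries
#' @slot asrMean,asrLower,asrUpper numeric per-year ASR summaries
#' @slot casesDraws,asrDraws matrices (draws x years)
#' @slot ageRateDraws array (draws x ages x years) of rates per 100,000
#' @slot mass HDI probability mass (default 0.95)
#'
#' @seealso [projectIncidence()], [asrSeries()], [hdi()]
#' @export
setClass("ProjectionResult",
         representation(years = "integer", casesMean = "numeric",
                        casesLower = "numeric", casesUpper = "numeric",
                        asrMean = "numeric", asrLower = "numeric",
                        asrUpper = "numeric", casesDraws = "matrix",
                        asrDraws = "matrix", ageRateDraws = "array",
                        mass = "numeric"))

setValidity("ProjectionResult", function(object) {
  H <- length(object@years)
  lens <- c(length(object@casesMean), length(object@casesLower),
            length(object@casesUpper), length(object@asrMean),
            length(object@asrLower), length(object@asrUpper))
  if (any(lens != H)) return("summary vectors must match years length")
  if (any(object@casesLower > object@casesMean + 1e-9) ||
      any(object@casesMean > object@casesUpper + 1e-9) ||
      any(object@asrLower > object@asrMean + 1e-9) ||
      any(object@asrMean > object@asrUpper + 1e-9))
    return("need lower <= mean <= upper per year")
  if (any(c(object@casesLower, object@asrLower) < 0))
    return("projections must be non-negative")
  TRUE
})

#' TrendEstimate: AAPC of a rate series
#'
#' Average annual percentage change 100*(exp(beta)-1), where beta is the
#' slope of an (optionally 1/se-weighted) linear regression of log rate on
#' calendar year, with a normal-theory 95% CI and an
#' increase/stable/decrease label.
#'
#' @slot aapc,ciLower,ciUpper percent per year
#' @slot beta,seBeta log-linear slope and its standard error
#' @slot pValue two-sided p-value for beta = 0
#' @slot label one of "increase", "stable", "decrease"
#' @slot nYears number of years in the regression
#' @slot weighted logical; 1/se weights used
#'
#' @seealso [aapc()], [classifyTrend()]
#' @export
setClass("TrendEstimate",
         representation(aapc = "numeric", ciLower = "numeric",
                        ciUpper = "numeric", beta = "numeric",
                        seBeta = "numeric", pValue = "numeric",
                        label = "character", nYears = "integer",
                        weighted = "logical"))

setValidity("TrendEstimate", function(object) {
  if (!(object@label %in% c("increase", "stable", "decrease")))
    return("label must be increase/stable/decrease")
  if (object@ciLower > object@aapc + 1e-9 ||
      object@aapc > object@ciUpper + 1e-9)
    return("need ciLower <= aapc <= ciUpper")
  TRUE
})

#' SimConfig: synthetic-registry scenario
#'
#' Describes the ground truth for the synthetic registry: a smooth
#' log-quadratic age curve peaking in old age, a drifting period effect with
#' RW2 wiggle, a smooth RW2 cohort effect, and Poisson (optionally
#' negative-binomial) sampling of counts given person-years.
#'
#' @slot ageGrid the \linkS4class{AgeGrid}
#' @slot years integer observed calendar years
#' @slot horizon integer number of future years also realized (>= 0)
#' @slot baseRate overall rate level, per 100,000 person-years
#' @slot ageCurvePeak,ageCurveWidth peak location and width (years) of the
#'   log-quadratic age curve
#' @slot periodDrift log-scale per-year slope of the period effect
#' @slot periodWiggleSd,cohortWiggleSd sd of the RW2 second differences
#' @slot personYears scalar or I x (J + horizon) matrix of exposures
#' @slot overdispersion 0 for Poisson; > 0 adds negative-binomial variance
#'   mu + overdispersion * mu^2
#' @slot seed integer RNG seed (mandatory)
#'
#' @seealso [simConfig()], [makeTrueEffects()], [simulateIncidence()]
#' @export
setClass("SimConfig",
         representation(ageGrid = "AgeGrid", years = "integer",
                        horizon = "integer", baseRate = "numeric",
                        ageCurvePeak = "numeric", ageCurveWidth = "numeric",
                        periodDrift = "numeric", periodWiggleSd = "numeric",
                        cohortWiggleSd = "numeric", personYears = "numeric",
                        overdispersion = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  if (length(object@seed) != 1L || is.na(object@seed))
    return("seed is mandatory")
  if (object@horizon < 0L) return("horizon must be >= 0")
  if (length(object@years) < 3L || !all(diff(object@years) == 1L))
    return("years must be >= 3 consecutive calendar years")
  if (any(object@personYears <= 0)) return("personYears must be positive")
  if (object@baseRate <= 0) return("baseRate must be positive")
  if (object@periodWiggleSd < 0 || object@cohortWiggleSd < 0 ||
      object@overdispersion < 0)
    return("sd and overdispersion parameters must be >= 0")
  TRUE
})

#' TrueEffects: realized ground truth of a synthetic scenario
#'
#' The realized intercept, centered age/period/cohort effect vectors and the
#' true rate matrix lambda (per 100,000) over observed and future periods.
#'
#' @slot mu numeric intercept (log-rate scale)
#' @slot age,period,cohort centered effect vectors; period and cohort cover
#'   the future extension as well
#' @slot lambda I x (J + horizon) matrix of true rates per 100,000
#' @slot years integer calendar years of the lambda columns
#' @slot nPast integer number of observed (non-future) periods
#'
#' @seealso [makeTrueEffects()], [simulateIncidence()]
#' @aliases trueLambda
#' @export
setClass("TrueEffects",
         representation(mu = "numeric", age = "numeric", period = "numeric",
                        cohort = "numeric", lambda = "matrix",
                        years = "integer", nPast = "integer"))

setValidity("TrueEffects", function(object) {
  if (any(object@lambda <= 0)) return("lambda must be positive")
  if (ncol(object@lambda) != length(object@years))
    return("lambda columns must match years")
  if (abs(sum(object@age)) > 1e-8)
    return("age effects must be centered")
  TRUE
})
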