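## Synthetic registry generator: ground-truth APC surfaces and Poisson
## sampling of counts, so every downstream stage can be tested against a
## known truth without external registry data.

#' Configure a synthetic-registry scenario
#'
#' Defaults mirror a national-registry kidney-cancer-like frame: 17 age
#' groups (ages 0--84 in 5-year classes), annual periods 1990--2017 plus a
#' 13-year future horizon (through 2030), an overall rate level of about 5
#' per 100,000, an age curve peaking in old age, a gently drifting period
#' effect and a smooth cohort effect. Person-years default to 1e7 per cell
#' (a large registry, giving expected counts of at least ~50 per cell).
#'
#' @param seed integer RNG seed (mandatory)
#' @param ageGrid an \linkS4class{AgeGrid}
#' @param years integer observed calendar years (consecutive)
#' @param horizon number of future years also realized
#' @param baseRate overall rate level per 100,000
#' @param ageCurvePeak,ageCurveWidth peak age and width (years) of the
#'   log-quadratic age curve
#' @param periodDrift log-scale per-year slope of the period effect
#' @param periodWiggleSd,cohortWiggleSd sd of RW2 second differences of the
#'   period and cohort noise
#' @param personYears scalar or I x (J + horizon) matrix of exposures
#' @param overdispersion 0 (default) for Poisson counts; > 0 switches to
#'   negative-binomial with variance mu + overdispersion * mu^2
#' @return a \linkS4class{SimConfig}
#' @examples
#' simConfig(seed = 1)
#' @export
simConfig <- function(seed, ageGrid = buildAgeGrid(0, 84, 5),
                      years = 1990:2017, horizon = 13, baseRate = 5,
                      ageCurvePeak = 72.5, ageCurveWidth = 30,
                      periodDrift = 0.02, periodWiggleSd = 0.001,
                      cohortWiggleSd = 0.0005, personYears = 1e7,
                      overdispersion = 0) {
  if (missing(seed)) stop("seed is mandatory")
  new("SimConfig", ageGrid = ageGrid, years = as.integer(years),
      horizon = as.integer(horizon), baseRate = as.numeric(baseRate),
      ageCurvePeak = as.numeric(ageCurvePeak),
      ageCurveWidth = as.numeric(ageCurveWidth),
      periodDrift = as.numeric(periodDrift),
      periodWiggleSd = as.numeric(periodWiggleSd),
      cohortWiggleSd = as.numeric(cohortWiggleSd),
      personYears = as.numeric(personYears),
      overdispersion = as.numeric(overdispersion),
      seed = as.integer(seed))
}

## RW2 noise of length n whose second differences are iid N(0, sd^2),
## then projected to have zero mean and zero linear trend over idx 1..nref.
.rw2_noise <- function(n, sd, nref = n) {
  if (sd == 0 || n < 3L) return(numeric(n))
  x <- cumsum(cumsum(c(0, 0, rnorm(n - 2L, sd = sd))))
  t0 <- seq_len(nref)
  fit <- lm.fit(cbind(1, t0), x[t0])
  as.numeric(x - cbind(1, seq_len(n)) %*% fit$coefficients)
}

#' Realize the ground-truth APC surfaces of a scenario
#'
#' Draws the true effects in the package's canonical (identified)
#' parameterization: a centered smooth unimodal log-quadratic age curve; a
#' period effect equal to drift * (j - jbar) plus centered, detrended RW2
#' noise (so the realized drift over the observed window equals
#' \code{periodDrift} exactly); and a centered, detrended RW2 cohort effect.
#' The true rate matrix is lambda_ij = exp(mu + a_i + p_j + c_k(i,j)) per
#' 100,000, over observed and future periods.
#'
#' @param config a \linkS4class{SimConfig}
#' @return a \linkS4class{TrueEffects}
#' @examples
#' truth <- makeTrueEffects(simConfig(seed = 1))
#' range(trueLambda(truth))
#' @export
makeTrueEffects <- function(config) {
  stopifnot(is(config, "SimConfig"))
  set.seed(deriveSeed(config@seed, "effects"))
  ag <- config@ageGrid
  I <- nAgeGroups(ag)
  J <- length(config@years)
  H <- config@horizon
  M <- ag@width                               # annual periods
  mids <- ageLowerBounds(ag) + ag@width / 2
  a <- -0.5 * ((mids - config@ageCurvePeak) / config@ageCurveWidth)^2
  a <- a - mean(a)
  jj <- seq_len(J + H)
  p <- config@periodDrift * (jj - mean(seq_len(J))) +
    .rw2_noise(J + H, config@periodWiggleSd, nref = J)
  K <- M * (I - 1L) + J
  cc <- .rw2_noise(K + H, config@cohortWiggleSd, nref = K)
  mu <- log(config@baseRate)
  kmap <- outer(seq_len(I), jj, function(i, j) M * (I - i) + j)
  lambda <- exp(mu + outer(a, p, "+") + matrix(cc[kmap], I, J + H))
  new("TrueEffects", mu = mu, age = a, period = as.numeric(p),
      cohort = as.numeric(cc), lambda = lambda,
      years = as.integer(c(config@years,
                           if (H > 0) max(config@years) + seq_len(H))),
      nPast = J)
}

## exposures as an I x (J + H) matrix
.exposure_matrix <- function(config) {
  I <- nAgeGroups(config@ageGrid)
  JH <- length(config@years) + config@horizon
  n <- config@personYears
  if (length(n) == 1L) matrix(n, I, JH)
  else if (is.matrix(n) && all(dim(n) == c(I, JH))) n
  else matrix(n, I, JH)
}

#' Simulate a long-format incidence table from a realized truth
#'
#' Draws cases_ij ~ Poisson(lambda_ij * n_ij / 1e5) independently per cell
#' (negative binomial when \code{overdispersion > 0}) for observed and
#' future years, so projections can be scored against held-out truth. The
#' output is a canonical long-format incidence table with location
#' "synthetic" and sex "both".
#'
#' @param truth a \linkS4class{TrueEffects} from [makeTrueEffects()]
#' @param config the matching \linkS4class{SimConfig}
#' @return an incidence data.frame
#' @examples
#' cfg <- simConfig(seed = 1, years = 1990:1995, horizon = 0)
#' head(simulateIncidence(makeTrueEffects(cfg), cfg))
#' @export
simulateIncidence <- function(truth, config) {
  stopifnot(is(truth, "TrueEffects"), is(config, "SimConfig"))
  lambda <- truth@lambda
  n <- .exposure_matrix(config)
  if (!all(dim(n) == dim(lambda)))
    stop("config person-years do not match the truth's grid")
  mu <- lambda * n / 1e5
  if (any(mu > 1e12)) stop("expected counts exceed 1e12; reduce exposures")
  set.seed(deriveSeed(config@seed, "counts"))
  y <- if (config@overdispersion > 0)
    rnbinom(length(mu), mu = mu, size = 1 / config@overdispersion)
  else rpois(length(mu), mu)
  I <- nrow(lambda); JH <- ncol(lambda)
  data.frame(location = "synthetic", sex = "both",
             year = rep(truth@years, each = I),
             age_group = rep(seq_len(I), JH),
             cases = as.numeric(y),
             person_years = as.numeric(n))
}
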