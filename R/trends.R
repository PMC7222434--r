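## Trend layer: ASR, AAPC with CIs and optional 1/se weights, trend
## classification, prediction error rate, and past-vs-future correlation.

#' Age-standardized rate
#'
#' Weighted mean sum_i w_i r_i of age-specific rates with standard-
#' population weights, per 100,000 person-years.
#'
#' @param ratesByAge numeric age-specific rates per 100,000
#' @param standard a \linkS4class{StandardPopulation} (or bare weight
#'   vector summing to 1)
#' @return scalar ASR per 100,000
#' @examples
#' ageStandardizedRate(c(10, 20), c(0.6, 0.4))  # 14
#' @export
ageStandardizedRate <- function(ratesByAge, standard) {
  w <- if (is(standard, "StandardPopulation")) standard@weights
  else as.numeric(standard)
  if (length(w) != length(ratesByAge))
    stop("rates and weights lengths differ")
  sum(w * ratesByAge)
}

#' Observed ASR series of a grid
#'
#' Crude age-specific rates 1e5 * y/n standardized with the given weights,
#' one value per period.
#'
#' @param grid an \linkS4class{APCGrid}
#' @param standard a \linkS4class{StandardPopulation}
#' @return data.frame with columns \code{year}, \code{asr}
#' @export
observedASR <- function(grid, standard) {
  stopifnot(is(grid, "APCGrid"))
  rates <- 1e5 * cases(grid) / personYears(grid)
  data.frame(year = gridYears(grid),
             asr = apply(rates, 2, ageStandardizedRate, standard = standard))
}

#' ASR series of a projection
#'
#' Posterior-mean projected ASR per future year, with the log-scale
#' standard error derived from the HDI width as
#' (log(upper) - log(lower)) / (2 * 1.96) for downstream 1/se weighting.
#'
#' @param projection a \linkS4class{ProjectionResult}
#' @return data.frame with columns \code{year}, \code{asr}, \code{seLog}
#' @export
asrSeries <- function(projection) {
  stopifnot(is(projection, "ProjectionResult"))
  data.frame(year = projection@years, asr = projection@asrMean,
             seLog = (log(projection@asrUpper) - log(projection@asrLower)) /
               (2 * 1.96))
}

#' Average annual percentage change of a rate series
#'
#' Fits ln(ASR) = alpha + beta * year by (optionally weighted) least
#' squares and reports AAPC = 100 (exp(beta) - 1) with the normal-theory
#' 95% CI 100 (exp(beta +/- 1.96 se_beta) - 1), a two-sided p-value for
#' beta = 0, and an increase/stable/decrease label from
#' [classifyTrend()]. When \code{weighted = TRUE} the regression weights
#' are 1/se of the log rates (column \code{seLog}), down-weighting
#' uncertain projected years.
#'
#' @param series data.frame with columns \code{year}, \code{asr} and, when
#'   weighting, \code{seLog}; at least 3 years, positive ASRs
#' @param weighted use 1/se weights (default FALSE)
#' @return a \linkS4class{TrendEstimate}
#' @examples
#' aapc(data.frame(year = 1990:2017, asr = 5 * exp(0.02 * (0:27))))
#' @export
aapc <- function(series, weighted = FALSE) {
  stopifnot(is.data.frame(series), all(c("year", "asr") %in% names(series)))
  if (nrow(series) < 3L) stop("need at least 3 years")
  if (any(!is.finite(series$asr)) || any(series$asr <= 0))
    stop("ASRs must be positive")
  wts <- NULL
  if (weighted) {
    if (!"seLog" %in% names(series) || any(!is.finite(series$seLog)) ||
        any(series$seLog <= 0))
      stop("weighted AAPC needs positive seLog per year")
    wts <- 1 / series$seLog
  }
  df <- data.frame(ly = log(series$asr), year = series$year)
  fit <- if (is.null(wts)) lm(ly ~ year, data = df)
  else lm(ly ~ year, data = df, weights = wts)
  beta <- unname(coef(fit)[2L])
  ## suppress the "essentially perfect fit" note on exact log-linear series
  se <- sqrt(suppressWarnings(vcov(fit)[2L, 2L]))
  if (!is.finite(se)) se <- 0
  dfree <- fit$df.residual
  p <- if (se > 0) 2 * pt(-abs(beta / se), df = dfree)
  else as.numeric(beta == 0)
  lo <- 100 * (exp(beta - 1.96 * se) - 1)
  hi <- 100 * (exp(beta + 1.96 * se) - 1)
  new("TrendEstimate", aapc = 100 * (exp(beta) - 1), ciLower = lo,
      ciUpper = hi, beta = beta, seBeta = se, pValue = p,
      label = classifyTrend(lo, hi), nYears = nrow(series),
      weighted = isTRUE(weighted))
}

#' Classify a trend from its AAPC confidence interval
#'
#' "increase" when the CI lies entirely above zero, "decrease" when
#' entirely below, otherwise "stable" (CI contains zero). Every CI maps to
#' exactly one label.
#'
#' @param x a \linkS4class{TrendEstimate}, or the CI lower bound
#' @param upper the CI upper bound when \code{x} is numeric
#' @return "increase", "stable" or "decrease"
#' @examples
#' classifyTrend(0.08, 0.20)    # increase
#' classifyTrend(-0.30, -0.23)  # decrease
#' @export
classifyTrend <- function(x, upper = NULL) {
  if (is(x, "TrendEstimate")) {
    lower <- x@ciLower; upper <- x@ciUpper
  } else lower <- x
  stopifnot(is.numeric(lower), is.numeric(upper), lower <= upper)
  if (lower > 0) "increase" else if (upper < 0) "decrease" else "stable"
}

#' Prediction error rate
#'
#' Per-point signed error rate (yhat - y) / y and its summaries: the mean
#' of absolute values (the headline forecaster score) and the signed mean.
#' Scale-invariant under joint rescaling of predictions and observations.
#'
#' @param predicted,observed equal-length numeric vectors; observed > 0
#' @return list with \code{rates}, \code{meanAbs}, \code{meanSigned}
#' @examples
#' predictionErrorRate(c(1.1, 0.9), c(1, 1))
#' @export
predictionErrorRate <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed lengths differ")
  if (any(!is.finite(observed)) || any(observed <= 0))
    stop("observed values must be positive")
  rates <- (predicted - observed) / observed
  list(rates = rates, meanAbs = mean(abs(rates)), meanSigned = mean(rates))
}

#' Pearson correlation of past and future AAPCs across locations
#'
#' Pairs per-location past and future AAPC values, drops incomplete pairs
#' (counted), and reports the Pearson correlation with its two-sided
#' t-test p-value, pooled and per stratum. Strata with fewer than 3
#' complete pairs are skipped with a warning.
#'
#' @param past,future named numeric vectors of AAPC keyed by location
#' @param strata optional named character vector mapping locations to
#'   stratum labels (e.g. development level)
#' @return data.frame with columns \code{stratum}, \code{rho},
#'   \code{pValue}, \code{n}, \code{dropped}
#' @export
pastFutureCorrelation <- function(past, future, strata = NULL) {
  locs <- union(names(past), names(future))
  if (is.null(names(past)) || is.null(names(future)))
    stop("past and future must be named by location")
  x <- past[locs]; y <- future[locs]
  ok <- is.finite(x) & is.finite(y)
  dropped_all <- sum(!ok)
  one <- function(label, sel) {
    n <- sum(sel & ok)
    if (n < 3L) {
      warning("stratum '", label, "' has fewer than 3 pairs; skipped")
      return(NULL)
    }
    ct <- cor.test(x[sel & ok], y[sel & ok], method = "pearson")
    data.frame(stratum = label, rho = unname(ct$estimate),
               pValue = ct$p.value, n = n,
               dropped = sum(sel & !ok))
  }
  out <- one("pooled", rep(TRUE, length(locs)))
  if (!is.null(strata)) {
    for (s in unique(strata[locs][!is.na(strata[locs])]))
      out <- rbind(out, one(s, !is.na(strata[locs]) & strata[locs] == s))
  }
  if (is.null(out)) stop("fewer than 3 complete location pairs")
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped_all
  out
}
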