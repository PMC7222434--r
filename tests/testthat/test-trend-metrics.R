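test_that("age standardization is the weighted mean of age-specific rates", {
  expect_equal(ageStandardizedRate(c(10, 20), c(0.6, 0.4)), 14)
  expect_equal(ageStandardizedRate(rep(7.3, 17), theStandard), 7.3)
  set.seed(61)
  r <- runif(17, 1, 50)
  w <- standardWeights(theStandard)
  expect_equal(ageStandardizedRate(r, theStandard),
               sum(sapply(1:17, function(i) w[i] * r[i])))
  expect_error(ageStandardizedRate(1:5, theStandard), "lengths differ")
})

test_that("AAPC is exact on a log-linear series", {
  yrs <- 1990:2017
  est <- aapc(data.frame(year = yrs, asr = 5 * exp(0.02 * (yrs - 1990))))
  expect_equal(est@beta, 0.02, tolerance = 1e-10)
  expect_equal(est@aapc, 100 * (exp(0.02) - 1), tolerance = 1e-8)
  expect_lt(est@ciUpper - est@ciLower, 1e-8)    # zero-width CI
  expect_identical(est@label, "increase")
})

test_that("a constant series has AAPC 0 and is labelled stable", {
  est <- aapc(data.frame(year = 2000:2010, asr = rep(4.2, 11)))
  expect_equal(est@aapc, 0)
  expect_identical(est@label, "stable")
})

test_that("AAPC is scale-invariant and antisymmetric under year reversal", {
  set.seed(62)
  yrs <- 1995:2010
  asr <- exp(0.01 * (yrs - 2000) + rnorm(length(yrs), sd = 0.03)) * 6
  a1 <- aapc(data.frame(year = yrs, asr = asr))
  a2 <- aapc(data.frame(year = yrs, asr = 1000 * asr))
  expect_equal(a1@beta, a2@beta, tolerance = 1e-12)
  rev <- aapc(data.frame(year = yrs, asr = rev(asr)))
  expect_equal(rev@beta, -a1@beta, tolerance = 1e-12)
})

test_that("equal weights reproduce the unweighted fit", {
  yrs <- 2000:2012
  set.seed(63)
  d <- data.frame(year = yrs, asr = exp(rnorm(13, 0, 0.05)) * 5,
                  seLog = rep(0.07, 13))
  wt <- aapc(d, weighted = TRUE)
  un <- aapc(d, weighted = FALSE)
  expect_equal(wt@beta, un@beta, tolerance = 1e-10)
  expect_equal(wt@seBeta, un@seBeta, tolerance = 1e-10)
})

test_that("weighting pulls the slope toward precise years", {
  yrs <- 2000:2009
  asr <- c(5 * exp(0.03 * 0:8), 20)       # wild final year
  se <- c(rep(0.01, 9), 5)                # ... which is very uncertain
  wt <- aapc(data.frame(year = yrs, asr = asr, seLog = se), weighted = TRUE)
  un <- aapc(data.frame(year = yrs, asr = asr))
  expect_lt(abs(wt@beta - 0.03), abs(un@beta - 0.03))
})

test_that("trend classification partitions every CI", {
  expect_identical(classifyTrend(0.08, 0.20), "increase")
  expect_identical(classifyTrend(-0.30, -0.23), "decrease")
  expect_identical(classifyTrend(-0.1, 0.2), "stable")
  expect_identical(classifyTrend(0, 0.2), "stable")     # boundary
  set.seed(64)
  for (rep in 1:100) {
    ci <- sort(rnorm(2))
    expect_length(classifyTrend(ci[1], ci[2]), 1L)
  }
})

test_that("prediction error rates preserve sign and scale invariance", {
  expect_equal(predictionErrorRate(c(1, 2), c(1, 2))$meanAbs, 0)
  pr <- predictionErrorRate(1.1 * c(3, 7, 9), c(3, 7, 9))
  expect_equal(pr$rates, rep(0.1, 3), tolerance = 1e-12)
  expect_equal(pr$meanAbs, 0.1, tolerance = 1e-12)
  mixed <- predictionErrorRate(c(1.1, 0.9), c(1, 1))
  expect_equal(mixed$meanAbs, 0.1, tolerance = 1e-12)
  expect_equal(mixed$meanSigned, 0, tolerance = 1e-12)
  set.seed(65)
  yhat <- runif(10, 1, 2); y <- runif(10, 1, 2)
  expect_equal(predictionErrorRate(3 * yhat, 3 * y)$rates,
               predictionErrorRate(yhat, y)$rates, tolerance = 1e-12)
  expect_error(predictionErrorRate(1, 0), "positive")
})

test_that("past/future correlation matches the textbook formula", {
  past <- c(a = 1.0, b = -0.5, c = 0.3, d = 2.0, e = -1.2)
  future <- c(a = 0.8, b = -0.1, c = 0.5, d = 1.1, e = -0.9)
  res <- pastFutureCorrelation(past, future)
  x <- past; y <- future
  rho_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$rho[res$stratum == "pooled"], rho_hand,
               tolerance = 1e-12)
  ## perfect agreement / opposition
  expect_equal(pastFutureCorrelation(past, past)$rho[1], 1)
  expect_equal(pastFutureCorrelation(past, -past)$rho[1], -1)
})

test_that("strata are reported separately and small ones skipped", {
  set.seed(66)
  locs <- paste0("L", 1:10)
  past <- setNames(rnorm(10), locs)
  future <- setNames(past + rnorm(10, sd = 0.2), locs)
  strata <- setNames(rep(c("high", "low"), each = 5), locs)
  res <- pastFutureCorrelation(past, future, strata)
  expect_setequal(res$stratum, c("pooled", "high", "low"))
  expect_true(all(res$n == c(10, 5, 5)))
  ## a 2-member stratum is skipped with a warning, pairs with NA dropped
  future[c("L1", "L2")] <- NA
  strata[] <- c(rep("high", 2), rep("low", 8))
  expect_warning(res2 <- pastFutureCorrelation(past, future, strata),
                 "fewer than 3")
  expect_false("high" %in% res2$stratum)
  expect_equal(res2$n[res2$stratum == "pooled"], 8)
})
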