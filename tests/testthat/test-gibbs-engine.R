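test_that("the precision full conditional matches the conjugate form", {
  prior <- rw2Prior(17, 0.5, 5e-4)
  ## linear effects: quadratic form 0, so the rate stays at the prior rate
  fc <- precisionFullConditional(0.1 * (1:17), prior)
  expect_equal(fc$shape, 8)                       # 0.5 + 15/2
  expect_equal(fc$rate, 5e-4)
  set.seed(2)
  a <- rnorm(17)
  fc2 <- precisionFullConditional(a, prior)
  expect_equal(fc2$rate, 5e-4 + 0.5 * rw2QuadraticForm(a))
  expect_error(precisionFullConditional(rnorm(5), prior), "length")
})

test_that("precision draws follow their full-conditional Gamma", {
  set.seed(3)
  prior <- rw2Prior(12, 1, 5e-5)
  a <- rnorm(12, sd = 0.5)
  fc <- precisionFullConditional(a, prior)
  draws <- samplePrecision(a, prior, n = 1e5)
  expect_lt(abs(mean(draws) / (fc$shape / fc$rate) - 1), 0.01)
  ks <- suppressWarnings(
    stats::ks.test(draws, stats::pgamma, shape = fc$shape, rate = fc$rate))
  expect_gt(ks$p.value, 0.001)
})

test_that("a zero proposal scale leaves the chain where it started", {
  s <- smallScenario(seed = 41, years = 1990:1995, horizon = 0)
  st <- apcState(mu = log(5), age = rep(0, 17), period = rep(0, 6),
                 cohort = rep(0, 5 * 16 + 6))
  pri <- defaultPriors(s$grid)
  set.seed(1)
  up <- updateEffectBlock(st, "age", s$grid, pri$age, scale = 0)
  expect_identical(up$state@age, st@age)
  set.seed(1)
  up2 <- updateEffectBlock(st, "intercept", s$grid, scale = 0)
  expect_identical(up2$state@mu, st@mu)
})

test_that("effect updates are deterministic given the RNG state", {
  s <- smallScenario(seed = 42, years = 1990:1995, horizon = 0)
  st <- apcState(mu = log(5), age = rep(0, 17), period = rep(0, 6),
                 cohort = rep(0, 5 * 16 + 6))
  pri <- defaultPriors(s$grid)
  set.seed(99); a1 <- updateEffectBlock(st, "period", s$grid, pri$period, 0.2)
  set.seed(99); a2 <- updateEffectBlock(st, "period", s$grid, pri$period, 0.2)
  expect_identical(a1$state@period, a2$state@period)
  expect_identical(a1$accepted, a2$accepted)
})

test_that("the MH kernel reproduces a 1-parameter conditional (quadrature)", {
  ## hold every effect fixed and update only the intercept: the target is
  ## pi(mu) prop exp(mu * Y - S * e^mu); compare the long-run draw
  ## distribution with the density integrated on a fine grid
  tab <- tinyTable()
  tab <- rbind(tab, transform(tab, year = year + 2))
  g <- toAPCGrid(tab, "X", "both", buildAgeGrid(0, 14, 5))
  st <- apcState(mu = 2, age = rep(0, 3), period = rep(0, 4),
                 cohort = rep(0, 14))
  Y <- sum(cases(g))
  S <- sum(personYears(g)) / 1e5
  set.seed(7)
  ndraw <- 1e5
  mus <- numeric(ndraw)
  for (t in seq_len(ndraw)) {
    st <- updateEffectBlock(st, "intercept", g, scale = 0.15)$state
    mus[t] <- st@mu
  }
  mus <- mus[-(1:5000)]
  grid_mu <- seq(min(mus) - 0.2, max(mus) + 0.2, length.out = 4001)
  logd <- grid_mu * Y - S * exp(grid_mu)
  dens <- exp(logd - max(logd))
  cdf <- cumsum(dens); cdf <- cdf / cdf[length(cdf)]
  emp <- ecdf(mus)
  ks_dist <- max(abs(emp(grid_mu) - cdf))
  expect_lt(ks_dist, 0.02)
})

test_that("runChain is bit-reproducible from its seed", {
  s <- smallScenario(seed = 43, years = 1990:1997, horizon = 0)
  cfg <- fastMCMC(seed = 5, iterations = 800, burnIn = 200, thin = 4)
  d1 <- runChain(s$grid, cfg)
  d2 <- runChain(s$grid, cfg)
  expect_identical(d1@mu, d2@mu)
  expect_identical(d1@cohort, d2@cohort)
  expect_identical(d1@kappa, d2@kappa)
  d3 <- runChain(s$grid, fastMCMC(seed = 6, iterations = 800, burnIn = 200,
                                  thin = 4))
  expect_false(identical(d1@mu, d3@mu))
  ## retained states are canonical
  expect_lt(max(abs(rowSums(d1@age))), 1e-8)
  expect_lt(max(abs(rowSums(d1@period))), 1e-8)
  kk <- seq_len(ncol(d1@cohort)); wk <- kk - mean(kk)
  expect_lt(max(abs(d1@cohort %*% wk)) / sum(wk * wk), 1e-10)
})

test_that("posterior uncertainty contracts as exposure grows", {
  ## quadrupling person-years should roughly halve posterior sd of log rates
  sdOf <- function(py, seed) {
    s <- smallScenario(seed = seed, years = 1990:1999, horizon = 0,
                       personYears = py)
    d <- runChain(s$grid, fastMCMC(seed = seed))
    eta <- etaDrawsOf(d)
    mean(apply(eta, c(2, 3), sd))
  }
  r <- sdOf(4e6, 44) / sdOf(1e6, 44)
  expect_gt(r, 0.5 * 0.7)
  expect_lt(r, 0.5 * 1.3)
})

test_that("the chain recovers known truth on a small scenario", {
  s <- smallScenario(seed = 45, years = 1990:2004, horizon = 0,
                     personYears = 1e6)
  d <- runChain(s$grid, fastMCMC(seed = 45, iterations = 4000,
                                 burnIn = 1500))
  fr <- fittedRates(d)
  lamPast <- trueLambda(s$truth)[, seq_len(15)]
  expect_gt(mean(abs(fr / lamPast - 1) < 0.1), 0.9)
  expect_gt(cor(colMeans(effectDraws(d, "age")), s$truth@age), 0.98)
  pm <- colMeans(effectDraws(d, "period"))
  expect_lt(abs(unname(coef(lm(pm ~ seq_along(pm)))[2]) - 0.02), 0.01)
})
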