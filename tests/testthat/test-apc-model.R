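test_that("the RW2 structure matrix is D'D with the printed interior band", {
  expect_equal(buildStructureMatrix(3),
               matrix(c(1, -2, 1, -2, 4, -2, 1, -2, 1), 3, 3),
               ignore_attr = TRUE)
  Q7 <- buildStructureMatrix(7)
  expect_equal(Q7[4, ], c(0, 1, -4, 6, -4, 1, 0), ignore_attr = TRUE)
  expect_equal(Q7[1, 1:3], c(1, -2, 1), ignore_attr = TRUE)  # rows sum to 0
  expect_error(buildStructureMatrix(2), ">= 3")
})

test_that("Q annihilates constants and lines and has rank dim - 2", {
  for (d in c(3L, 5L, 17L)) {
    Q <- buildStructureMatrix(d)
    expect_lt(max(abs(Q %*% rep(1, d))), 1e-9)
    expect_lt(max(abs(Q %*% seq_len(d))), 1e-9)
    expect_identical(qr(Q)$rank, d - 2L)
  }
})

test_that("the second-difference penalty agrees with the a'Qa oracle", {
  expect_identical(rw2QuadraticForm(c(0, 0, 1)), 1)
  expect_identical(rw2QuadraticForm(2 + 3 * (1:10)), 0)
  set.seed(101)
  for (rep in 1:50) {
    d <- sample(3:25, 1)
    a <- rnorm(d, sd = 10)
    expect_equal(rw2QuadraticForm(a),
                 as.numeric(t(a) %*% buildStructureMatrix(d) %*% a),
                 tolerance = 1e-10)
  }
  expect_error(rw2QuadraticForm(c(1, 2)), "at least 3")
})

test_that("the RW2 log density follows its closed form", {
  lin <- 1 + 0.5 * (1:9)
  expect_equal(rw2LogDensity(lin, 2), (7 / 2) * log(2))
  expect_equal(rw2LogDensity(lin, 4) - rw2LogDensity(lin, 2),
               (7 / 2) * log(2))
  x <- c(0, 0, 1, 0, 0)
  expect_lt(rw2LogDensity(x * 2, 1), rw2LogDensity(x, 1))
  expect_error(rw2LogDensity(x, 0), "positive")
})

test_that("cohort indexing follows k = M(I - i) + j", {
  expect_identical(cohortIndex(17, 1, I = 17, M = 5), 1L)
  expect_identical(cohortIndex(16, 1, I = 17, M = 5), 6L)
  expect_identical(cohortIndex(1, 28, I = 17, M = 5), 108L)
  ## strictly decreasing in age, increasing in period
  expect_true(all(diff(cohortIndex(17:1, 1, 17, 5)) > 0))
  expect_true(all(diff(cohortIndex(3, 1:10, 17, 5)) > 0))
  expect_error(cohortIndex(18, 1, 17, 5), "out of range")
  expect_error(cohortIndex(1, 0, 17, 5), ">= 1")
})

test_that("the Poisson log-likelihood matches a brute-force cell sum", {
  set.seed(7)
  ag <- buildAgeGrid(0, 24, 5)                       # I = 5
  n <- matrix(runif(25, 1e5, 1e6), 5, 5)
  y <- matrix(rpois(25, 50), 5, 5)
  tab <- data.frame(location = "X", sex = "both",
                    year = rep(2000:2004, each = 5),
                    age_group = rep(1:5, 5),
                    cases = as.numeric(y), person_years = as.numeric(n))
  g <- toAPCGrid(tab, "X", "both", ag)
  K <- 5 * 4 + 5
  st <- apcState(mu = log(8), age = rnorm(5, sd = .3),
                 period = rnorm(5, sd = .1), cohort = rnorm(K, sd = .1))
  oracle <- 0
  for (i in 1:5) for (j in 1:5) {
    m <- n[i, j] * exp(st@mu + st@age[i] + st@period[j] +
                         st@cohort[cohortIndex(i, j, 5, 5)]) / 1e5
    oracle <- oracle + y[i, j] * log(m) - m
  }
  expect_equal(poissonLogLik(g, st), oracle, tolerance = 1e-12)
  ## all-zero counts reduce to -sum(mu_ij)
  g0 <- toAPCGrid(transform(tab, cases = 0), "X", "both", ag)
  m_all <- n * exp(st@mu + outer(st@age, st@period, "+") +
                     matrix(st@cohort[cohortIndexMap(g)], 5, 5)) / 1e5
  expect_equal(poissonLogLik(g0, st), -sum(m_all), tolerance = 1e-12)
})

test_that("the log-likelihood peaks where fitted rates meet the data", {
  tab <- tinyTable()
  tab <- rbind(tab, transform(tab, year = year + 2))
  g <- toAPCGrid(tab, "X", "both", buildAgeGrid(0, 14, 5))
  base <- apcState(mu = log(7), age = rep(0, 3), period = rep(0, 4),
                   cohort = rep(0, 5 * 2 + 4))
  mle_mu <- log(sum(cases(g)) / sum(personYears(g)) * 1e5)
  lls <- sapply(mle_mu + c(-0.5, -0.1, 0, 0.1, 0.5), function(m) {
    s <- base; s@mu <- m; poissonLogLik(g, s)
  })
  expect_identical(which.max(lls), 3L)
})

test_that("canonicalization preserves fitted rates and is idempotent", {
  set.seed(11)
  I <- 6L; J <- 8L; M <- 5L; K <- M * (I - 1L) + J
  st <- apcState(mu = 1, age = rnorm(I), period = rnorm(J),
                 cohort = rnorm(K), kappaAge = 2, kappaPeriod = 3,
                 kappaCohort = 4)
  eta <- function(s) {
    kmap <- outer(seq_len(I), seq_len(J), function(i, j) M * (I - i) + j)
    s@mu + outer(s@age, s@period, "+") + matrix(s@cohort[kmap], I, J)
  }
  cn <- applyIdentifiability(st)
  expect_equal(eta(cn), eta(st), tolerance = 1e-10)
  expect_equal(sum(cn@age), 0, tolerance = 1e-9)
  expect_equal(sum(cn@period), 0, tolerance = 1e-9)
  expect_equal(sum(cn@cohort), 0, tolerance = 1e-9)
  ## cohort drift removed
  kk <- seq_len(K)
  expect_equal(unname(coef(lm(cn@cohort ~ kk))[2]), 0, tolerance = 1e-9)
  ## idempotent
  cn2 <- applyIdentifiability(cn)
  expect_equal(cn2@cohort, cn@cohort, tolerance = 1e-12)
  expect_equal(cn2@mu, cn@mu, tolerance = 1e-12)
})

test_that("equivalent drift-shifted states canonicalize identically", {
  set.seed(12)
  I <- 6L; J <- 8L; M <- 5L; K <- M * (I - 1L) + J
  st <- apcState(mu = 1, age = rnorm(I), period = rnorm(J),
                 cohort = rnorm(K))
  ## shift delta*i into age, compensating via mu, period and cohort so the
  ## fitted surface is untouched (delta*i = delta*I + (delta/M) j - (delta/M) k)
  delta <- 0.3
  sh <- st
  sh@age <- st@age + delta * seq_len(I)
  sh@mu <- st@mu - delta * I
  sh@period <- st@period - (delta / M) * seq_len(J)
  sh@cohort <- st@cohort + (delta / M) * seq_len(K)
  a <- applyIdentifiability(st); b <- applyIdentifiability(sh)
  expect_equal(a@age, b@age, tolerance = 1e-9)
  expect_equal(a@period, b@period, tolerance = 1e-9)
  expect_equal(a@cohort, b@cohort, tolerance = 1e-9)
  expect_equal(a@mu, b@mu, tolerance = 1e-9)
})
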