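## MCMC layer: conjugate precision updates, a reference R implementation of
## the single-component MH effect updates, and the full chain driver backed
## by the compiled sweep.

#' Configure the MCMC sampler
#'
#' @param seed integer RNG seed (mandatory; never defaulted silently)
#' @param iterations total sweeps (default 50,000)
#' @param burnIn discarded initial sweeps (default 10,000)
#' @param thin keep every thin-th post burn-in sweep (default 10)
#' @param proposalScale initial Gaussian random-walk proposal sd
#' @param adapt adapt proposal scales during burn-in towards ~40%
#'   acceptance (default TRUE); adaptation stops at the end of burn-in so
#'   retained draws target the exact posterior
#' @return an \linkS4class{MCMCConfig}
#' @export
mcmcConfig <- function(seed, iterations = 50000, burnIn = 10000, thin = 10,
                       proposalScale = 0.1, adapt = TRUE) {
  if (missing(seed)) stop("seed is mandatory")
  new("MCMCConfig", iterations = as.integer(iterations),
      burnIn = as.integer(burnIn), thin = as.integer(thin),
      seed = as.integer(seed), proposalScale = as.numeric(proposalScale),
      adapt = isTRUE(adapt))
}

#' Full conditional of an RW2 precision
#'
#' Given effects x with RW2 prior and kappa ~ Gamma(shape, rate), the full
#' conditional is Gamma(shape + rank(Q)/2, rate + x'Qx/2) with
#' rank(Q) = dim - 2. For example, I = 17 age effects with prior shape 0.5
#' give full-conditional shape 0.5 + 15/2 = 8.
#'
#' @param effects numeric effect vector of length \code{prior@dim}
#' @param prior an \linkS4class{RW2Prior}
#' @return list with elements \code{shape} and \code{rate}
#' @export
precisionFullConditional <- function(effects, prior) {
  stopifnot(is(prior, "RW2Prior"))
  if (length(effects) != prior@dim)
    stop("effects length does not match prior dim")
  qf <- rw2QuadraticForm(effects)
  if (!is.finite(qf)) stop("non-finite RW2 quadratic form")
  list(shape = prior@shape + 0.5 * (prior@dim - 2),
       rate = prior@rate + 0.5 * qf)
}

#' Draw an RW2 precision from its conjugate full conditional
#'
#' @inheritParams precisionFullConditional
#' @param n number of draws (default 1)
#' @return numeric draws from the full-conditional Gamma
#' @examples
#' set.seed(1)
#' samplePrecision(rnorm(17), rw2Prior(17, 0.5, 5e-4))
#' @export
samplePrecision <- function(effects, prior, n = 1) {
  fc <- precisionFullConditional(effects, prior)
  rgamma(n, shape = fc$shape, rate = fc$rate)
}

#' One Metropolis-Hastings sweep over an effect block (reference
#' implementation)
#'
#' Updates each component of the chosen block once by a Gaussian
#' random-walk proposal targeting the Poisson log-likelihood plus the
#' block's RW2 log prior (flat prior for the intercept), leaving the state
#' unchanged on rejection. This plain-R implementation defines the update
#' the compiled chain driver performs; it is used directly in the
#' distributional tests.
#'
#' @param state an \linkS4class{APCState}
#' @param block "intercept", "age", "period" or "cohort"
#' @param grid an \linkS4class{APCGrid}
#' @param prior the block's \linkS4class{RW2Prior} (ignored for the
#'   intercept)
#' @param scale proposal sd
#' @return list with the updated \code{state} and the \code{accepted} count
#' @export
updateEffectBlock <- function(state, block, grid, prior = NULL,
                              scale = 0.1) {
  block <- match.arg(block, c("intercept", "age", "period", "cohort"))
  y <- cases(grid)
  m <- personYears(grid) * exp(.linear_predictor(grid, state)) / 1e5
  accepted <- 0L
  if (block == "intercept") {
    delta <- rnorm(1, 0, scale)
    dll <- delta * sum(y) - expm1(delta) * sum(m)
    if (log(runif(1)) < dll) {
      state@mu <- state@mu + delta
      accepted <- 1L
    }
    return(list(state = state, accepted = accepted))
  }
  kappa <- switch(block, age = state@kappaAge, period = state@kappaPeriod,
                  cohort = state@kappaCohort)
  x <- slot(state, block)
  if (is.null(prior) || prior@dim != length(x))
    stop("prior must match the block's effect length")
  Q <- prior@Q
  kmap <- cohortIndexMap(grid)
  cellsums <- function(idx) switch(
    block,
    age = c(sum(y[idx, ]), sum(m[idx, ])),
    period = c(sum(y[, idx]), sum(m[, idx])),
    cohort = c(sum(y[kmap == idx]), sum(m[kmap == idx])))
  for (idx in seq_along(x)) {
    s <- cellsums(idx)
    delta <- rnorm(1, 0, scale)
    dq <- 2 * delta * sum(Q[idx, ] * x) + delta^2 * Q[idx, idx]
    dpost <- delta * s[1] - expm1(delta) * s[2] - 0.5 * kappa * dq
    if (log(runif(1)) < dpost) {
      x[idx] <- x[idx] + delta
      accepted <- accepted + 1L
      scl <- exp(delta)
      if (block == "age") m[idx, ] <- m[idx, ] * scl
      else if (block == "period") m[, idx] <- m[, idx] * scl
      else m[kmap == idx] <- m[kmap == idx] * scl
    }
  }
  slot(state, block) <- x
  list(state = state, accepted = accepted)
}

## vectorized canonicalization of draw matrices (see applyIdentifiability)
.canonicalize_draws <- function(mu, A, P, C, M) {
  I <- ncol(A); J <- ncol(P); K <- ncol(C)
  kk <- seq_len(K); wk <- kk - mean(kk)
  g <- as.numeric(C %*% wk) / sum(wk * wk)
  C <- C - g %*% t(wk)
  A <- A - (g * M) %*% t(seq_len(I))
  P <- P + g %*% t(seq_len(J))
  mu <- mu + g * (M * I - mean(kk))
  mu <- mu + rowMeans(A) + rowMeans(P) + rowMeans(C)
  list(mu = mu, age = A - rowMeans(A), period = P - rowMeans(P),
       cohort = C - rowMeans(C))
}

#' Run the Metropolis-within-Gibbs chain
#'
#' Each sweep updates the intercept, age, period and cohort blocks by
#' single-component Gaussian random-walk MH (see [updateEffectBlock()]) and
#' then draws the three RW2 precisions exactly from their conjugate Gamma
#' full conditionals. Proposal scales are adapted during burn-in only.
#' Burn-in is discarded, thinning applied, and every retained state is
#' canonicalized with [applyIdentifiability()]. Fully reproducible given
#' the config seed.
#'
#' @param grid an \linkS4class{APCGrid} (I >= 3, J >= 3)
#' @param config an \linkS4class{MCMCConfig}
#' @param priors named list of \linkS4class{RW2Prior}s for age, period and
#'   cohort; defaults to [defaultPriors()]
#' @return a \linkS4class{PosteriorDraws}
#' @examples
#' cfg <- simConfig(seed = 1, years = 1990:1999, horizon = 0,
#'                  personYears = 1e6)
#' grid <- toAPCGrid(simulateIncidence(makeTrueEffects(cfg), cfg),
#'                   "synthetic", "both", buildAgeGrid(0, 84, 5))
#' draws <- runChain(grid, mcmcConfig(seed = 1, iterations = 600,
#'                                    burnIn = 100, thin = 5))
#' draws
#' @export
runChain <- function(grid, config, priors = defaultPriors(grid)) {
  stopifnot(is(grid, "APCGrid"), is(config, "MCMCConfig"))
  I <- nrow(grid); J <- ncol(grid); M <- widthRatio(grid)
  K <- M * (I - 1L) + J
  for (nm in c("age", "period", "cohort"))
    if (!is(priors[[nm]], "RW2Prior")) stop("priors$", nm, " must be RW2Prior")
  if (priors$age@dim != I || priors$period@dim != J || priors$cohort@dim != K)
    stop("prior dims must be (I, J, K) = (", I, ", ", J, ", ", K, ")")
  set.seed(config@seed)
  res <- apc_gibbs_cpp(
    y = cases(grid), off = personYears(grid) / 1e5,
    kmap = cohortIndexMap(grid), K = K,
    alphas = c(priors$age@shape, priors$period@shape, priors$cohort@shape),
    lambdas = c(priors$age@rate, priors$period@rate, priors$cohort@rate),
    Qa = priors$age@Q, Qp = priors$period@Q, Qc = priors$cohort@Q,
    iterations = config@iterations, burnin = config@burnIn,
    thin = config@thin, scales0 = rep(config@proposalScale, 4),
    adapt = config@adapt)
  cn <- .canonicalize_draws(res$mu, res$age, res$period, res$cohort, M)
  kap <- res$kappa
  colnames(kap) <- c("age", "period", "cohort")
  new("PosteriorDraws", mu = cn$mu, age = cn$age, period = cn$period,
      cohort = cn$cohort, kappa = kap, logPosterior = res$logPosterior,
      acceptanceRates = res$acceptance, grid = grid, config = config)
}

#' Posterior mean fitted rates
#'
#' Posterior mean of the fitted rate surface exp(mu + a_i + p_j + c_k), per
#' 100,000 person-years, averaged over retained draws.
#'
#' @param draws a \linkS4class{PosteriorDraws}
#' @return an I x J matrix of rates per 100,000
#' @export
fittedRates <- function(draws) {
  stopifnot(is(draws, "PosteriorDraws"))
  grid <- draws@grid
  I <- nrow(grid); J <- ncol(grid)
  kmap <- cohortIndexMap(grid)
  acc <- matrix(0, I, J)
  for (r in seq_len(nDraws(draws))) {
    eta <- draws@mu[r] + outer(draws@age[r, ], draws@period[r, ], "+") +
      matrix(draws@cohort[r, kmap], I, J)
    acc <- acc + exp(eta)
  }
  out <- acc / nDraws(draws)
  dimnames(out) <- dimnames(cases(grid))
  out
}
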