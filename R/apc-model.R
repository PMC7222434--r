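## Mathematical core of the Bayesian APC model: RW2 structure matrix and
## prior density, cohort indexing, Poisson likelihood with person-years
## offset, and the identifiability convention.

#' RW2 structure matrix
#'
#' Returns Q = D'D where D is the (dim-2) x dim second-difference operator
#' with rows (..., 1, -2, 1, ...). Q is symmetric, positive semi-definite
#' with rank dim - 2, its rows sum to zero, and it annihilates constant and
#' linear vectors; its interior band is (1, -4, 6, -4, 1). a'Qa equals the
#' sum of squared second differences of a, the quadratic form penalized by
#' the RW2 prior.
#'
#' @param dim effect-vector length (>= 3)
#' @return a dim x dim numeric matrix
#' @examples
#' buildStructureMatrix(3)
#' @export
buildStructureMatrix <- function(dim) {
  dim <- as.integer(dim)
  if (is.na(dim) || dim < 3L) stop("dim must be >= 3")
  D <- diff(diag(dim), differences = 2)
  crossprod(D)
}

#' RW2 penalty: sum of squared second differences
#'
#' Computes sum_{i=3}^I (a_i - 2 a_{i-1} + a_{i-2})^2, identical to a'Qa for
#' the structure matrix of [buildStructureMatrix()]. Zero exactly on
#' constant and linear vectors.
#'
#' @param effects numeric vector of length >= 3
#' @return a non-negative scalar
#' @examples
#' rw2QuadraticForm(c(0, 0, 1))  # 1
#' rw2QuadraticForm(1:10)        # 0: linear
#' @export
rw2QuadraticForm <- function(effects) {
  if (length(effects) < 3L) stop("need at least 3 effects")
  if (any(!is.finite(effects))) stop("effects must be finite")
  sum(diff(effects, differences = 2)^2)
}

#' Unnormalized RW2 log prior density
#'
#' log f(a | kappa) = ((dim - 2)/2) log(kappa) - (kappa/2) a'Qa, the
#' Gaussian smoothing prior on second differences with precision kappa; the
#' exponent (dim - 2)/2 is half the rank of Q.
#'
#' @param effects numeric vector of length >= 3
#' @param kappa positive precision
#' @return scalar log density (unnormalized)
#' @export
rw2LogDensity <- function(effects, kappa) {
  if (length(kappa) != 1L || is.na(kappa) || kappa <= 0)
    stop("kappa must be a single positive number")
  d <- length(effects)
  ((d - 2) / 2) * log(kappa) - (kappa / 2) * rw2QuadraticForm(effects)
}

#' Construct an RW2 prior
#'
#' @param dim effect length (>= 3)
#' @param shape,rate Gamma hyperprior parameters for the precision kappa
#' @return an \linkS4class{RW2Prior}
#' @details The defaults used for the three APC blocks are shape 0.5 / rate
#'   0.0005 for age and shape 1 / rate 0.00005 for period and cohort; see
#'   [defaultPriors()].
#' @export
rw2Prior <- function(dim, shape, rate) {
  new("RW2Prior", dim = as.integer(dim), Q = buildStructureMatrix(dim),
      shape = as.numeric(shape), rate = as.numeric(rate))
}

#' Default RW2 priors for the three effect blocks
#'
#' Gamma hyperparameters (shape, rate): age (0.5, 0.0005), period
#' (1, 0.00005), cohort (1, 0.00005) — weakly informative, favouring smooth
#' effect curves.
#'
#' @param grid an \linkS4class{APCGrid}
#' @return named list of \linkS4class{RW2Prior} objects (age, period,
#'   cohort)
#' @export
defaultPriors <- function(grid) {
  stopifnot(is(grid, "APCGrid"))
  I <- nrow(grid); J <- ncol(grid); M <- widthRatio(grid)
  list(age = rw2Prior(I, 0.5, 5e-4),
       period = rw2Prior(J, 1, 5e-5),
       cohort = rw2Prior(M * (I - 1L) + J, 1, 5e-5))
}

#' Cohort index of an (age, period) cell
#'
#' With I age groups and width ratio M (age-class width / period width), the
#' birth cohort of cell (i, j) is k = M(I - i) + j: the oldest age group in
#' the first period is cohort 1, k decreases with age and increases with
#' period, and K = M(I - 1) + J indexes the youngest cohort of the last
#' observed period.
#'
#' @param i,j age and period indices (1-based; vectorized)
#' @param I number of age groups
#' @param M width ratio (>= 1)
#' @return integer cohort indices
#' @examples
#' cohortIndex(17, 1, I = 17, M = 5)  # 1
#' cohortIndex(1, 28, I = 17, M = 5)  # 108
#' @export
cohortIndex <- function(i, j, I, M = 1L) {
  i <- as.integer(i); j <- as.integer(j)
  I <- as.integer(I); M <- as.integer(M)
  if (I < 1L || M < 1L) stop("need I >= 1 and M >= 1")
  if (any(i < 1L | i > I)) stop("age index out of range 1..I")
  if (any(j < 1L)) stop("period index must be >= 1")
  M * (I - i) + j
}

#' Construct an APC parameter state
#'
#' @param mu intercept on the log-rate scale (rates per 100,000)
#' @param age,period,cohort effect vectors
#' @param kappaAge,kappaPeriod,kappaCohort positive precisions
#' @return an \linkS4class{APCState}
#' @export
apcState <- function(mu, age, period, cohort, kappaAge = 1,
                     kappaPeriod = 1, kappaCohort = 1) {
  new("APCState", mu = as.numeric(mu), age = as.numeric(age),
      period = as.numeric(period), cohort = as.numeric(cohort),
      kappaAge = as.numeric(kappaAge), kappaPeriod = as.numeric(kappaPeriod),
      kappaCohort = as.numeric(kappaCohort))
}

## log-rate surface eta_ij = mu + a_i + p_j + c_k(i,j) for the grid's layout
.linear_predictor <- function(grid, state) {
  I <- nrow(grid); J <- ncol(grid)
  if (length(state@age) != I || length(state@period) < J)
    stop("state dimensions do not match the grid")
  M <- grid@widthRatio
  kmap <- outer(seq_len(I), seq_len(J), function(i, j) M * (I - i) + j)
  if (max(kmap) > length(state@cohort))
    stop("cohort vector shorter than the grid's cohort range")
  state@mu + outer(state@age, state@period[seq_len(J)], "+") +
    matrix(state@cohort[kmap], I, J)
}

#' Poisson log-likelihood of an APC state
#'
#' Observation model: y_ij ~ Poisson(mu_ij) with mean
#' mu_ij = n_ij exp(mu + a_i + p_j + c_k(i,j)) / 1e5, i.e. a log link with
#' person-years offset and rates on the per-100,000 scale. Returns
#' sum_ij [ y_ij log(mu_ij) - mu_ij ], dropping the y! constant.
#'
#' @param grid an \linkS4class{APCGrid}
#' @param state an \linkS4class{APCState}
#' @return scalar log-likelihood (up to an additive constant)
#' @export
poissonLogLik <- function(grid, state) {
  eta <- .linear_predictor(grid, state)
  if (any(!is.finite(eta))) stop("non-finite linear predictor")
  m <- personYears(grid) * exp(eta) / 1e5
  y <- cases(grid)
  sum(y * log(m) - m)
}

#' Canonicalize an APC state (identifiability convention)
#'
#' The APC decomposition is unidentified: because k = M(I - i) + j, one
#' linear combination of the age, period and cohort slopes can be shifted
#' between blocks without changing any fitted rate. The canonical form used
#' throughout this package removes the cohort vector's linear component
#' (transferring it into the period effect, the age effect and the
#' intercept) and centers all three vectors to sum zero, absorbing means
#' into the intercept. The period effect then carries the entire
#' identifiable per-calendar-year secular trend — the convention required
#' for projections, which extend the period walk. Fitted cell rates are
#' unchanged (to 1e-10 relative) and the map is idempotent.
#'
#' @param state an \linkS4class{APCState}
#' @return the canonicalized \linkS4class{APCState}
#' @export
applyIdentifiability <- function(state) {
  a <- state@age; p <- state@period; cc <- state@cohort
  I <- length(a); J <- length(p); K <- length(cc)
  M <- (K - J) / (I - 1)
  if (abs(M - round(M)) > 1e-9 || M < 1)
    stop("effect lengths inconsistent with K = M(I-1)+J")
  M <- round(M)
  kk <- seq_len(K)
  wk <- kk - mean(kk)
  g <- sum(wk * cc) / sum(wk * wk)       # cohort drift
  cc <- cc - g * wk
  a <- a - g * M * seq_len(I)
  p <- p + g * seq_len(J)
  mu <- state@mu + g * (M * I - mean(kk))
  mu <- mu + mean(a) + mean(p) + mean(cc)
  apcState(mu, a - mean(a), p - mean(p), cc - mean(cc),
           state@kappaAge, state@kappaPeriod, state@kappaCohort)
}
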