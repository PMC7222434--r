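## Projection layer: stochastic extension of the RW2 walks, per-draw future
## rates, and HDI summaries.

#' Highest-density interval from samples
#'
#' The shortest contiguous interval containing ceiling(mass * n) of the
#' sorted samples — the empirical shortest-interval HDI estimator (no
#' density smoothing), deterministic given the samples. Ties are broken by
#' the first (lowest) window.
#'
#' @param samples numeric vector (length >= 1)
#' @param mass probability mass in (0, 1); default 0.95
#' @return named numeric c(lower, upper)
#' @examples
#' hdi(c(1, 1, 1))           # degenerate: (1, 1)
#' set.seed(1); hdi(rnorm(1e4))
#' @export
hdi <- function(samples, mass = 0.95) {
  if (!length(samples) || any(!is.finite(samples)))
    stop("samples must be non-empty and finite")
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)")
  n <- length(samples)
  m <- ceiling(mass * n)
  s <- sort(samples)
  if (m >= n) return(c(lower = s[1L], upper = s[n]))
  widths <- s[m:n] - s[seq_len(n - m + 1L)]
  i <- which.min(widths)
  c(lower = s[i], upper = s[i + m - 1L])
}

#' Extend an RW2 trajectory by predictive sampling
#'
#' Sequentially draws x_{T+h} ~ Normal(2 x_{T+h-1} - x_{T+h-2}, 1/kappa):
#' the RW2 predictive distribution, whose mean path is the linear
#' extrapolation of the last two points and whose variance grows with the
#' horizon. kappa = Inf gives the deterministic linear continuation.
#'
#' @param x numeric trajectory (length >= 2)
#' @param kappa positive precision of the RW2 increments
#' @param horizon number of future steps (>= 1)
#' @return the extended vector, length(x) + horizon
#' @examples
#' extendRandomWalk(c(0, 1, 2), Inf, 3)  # 0 1 2 3 4 5
#' @export
extendRandomWalk <- function(x, kappa, horizon) {
  if (length(x) < 2L) stop("need at least 2 observed points")
  if (length(kappa) != 1L || is.na(kappa) || kappa <= 0)
    stop("kappa must be a single positive number")
  horizon <- as.integer(horizon)
  if (horizon < 1L) stop("horizon must be >= 1")
  sdstep <- if (is.infinite(kappa)) 0 else 1 / sqrt(kappa)
  out <- c(x, numeric(horizon))
  Tn <- length(x)
  for (h in seq_len(horizon))
    out[Tn + h] <- rnorm(1, 2 * out[Tn + h - 1L] - out[Tn + h - 2L], sdstep)
  out
}

#' Project future cases and age-standardized rates with HDIs
#'
#' For every retained posterior draw, the period effect is extended
#' \code{horizon} steps by RW2 predictive sampling with that draw's period
#' precision, and the cohort walk is likewise extended to cover the cohorts
#' newly entering the grid (or those new cohort effects are pinned at zero
#' with \code{newCohorts = "zero"}). Future cell rates
#' lambda_ih = exp(mu + a_i + p_{J+h} + c_k) and expected cases
#' lambda * n / 1e5 are computed per draw; per-year totals and ASRs are
#' summarized by their posterior mean and 95% HDI. Summaries use the same
#' retained draws as the fit, so case and ASR intervals are internally
#' coherent.
#'
#' @param draws a \linkS4class{PosteriorDraws}
#' @param futureN I x horizon matrix (or scalar) of future person-years;
#'   may be zero (zero projected cases; ASR still defined from rates)
#' @param standard a \linkS4class{StandardPopulation}
#' @param horizon number of future periods (default: columns of
#'   \code{futureN})
#' @param mass HDI mass (default 0.95)
#' @param newCohorts "extend" (default) or "zero"
#' @param seed optional seed for the extension noise; defaults to the
#'   chain seed combined with stream "project"
#' @return a \linkS4class{ProjectionResult}
#' @export
projectIncidence <- function(draws, futureN, standard,
                             horizon = NULL, mass = 0.95,
                             newCohorts = c("extend", "zero"),
                             seed = NULL) {
  stopifnot(is(draws, "PosteriorDraws"), is(standard, "StandardPopulation"))
  newCohorts <- match.arg(newCohorts)
  grid <- draws@grid
  I <- nrow(grid); J <- ncol(grid); M <- widthRatio(grid)
  if (is.null(horizon))
    horizon <- if (is.matrix(futureN)) ncol(futureN) else
      stop("horizon required when futureN is scalar")
  horizon <- as.integer(horizon)
  if (horizon < 1L) stop("horizon must be >= 1")
  if (!is.matrix(futureN)) futureN <- matrix(futureN, I, horizon)
  if (!all(dim(futureN) == c(I, horizon)))
    stop("futureN must be I x horizon")
  if (any(!is.finite(futureN)) || any(futureN < 0))
    stop("future person-years must be finite and >= 0")
  w <- standard@weights
  if (length(w) != I) stop("standard population does not match the grid")
  set.seed(if (is.null(seed)) deriveSeed(draws@config@seed, "project")
           else seed)
  R <- nDraws(draws)
  step <- diff(gridYears(grid))[1L]
  years <- max(gridYears(grid)) + step * seq_len(horizon)
  kfut <- outer(seq_len(I), J + seq_len(horizon),
                function(i, j) M * (I - i) + j)
  casesD <- matrix(0, R, horizon)
  asrD <- matrix(0, R, horizon)
  ageRateD <- array(0, dim = c(R, I, horizon))
  for (r in seq_len(R)) {
    pext <- extendRandomWalk(draws@period[r, ], draws@kappa[r, "period"],
                             horizon)
    cext <- if (newCohorts == "extend")
      extendRandomWalk(draws@cohort[r, ], draws@kappa[r, "cohort"], horizon)
    else c(draws@cohort[r, ], rep(0, horizon))
    lam <- exp(draws@mu[r] + outer(draws@age[r, ], pext[J + seq_len(horizon)],
                                   "+") + matrix(cext[kfut], I, horizon))
    ageRateD[r, , ] <- lam
    casesD[r, ] <- colSums(lam * futureN) / 1e5
    asrD[r, ] <- as.numeric(crossprod(w, lam))
  }
  hlo <- function(m) apply(m, 2, function(v) hdi(v, mass))
  hc <- hlo(casesD); ha <- hlo(asrD)
  new("ProjectionResult", years = as.integer(years),
      casesMean = colMeans(casesD), casesLower = hc[1, ],
      casesUpper = hc[2, ], asrMean = colMeans(asrD),
      asrLower = ha[1, ], asrUpper = ha[2, ], casesDraws = casesD,
      asrDraws = asrD, ageRateDraws = ageRateD, mass = mass)
}
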