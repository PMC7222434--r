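## Pipeline entry point wiring the stages (simulate / fit / project /
## trends / bench) with YAML config, per-stage derived seeds, run manifests
## and a run.log. A thin command-line wrapper lives in
## inst/scripts/apc-pipeline.R.

#' Persist posterior draws as text
#'
#' Writes one CSV row per retained state (intercept, flattened effects,
#' precisions, log posterior) plus a JSON sidecar recording the sampler
#' config, acceptance rates and the full grid (years, age grid, width
#' ratio, case and person-years matrices), so the draws object — and any
#' artifact derived from it — is regenerable from the two files alone.
#'
#' @param draws a \linkS4class{PosteriorDraws}
#' @param path CSV path; the sidecar is written next to it as
#'   \code{<path>.meta.json}
#' @return the path, invisibly
#' @export
writePosteriorDraws <- function(draws, path) {
  stopifnot(is(draws, "PosteriorDraws"))
  g <- draws@grid
  flat <- data.frame(mu = draws@mu)
  add <- function(prefix, m) {
    colnames(m) <- paste0(prefix, seq_len(ncol(m)))
    cbind(flat, m)
  }
  flat <- add("a", draws@age); flat <- add("p", draws@period)
  flat <- add("c", draws@cohort)
  flat$kappa_age <- draws@kappa[, "age"]
  flat$kappa_period <- draws@kappa[, "period"]
  flat$kappa_cohort <- draws@kappa[, "cohort"]
  flat$log_posterior <- draws@logPosterior
  ## %.17g round-trips doubles exactly through the text file
  flat[] <- lapply(flat, function(col) sprintf("%.17g", col))
  write.csv(flat, path, row.names = FALSE, quote = FALSE)
  meta <- list(
    years = gridYears(g), age_lower = ageLowerBounds(ageGrid(g)),
    age_width = ageGrid(g)@width, width_ratio = widthRatio(g),
    cases = as.numeric(cases(g)), person_years = as.numeric(personYears(g)),
    mcmc = list(iterations = draws@config@iterations,
                burn_in = draws@config@burnIn, thin = draws@config@thin,
                seed = draws@config@seed,
                proposal_scale = draws@config@proposalScale,
                adapt = draws@config@adapt),
    acceptance = as.list(draws@acceptanceRates))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Reload posterior draws written by [writePosteriorDraws()]
#'
#' @param path the CSV path
#' @return a \linkS4class{PosteriorDraws}
#' @export
readPosteriorDraws <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  flat <- read.csv(path)
  ag <- new("AgeGrid", lowerBounds = as.integer(meta$age_lower),
            width = as.integer(meta$age_width))
  I <- length(meta$age_lower); J <- length(meta$years)
  se <- SummarizedExperiment(
    assays = list(cases = matrix(meta$cases, I, J),
                  personYears = matrix(meta$person_years, I, J)),
    rowData = DataFrame(ageLower = ageLowerBounds(ag),
                        row.names = ageLabels(ag)),
    colData = DataFrame(year = as.integer(meta$years),
                        row.names = as.character(meta$years)))
  grid <- new("APCGrid", se, ageGrid = ag,
              widthRatio = as.integer(meta$width_ratio))
  cfg <- mcmcConfig(seed = meta$mcmc$seed,
                    iterations = meta$mcmc$iterations,
                    burnIn = meta$mcmc$burn_in, thin = meta$mcmc$thin,
                    proposalScale = meta$mcmc$proposal_scale,
                    adapt = meta$mcmc$adapt)
  pick <- function(prefix, d)
    as.matrix(flat[paste0(prefix, seq_len(d))])
  K <- as.integer(meta$width_ratio) * (I - 1L) + J
  kap <- cbind(age = flat$kappa_age, period = flat$kappa_period,
               cohort = flat$kappa_cohort)
  new("PosteriorDraws", mu = flat$mu, age = pick("a", I),
      period = pick("p", J), cohort = pick("c", K), kappa = kap,
      logPosterior = flat$log_posterior,
      acceptanceRates = unlist(meta$acceptance), grid = grid, config = cfg)
}

.cfg_get <- function(config, path, default = NULL, required = FALSE) {
  node <- config
  for (f in strsplit(path, ".", fixed = TRUE)[[1L]]) {
    node <- node[[f]]
    if (is.null(node)) break
  }
  if (is.null(node)) {
    if (required) stop("config validation: missing field '", path, "'",
                       call. = FALSE)
    return(default)
  }
  node
}

.age_grid_from <- function(config, key) {
  a <- .cfg_get(config, key, default = list())
  buildAgeGrid(a$min %||% 0, a$max %||% 84, a$width %||% 5)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

.mcmc_from <- function(config, key, seed) {
  m <- .cfg_get(config, key, default = list())
  mcmcConfig(seed = seed, iterations = m$iterations %||% 50000,
             burnIn = m$burn_in %||% 10000, thin = m$thin %||% 10,
             proposalScale = m$proposal_scale %||% 0.1,
             adapt = m$adapt %||% TRUE)
}

.manifest <- function(outdir, command, config, seed, inputs = character()) {
  checksums <- if (length(inputs))
    as.list(tools::md5sum(inputs[file.exists(inputs)])) else list()
  jsonlite::write_json(
    list(command = command, seed = seed,
         package_version = as.character(utils::packageVersion("apcProj")),
         input_md5 = checksums, config = config),
    file.path(outdir, paste0("manifest_", command, ".json")),
    auto_unbox = TRUE, digits = NA, null = "null")
}

#' Run one pipeline stage
#'
#' Stages mirror the analysis workflow: \strong{simulate} a synthetic
#' registry with held-out future truth; \strong{fit} the Bayesian APC model
#' to one series (after fluctuation screening, which is logged);
#' \strong{project} future cases and ASRs from persisted draws;
#' \strong{trends} — AAPC tables for observed (unweighted) and projected
#' (1/se-weighted) ASR series with trend labels; \strong{bench} — the
#' forecaster comparison. Each stage writes its output CSVs plus a
#' manifest (config echo, seed, package version, input checksums) under
#' \code{outdir}, appends to \code{run.log}, and draws its randomness from
#' a stage-named stream derived from the single config seed.
#'
#' @param config a YAML file path or an equivalent nested list; must
#'   contain a \code{seed} unless \code{seed} is given
#' @param command one of "simulate", "fit", "project", "trends", "bench"
#' @param outdir output directory (default \code{config$outdir})
#' @param seed optional integer overriding \code{config$seed}
#' @param verbose echo log lines to stderr
#' @return invisible list of written artifact paths
#' @export
runPipeline <- function(config,
                        command = c("simulate", "fit", "project", "trends",
                                    "bench"),
                        outdir = NULL, seed = NULL, verbose = FALSE) {
  command <- match.arg(command)
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("config validation: missing field 'config' (file not found: ",
           config, ")", call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config validation: missing field 'config'",
                             call. = FALSE)
  seed <- seed %||% .cfg_get(config, "seed", required = TRUE)
  seed <- as.integer(seed)
  outdir <- outdir %||% .cfg_get(config, "outdir", required = TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(outdir, "run.log")
  log <- function(...) {
    line <- paste0("[", command, "] ", sprintf(...))
    cat(line, "\n", sep = "", file = logfile, append = TRUE)
    if (verbose) message(line)
  }
  artifacts <- character()
  out <- function(name) {
    artifacts[[length(artifacts) + 1L]] <<- file.path(outdir, name)
    file.path(outdir, name)
  }

  if (command == "simulate") {
    s <- .cfg_get(config, "simulate", default = list())
    yr <- s$years %||% c(1990, 2017)
    cfg <- simConfig(seed = deriveSeed(seed, "simulate"),
                     ageGrid = .age_grid_from(config, "simulate.age"),
                     years = yr[1L]:yr[2L], horizon = s$horizon %||% 13,
                     baseRate = s$base_rate %||% 5,
                     periodDrift = s$period_drift %||% 0.02,
                     periodWiggleSd = s$period_wiggle_sd %||% 0.005,
                     cohortWiggleSd = s$cohort_wiggle_sd %||% 0.01,
                     personYears = s$person_years %||% 1e7,
                     overdispersion = s$overdispersion %||% 0)
    truth <- makeTrueEffects(cfg)
    tab <- simulateIncidence(truth, cfg)
    writeIncidenceTable(tab[tab$year <= max(cfg@years), ], out("incidence.csv"))
    if (cfg@horizon > 0)
      writeIncidenceTable(tab[tab$year > max(cfg@years), ],
                          out("incidence_future.csv"))
    eff <- data.frame(
      block = c("intercept", rep("age", length(truth@age)),
                rep("period", length(truth@period)),
                rep("cohort", length(truth@cohort))),
      index = c(1L, seq_along(truth@age), seq_along(truth@period),
                seq_along(truth@cohort)),
      value = c(truth@mu, truth@age, truth@period, truth@cohort))
    write.csv(eff, out("truth_effects.csv"), row.names = FALSE, quote = FALSE)
    log("simulated %d x %d grid + %d future years (seed stream 'simulate')",
        nrow(truth@lambda), truth@nPast, cfg@horizon)
  } else if (command == "fit") {
    f <- .cfg_get(config, "fit", default = list())
    data_path <- f$data %||% file.path(outdir, "incidence.csv")
    if (!file.exists(data_path))
      stop("config validation: missing field 'fit.data' (file not found: ",
           data_path, ")", call. = FALSE)
    tab <- readIncidenceTable(data_path)
    scr <- screenFluctuations(tab, f$fluctuation_threshold %||% 3)
    log("fluctuation screen (year-over-year total-case ratio > %.3g): %d series retained, %d excluded",
        f$fluctuation_threshold %||% 3, nrow(scr$retained),
        nrow(scr$excluded))
    for (r in seq_len(nrow(scr$excluded)))
      log("excluded %s/%s: %s", scr$excluded$location[r],
          scr$excluded$sex[r], scr$excluded$reason[r])
    loc <- f$location %||% scr$retained$location[1L]
    sx <- f$sex %||% "both"
    grid <- toAPCGrid(scr$table, loc, sx, .age_grid_from(config, "fit.age"),
                      periodWidth = f$period_width %||% 1)
    log("reporting convention: RW2 structure matrix D'D (rows sum to zero); effects centered, secular drift attributed to the period block")
    draws <- runChain(grid, .mcmc_from(config, "fit.mcmc",
                                       deriveSeed(seed, "fit")))
    writePosteriorDraws(draws, out("draws.csv"))
    artifacts[[length(artifacts) + 1L]] <- file.path(outdir,
                                                     "draws.csv.meta.json")
    std <- loadStandardPopulation(f$standard %||% "world2000",
                                  ageGrid(grid))
    write.csv(observedASR(grid, std), out("observed_asr.csv"),
              row.names = FALSE, quote = FALSE)
    log("fit %s/%s: %d draws, acceptance %s", loc, sx, nDraws(draws),
        paste(sprintf("%.2f", draws@acceptanceRates), collapse = "/"))
    .manifest(outdir, command, config, seed, data_path)
  } else if (command == "project") {
    p <- .cfg_get(config, "project", default = list())
    draws_path <- p$draws %||% file.path(outdir, "draws.csv")
    if (!file.exists(draws_path))
      stop("config validation: missing field 'project.draws' (file not found: ",
           draws_path, ")", call. = FALSE)
    draws <- readPosteriorDraws(draws_path)
    horizon <- p$horizon %||% 13
    I <- nrow(draws@grid)
    futureN <- if (!is.null(p$future_population) &&
                   is.character(p$future_population)) {
      m <- as.matrix(read.csv(p$future_population, header = TRUE))
      matrix(as.numeric(m), I, horizon)
    } else matrix(p$future_population %||%
                    personYears(draws@grid)[, ncol(draws@grid)], I, horizon)
    std <- loadStandardPopulation(p$standard %||% "world2000",
                                  ageGrid(draws@grid))
    proj <- projectIncidence(draws, futureN, std, horizon = horizon,
                             newCohorts = p$new_cohorts %||% "extend",
                             seed = deriveSeed(seed, "project"))
    write.csv(data.frame(year = proj@years, cases_mean = proj@casesMean,
                         cases_lo = proj@casesLower,
                         cases_hi = proj@casesUpper,
                         asr_mean = proj@asrMean, asr_lo = proj@asrLower,
                         asr_hi = proj@asrUpper),
              out("projection.csv"), row.names = FALSE, quote = FALSE)
    write.csv(asrSeries(proj), out("projected_asr.csv"), row.names = FALSE,
              quote = FALSE)
    log("projected %d years from %d draws (seed stream 'project')",
        horizon, nDraws(draws))
    .manifest(outdir, command, config, seed, draws_path)
  } else if (command == "trends") {
    t <- .cfg_get(config, "trends", default = list())
    obs_path <- t$observed %||% file.path(outdir, "observed_asr.csv")
    proj_path <- t$projected %||% file.path(outdir, "projected_asr.csv")
    rows <- list()
    if (file.exists(obs_path)) {
      obs <- read.csv(obs_path)
      est <- aapc(obs, weighted = FALSE)
      rows[[1L]] <- data.frame(
        period = sprintf("%d-%d", min(obs$year), max(obs$year)),
        aapc = est@aapc, ci_lo = est@ciLower, ci_hi = est@ciUpper,
        p_value = est@pValue, label = est@label)
    }
    if (file.exists(proj_path)) {
      prj <- read.csv(proj_path)
      est <- aapc(prj, weighted = "seLog" %in% names(prj))
      rows[[length(rows) + 1L]] <- data.frame(
        period = sprintf("%d-%d", min(prj$year), max(prj$year)),
        aapc = est@aapc, ci_lo = est@ciLower, ci_hi = est@ciUpper,
        p_value = est@pValue, label = est@label)
    }
    if (!length(rows))
      stop("config validation: missing field 'trends.observed' (no ASR series found)",
           call. = FALSE)
    write.csv(do.call(rbind, rows), out("trends.csv"), row.names = FALSE,
              quote = FALSE)
    log("AAPC computed for %d series", length(rows))
    .manifest(outdir, command, config, seed,
              c(obs_path, proj_path))
  } else if (command == "bench") {
    b <- .cfg_get(config, "bench", default = list())
    data_path <- .cfg_get(config, "bench.data", required = TRUE)
    tab <- readIncidenceTable(data_path)
    ag <- .age_grid_from(config, "bench.age")
    std <- loadStandardPopulation(b$standard %||% "world2000", ag)
    specs <- lapply(b$models %||% list(
      list(name = "bayesian_apc", kind = "bayesian_apc"),
      list(name = "loglinear", kind = "loglinear"),
      list(name = "natural_spline", kind = "natural_spline")),
      function(m) forecastModelSpec(m$name, m$kind,
                                    m$settings %||% list()))
    bench <- evaluateModels(
      specs, tab, trainEnd = .cfg_get(config, "bench.train_end",
                                      required = TRUE),
      testEnd = .cfg_get(config, "bench.test_end", required = TRUE),
      ageGrid = ag, standard = std, seed = deriveSeed(seed, "bench"),
      mcmc = .mcmc_from(config, "bench.mcmc", seed = 1L),
      score = b$score %||% "asr")
    write.csv(bench$results, out("bench_results.csv"), row.names = FALSE,
              quote = FALSE)
    write.csv(bench$summary, out("bench_summary.csv"), row.names = FALSE,
              quote = FALSE)
    log("benchmark ranking: %s", paste(bench$ranking, collapse = " > "))
    .manifest(outdir, command, config, seed, data_path)
  }
  if (command == "simulate")
    .manifest(outdir, command, config, seed)
  invisible(artifacts)
}
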