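## registry IO: read/validate/reshape long-format incidence records into the
## model's age x period grid representation.

#' Build a contiguous uniform age grid
#'
#' @param minAge,maxAge integer first and last age covered (inclusive)
#' @param width integer class width in years
#' @return an \linkS4class{AgeGrid}
#' @details The span \code{maxAge - minAge + 1} must be divisible by
#'   \code{width} (no ragged last class). The default epidemiological grid
#'   \code{buildAgeGrid(0, 84, 5)} has 17 groups.
#' @examples
#' buildAgeGrid(0, 84, 5)
#' @export
buildAgeGrid <- function(minAge, maxAge, width) {
  minAge <- as.integer(minAge); maxAge <- as.integer(maxAge)
  width <- as.integer(width)
  if (width < 1L) stop("width must be >= 1")
  span <- maxAge - minAge + 1L
  if (span < width) stop("maxAge too small for one full class")
  if (span %% width != 0L)
    stop(sprintf("age span %d is not divisible by width %d", span, width))
  new("AgeGrid", lowerBounds = seq(minAge, maxAge, by = width),
      width = width)
}

.validate_incidence <- function(df) {
  missing_cols <- setdiff(.REC_FIELDS, names(df))
  if (length(missing_cols))
    .fail(paste("schema error: missing columns:",
                paste(missing_cols, collapse = ", ")))
  df$location <- as.character(df$location)
  df$sex <- as.character(df$sex)
  df$year <- as.integer(df$year)
  df$age_group <- as.integer(df$age_group)
  df$cases <- as.numeric(df$cases)
  df$person_years <- as.numeric(df$person_years)
  bad <- list()
  rows <- function(i) sprintf("row %d (%s/%s/%d/age %d)", i, df$location[i],
                              df$sex[i], df$year[i], df$age_group[i])
  i <- which(!df$sex %in% .SEX_LEVELS)
  if (length(i)) bad <- c(bad, paste("invalid sex:", sapply(i, rows)))
  i <- which(is.na(df$cases) | df$cases < 0)
  if (length(i)) bad <- c(bad, paste("negative or missing cases:",
                                     sapply(i, rows)))
  i <- which(is.na(df$person_years) | df$person_years <= 0)
  if (length(i)) bad <- c(bad, paste("non-positive person-years:",
                                     sapply(i, rows)))
  i <- which(df$cases > df$person_years)
  if (length(i)) bad <- c(bad, paste("cases exceed person-years:",
                                     sapply(i, rows)))
  key <- paste(df$location, df$sex, df$year, df$age_group, sep = "|")
  i <- which(duplicated(key))
  if (length(i)) bad <- c(bad, paste("duplicate key:", sapply(i, rows)))
  if (length(bad)) .fail("validation error:", unlist(bad))
  df[.REC_FIELDS]
}

#' Read a long-format incidence table
#'
#' Reads a delimited text file (comma- or tab-separated, autodetected by
#' extension: .tsv/.txt use tabs) holding one record per (location, sex,
#' year, age group) with case counts and person-years, validates it, and
#' returns a data.frame with the canonical columns \code{location}, sex,
#' \code{year}, \code{age_group} (1-based index into the age grid),
#' \code{cases}, \code{person_years}.
#'
#' @param path file path
#' @param dialect optional named character vector mapping canonical column
#'   names to the file's column names, e.g.
#'   \code{c(cases = "val", person_years = "pop")}
#' @return validated incidence data.frame
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeIncidenceTable(data.frame(location = "X", sex = "both",
#'   year = c(2000, 2000), age_group = 1:2, cases = c(5, 7),
#'   person_years = 1e5), tf)
#' readIncidenceTable(tf)
#' @export
readIncidenceTable <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 check.names = FALSE)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      if (!dialect[[canon]] %in% names(df))
        .fail(paste("schema error: dialect column not in file:",
                    dialect[[canon]]))
      names(df)[names(df) == dialect[[canon]]] <- canon
    }
  }
  .validate_incidence(df)
}

#' Write an incidence table
#'
#' Writes the canonical long format with a header, '.' decimal separator and
#' no quoting; integer-valued columns round-trip bit-exactly.
#'
#' @param table incidence data.frame
#' @param path output path (.csv or .tsv)
#' @return the path, invisibly
#' @export
writeIncidenceTable <- function(table, path) {
  table <- .validate_incidence(table)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  write.table(table, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Reshape incidence records into an age x period grid
#'
#' Selects one (location, sex) series and lays its records out as dense
#' I x J case and person-years matrices. Every (year, age group) cell of the
#' selection must be present; total cases and person-years are conserved
#' exactly. With annual input periods the width ratio is
#' M = age-class width; setting \code{periodWidth} to the age-class width
#' pre-aggregates years into blocks, giving the classical equal-interval
#' APC layout with M = 1.
#'
#' @param table incidence data.frame
#' @param location,sex series key
#' @param ageGrid an \linkS4class{AgeGrid}; its group count must cover the
#'   table's \code{age_group} indices
#' @param years optional integer vector of consecutive years to use
#'   (default: all years present for the series)
#' @param periodWidth period width in years (default 1 = annual)
#' @return an \linkS4class{APCGrid}
#' @examples
#' cfg <- simConfig(seed = 1, years = 1990:1999, horizon = 0,
#'                  personYears = 1e6)
#' tab <- simulateIncidence(makeTrueEffects(cfg), cfg)
#' toAPCGrid(tab, "synthetic", "both", ageGrid = buildAgeGrid(0, 84, 5))
#' @export
toAPCGrid <- function(table, location, sex, ageGrid, years = NULL,
                      periodWidth = 1L) {
  table <- .validate_incidence(table)
  periodWidth <- as.integer(periodWidth)
  sel <- table[table$location == location & table$sex == sex, ]
  if (!nrow(sel)) stop("no records for ", location, "/", sex)
  if (is.null(years)) years <- sort(unique(sel$year))
  years <- as.integer(years)
  if (!all(diff(years) == 1L)) stop("years must be consecutive")
  sel <- sel[sel$year %in% years, ]
  I <- nAgeGroups(ageGrid)
  if (I < 3L) stop("age grid has fewer than 3 groups (I < 3)")
  if (any(sel$age_group < 1L | sel$age_group > I))
    stop("age_group indices outside the age grid")
  J0 <- length(years)
  want <- expand.grid(year = years, age_group = seq_len(I))
  have <- paste(sel$year, sel$age_group)
  miss <- want[!paste(want$year, want$age_group) %in% have, ]
  if (nrow(miss))
    .fail("missing cells:", sprintf("(year %d, age group %d)",
                                    miss$year, miss$age_group))
  y <- matrix(0, I, J0); n <- matrix(0, I, J0)
  y[cbind(sel$age_group, match(sel$year, years))] <- sel$cases
  n[cbind(sel$age_group, match(sel$year, years))] <- sel$person_years
  if (periodWidth > 1L) {
    if (J0 %% periodWidth != 0L)
      stop("number of years not divisible by periodWidth")
    grp <- rep(seq_len(J0 %/% periodWidth), each = periodWidth)
    y <- t(rowsum(t(y), grp)); n <- t(rowsum(t(n), grp))
    dimnames(y) <- dimnames(n) <- NULL
    years <- years[seq(1L, J0, by = periodWidth)]
  }
  if (ageGrid@width %% periodWidth != 0L)
    stop("age-class width not divisible by periodWidth")
  M <- ageGrid@width %/% periodWidth
  se <- SummarizedExperiment(
    assays = list(cases = y, personYears = n),
    rowData = DataFrame(ageLower = ageLowerBounds(ageGrid),
                        row.names = ageLabels(ageGrid)),
    colData = DataFrame(year = years, row.names = as.character(years)))
  new("APCGrid", se, ageGrid = ageGrid, widthRatio = as.integer(M))
}

#' Screen series for striking short-interval fluctuations
#'
#' Flags (location, sex) series whose total yearly case counts jump or drop
#' too sharply between consecutive years: a series is excluded when any
#' year-over-year ratio max(r, 1/r) of total cases exceeds
#' \code{ratioThreshold}. Smoothing priors cannot be expected to track such
#' discontinuities, so these series are removed before fitting. The rule and
#' each exclusion are reported by the pipeline log.
#'
#' @param table incidence data.frame
#' @param ratioThreshold exclusion threshold (> 1); default 3
#' @return list with \code{retained} and \code{excluded} data.frames
#'   (location, sex, reason) and \code{table}, the retained records
#' @examples
#' cfg <- simConfig(seed = 1, years = 1990:1995, horizon = 0)
#' tab <- simulateIncidence(makeTrueEffects(cfg), cfg)
#' screenFluctuations(tab)$retained
#' @export
screenFluctuations <- function(table, ratioThreshold = 3) {
  stopifnot(ratioThreshold > 1)
  table <- .validate_incidence(table)
  keys <- unique(table[c("location", "sex")])
  verdict <- lapply(seq_len(nrow(keys)), function(r) {
    sel <- table[table$location == keys$location[r] &
                   table$sex == keys$sex[r], ]
    tot <- tapply(sel$cases, sel$year, sum)
    yrs <- as.integer(names(tot))
    if (length(tot) < 2L) return("too short")
    a <- as.numeric(tot[-length(tot)]); b <- as.numeric(tot[-1])
    ratio <- ifelse(a == 0 & b == 0, 1, pmax(a, b) / pmin(a, b))
    bad <- which(!is.finite(ratio) | ratio > ratioThreshold)
    if (length(bad))
      return(sprintf("case ratio %.3g between %d and %d exceeds %.3g",
                     ratio[bad[1L]], yrs[bad[1L]], yrs[bad[1L] + 1L],
                     ratioThreshold))
    NA_character_
  })
  reason <- unlist(verdict)
  excluded <- cbind(keys[!is.na(reason), , drop = FALSE],
                    reason = reason[!is.na(reason)])
  retained <- keys[is.na(reason), , drop = FALSE]
  rownames(excluded) <- rownames(retained) <- NULL
  keep <- paste(table$location, table$sex) %in%
    paste(retained$location, retained$sex)
  list(retained = retained, excluded = excluded,
       table = table[keep, , drop = FALSE])
}
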