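## WHO World Standard 2000 age distribution (percent of population) for
## 5-year classes 0-4 ... 80-84 plus 85+, as published by WHO (Ahmad et al.
## age-standardization working paper scaling). Weights are renormalized over
## whichever classes the analysis grid covers.
.WORLD2000 <- data.frame(
  age_lower = seq(0L, 85L, by = 5L),
  weight = c(8.86, 8.69, 8.60, 8.47, 8.22, 7.93, 7.61, 7.15, 6.59, 6.04,
             5.37, 4.55, 3.72, 2.96, 2.21, 1.52, 0.91, 0.63))

#' Load a standard population for age standardization
#'
#' Either the embedded "world2000" standard (WHO World Standard 2000 age
#' distribution) or a custom two-column CSV (\code{age_lower},
#' \code{weight}) giving one weight per age group. Weights are matched to
#' the grid's age-class lower bounds and normalized to sum to one.
#'
#' @param source "world2000" or a file path
#' @param ageGrid the \linkS4class{AgeGrid} the weights must cover
#' @return a \linkS4class{StandardPopulation}
#' @examples
#' loadStandardPopulation("world2000", buildAgeGrid(0, 84, 5))
#' @export
loadStandardPopulation <- function(source = "world2000", ageGrid) {
  stopifnot(is(ageGrid, "AgeGrid"))
  if (identical(source, "world2000")) {
    tab <- .WORLD2000
    if (ageGrid@width != 5L)
      stop("the world2000 standard is tabulated in 5-year classes")
    name <- "world2000"
  } else {
    if (!file.exists(source)) stop("standard population file not found: ",
                                   source)
    tab <- read.csv(source, stringsAsFactors = FALSE)
    if (!all(c("age_lower", "weight") %in% names(tab)))
      stop("custom standard needs columns age_lower, weight")
    name <- basename(source)
  }
  lb <- ageLowerBounds(ageGrid)
  idx <- match(lb, tab$age_lower)
  if (anyNA(idx))
    stop(sprintf(
      "standard population does not cover age groups starting at: %s",
      paste(lb[is.na(idx)], collapse = ", ")))
  if (!identical(source, "world2000") && nrow(tab) != length(lb))
    stop(sprintf("standard has %d entries but the grid has %d age groups",
                 nrow(tab), length(lb)))
  w <- as.numeric(tab$weight[idx])
  if (any(!is.finite(w)) || any(w < 0) || sum(w) <= 0)
    stop("weights must be non-negative with a positive sum")
  new("StandardPopulation", weights = w / sum(w), lowerBounds = lb,
      name = name)
}
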