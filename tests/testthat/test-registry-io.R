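test_that("incidence tables round-trip through write/read unchanged", {
  tab <- tinyTable()
  for (ext in c(".csv", ".tsv")) {
    tf <- tempfile(fileext = ext)
    writeIncidenceTable(tab, tf)
    back <- readIncidenceTable(tf)
    expect_equal(back, tab)
    expect_identical(sum(back$cases), sum(tab$cases))
  }
})

test_that("column dialects are remapped and schema errors are caught", {
  tab <- tinyTable()
  names(tab)[names(tab) == "cases"] <- "val"
  tf <- tempfile(fileext = ".csv")
  write.csv(tab, tf, row.names = FALSE)
  expect_error(readIncidenceTable(tf), "schema error")
  back <- readIncidenceTable(tf, dialect = c(cases = "val"))
  expect_equal(back$cases, tinyTable()$cases)
  expect_error(readIncidenceTable(tf, dialect = c(cases = "nope")),
               "schema error")
})

test_that("invalid records are rejected with their keys", {
  tab <- tinyTable()
  expect_error(writeIncidenceTable(rbind(tab, tab[1, ]), tempfile()),
               "duplicate key")
  bad <- tab; bad$cases[2] <- -1
  expect_error(.validate_incidence(bad), "negative or missing cases")
  bad <- tab; bad$person_years[3] <- 0
  expect_error(.validate_incidence(bad), "non-positive person-years")
  bad <- tab; bad$sex[1] <- "unknown"
  expect_error(.validate_incidence(bad), "invalid sex")
  bad <- tab; bad$cases[1] <- bad$person_years[1] + 1
  expect_error(.validate_incidence(bad), "exceed person-years")
})

test_that("age grids cover the span uniformly or fail", {
  g <- buildAgeGrid(0, 84, 5)
  expect_equal(nAgeGroups(g), 17L)
  expect_equal(ageLowerBounds(g), seq(0L, 80L, 5L))
  expect_equal(ageLabels(g)[c(1, 17)], c("0-4", "80-84"))
  expect_equal(nAgeGroups(buildAgeGrid(0, 9, 5)), 2L)  # rejected only at fit
  expect_error(buildAgeGrid(0, 84, 7), "not divisible")
})

test_that("grid reshaping conserves totals exactly and names missing cells", {
  s <- smallScenario(seed = 21)
  sel <- s$tab[s$tab$year <= max(s$cfg@years), ]
  g <- s$grid
  expect_s4_class(g, "APCGrid")
  expect_identical(dim(g), c(17L, 15L))
  expect_identical(sum(cases(g)), sum(sel$cases))
  expect_identical(sum(personYears(g)), sum(sel$person_years))
  ## per-year marginals match the table
  byyear <- tapply(sel$cases, sel$year, sum)
  expect_equal(unname(colSums(cases(g))), unname(as.numeric(byyear)))
  ## deleting one cell is reported by (year, age) pair
  drop1 <- sel[!(sel$year == 1993 & sel$age_group == 4), ]
  expect_error(toAPCGrid(drop1, "synthetic", "both", theAgeGrid),
               "year 1993, age group 4")
  ## too few age groups for RW2
  expect_error(toAPCGrid(sel, "synthetic", "both", buildAgeGrid(0, 9, 5)),
               "I < 3")
})

test_that("period aggregation builds the classical M = 1 layout", {
  s <- smallScenario(seed = 22)
  sel <- s$tab[s$tab$year <= max(s$cfg@years), ]
  g <- toAPCGrid(sel, "synthetic", "both", theAgeGrid, periodWidth = 5)
  expect_identical(dim(g), c(17L, 3L))
  expect_identical(widthRatio(g), 1L)
  expect_identical(sum(cases(g)), sum(sel$cases))
  expect_equal(max(cohortIndexMap(g)), 16L + 3L)
})

test_that("fluctuation screening applies the year-over-year ratio rule", {
  mk <- function(loc, totals) data.frame(
    location = loc, sex = "both", year = seq(2000, by = 1,
                                             length.out = length(totals)),
    age_group = 1L, cases = totals, person_years = 1e6)
  tab <- rbind(mk("steady", rep(100, 4)), mk("jumpy", c(100, 100, 1000, 100)),
               mk("short", 50))
  scr <- screenFluctuations(tab, ratioThreshold = 3)
  expect_identical(scr$retained$location, "steady")
  expect_setequal(scr$excluded$location, c("jumpy", "short"))
  expect_match(scr$excluded$reason[scr$excluded$location == "jumpy"],
               "between 2001 and 2002")
  expect_match(scr$excluded$reason[scr$excluded$location == "short"],
               "too short")
  ## 10x jump is tolerated at threshold 11
  scr11 <- screenFluctuations(tab[tab$location == "jumpy", ],
                              ratioThreshold = 11)
  expect_identical(scr11$retained$location, "jumpy")
  ## invariance under uniform rescaling of all counts
  resc <- tab; resc$cases <- resc$cases * 7
  expect_identical(screenFluctuations(resc, 3)$retained$location, "steady")
})

test_that("standard populations load, normalize and reject mismatches", {
  std <- loadStandardPopulation("world2000", theAgeGrid)
  expect_length(standardWeights(std), 17L)
  expect_equal(sum(standardWeights(std)), 1, tolerance = 1e-12)
  expect_true(all(diff(standardWeights(std)[5:17]) < 0))  # old-age taper
  ## custom uniform file
  tf <- tempfile(fileext = ".csv")
  write.csv(data.frame(age_lower = seq(0, 80, 5), weight = 1),
            tf, row.names = FALSE)
  unif <- loadStandardPopulation(tf, theAgeGrid)
  expect_equal(unname(standardWeights(unif)), rep(1 / 17, 17))
  ## 16-entry file against a 17-group grid
  write.csv(data.frame(age_lower = seq(0, 75, 5), weight = 1),
            tf, row.names = FALSE)
  expect_error(loadStandardPopulation(tf, theAgeGrid), "does not cover")
})
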