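test_that("territory reading validates structure and invariants", {
  tabs <- tinyTables()
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tabs$territories, path, row.names = FALSE)
  got <- readTerritories(path)
  expect_equal(nrow(got), 4)
  expect_equal(got$id, tabs$territories$id)

  bad <- tabs$territories
  bad$population[2] <- 0
  write.csv(bad, path, row.names = FALSE)
  expect_error(readTerritories(path), "positive")

  dup <- tabs$territories
  dup$id[2] <- dup$id[1]
  write.csv(dup, path, row.names = FALSE)
  expect_error(readTerritories(path), "duplicated")

  write.csv(tabs$territories[, -3], path, row.names = FALSE)
  expect_error(readTerritories(path), "missing column")
})

test_that("study write/read round-trip is lossless", {
  study <- smallSynthetic(seed = 3, n = 6)
  dir <- withr::local_tempdir()
  writeStudy(study, dir)
  back <- readStudy(dir)
  expect_equal(lineCounts(back), lineCounts(study))
  expect_equal(odDistances(back), odDistances(study), tolerance = 1e-12)
  expect_equal(odTravelTimes(back), odTravelTimes(study), tolerance = 1e-12)
  expect_equal(as.data.frame(rowData(back))[, c("population", "lon", "lat")],
               as.data.frame(rowData(study))[, c("population", "lon", "lat")],
               tolerance = 1e-12)
  expect_equal(metadata(back)$truth$theta,
               metadata(study)$truth$theta, tolerance = 1e-12)
})

test_that("OD matrix reading rejects malformed input", {
  tabs <- tinyTables()
  od <- odFromCoords(tabs$territories)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(id = rownames(od$distance), od$distance,
                       check.names = FALSE), path, row.names = FALSE)
  m <- readODMatrix(path, "distance", ids = tabs$territories$id)
  expect_identical(dim(m), c(4L, 4L))
  expect_true(all(diag(m) == 0))

  expect_error(readODMatrix(path, "distance", ids = c("a", "b")),
               "reconcile")

  neg <- od$travel_time
  neg[1, 2] <- -5
  write.csv(data.frame(id = rownames(neg), neg, check.names = FALSE),
            path, row.names = FALSE)
  expect_error(readODMatrix(path, "travel_time"), "positive")
})

test_that("line counts read back with correct totals and validation", {
  tabs <- tinyTables()
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tabs$lines, path, row.names = FALSE)
  lines <- readLineCounts(path)
  expect_equal(sum(lines$count[lines$year == "2019"]), 55)

  frac <- tabs$lines
  frac$count[1] <- 2.5
  write.csv(frac, path, row.names = FALSE)
  expect_error(readLineCounts(path), "integer")
})

test_that("merging Greater London sums populations, covariates and lines", {
  tabs <- tinyTables()
  merged <- mergeLondon(tabs$territories, tabs$covariates, tabs$lines)

  expect_equal(merged$territories$population[merged$territories$id == "london"],
               8.9e6 + 1e4)
  lc <- merged$covariates[merged$covariates$id == "london", ]
  expect_equal(lc$knife_crimes, 14000 + 500)

  # conservation of totals
  expect_equal(sum(merged$territories$population),
               sum(tabs$territories$population))
  for (col in c("misuse_admissions", "poisoning_admissions",
                "police_officers", "gdhi", "knife_crimes", "hospital_beds"))
    expect_equal(sum(merged$covariates[[col]]), sum(tabs$covariates[[col]]))
  expect_equal(sum(merged$lines$count), sum(tabs$lines$count))
  got_ta_2019 <- merged$lines$count[merged$lines$destination == "t_a" &
                                      merged$lines$year == "2019"]
  expect_equal(got_ta_2019, 40 + 5)

  # absent constituent: warning and unchanged tables
  expect_warning(
    res <- mergeLondon(tabs$territories[-2, ], tabs$covariates, tabs$lines),
    "must be present")
  expect_equal(res$territories, tabs$territories[-2, ])
})

test_that("merged normalised rates come from summed raw counts, not averaged rates", {
  # a study in which merged London is itself a destination
  tabs <- tinyTables()
  merged <- mergeLondon(tabs$territories, tabs$covariates, tabs$lines)
  lines <- data.frame(origin = "t_a", destination = c("london", "t_b"),
                      year = "2019", count = c(3, 2))
  od <- odFromCoords(merged$territories)
  study <- LinesStudy(merged$territories, merged$covariates, lines,
                      od$distance, od$travel_time, origin = "t_a")
  w <- normalisedBenefits(study)
  expect_equal(w["london", "knife"], (14000 + 500) * 1e5 / 8.91e6)
  rate_avg <- mean(c(14000 * 1e5 / 8.9e6, 500 * 1e5 / 1e4))
  expect_false(isTRUE(all.equal(w["london", "knife"], rate_avg)))
})

test_that("covariate normalisation follows the per-100k and per-bed rules", {
  tabs <- tinyTables()
  tabs$lines <- tabs$lines[tabs$lines$origin == "metropolitan", ]
  tabs$covariates$knife_crimes[tabs$covariates$id == "t_a"] <- 400
  od <- odFromCoords(tabs$territories)
  study <- LinesStudy(tabs$territories, tabs$covariates, tabs$lines,
                      od$distance, od$travel_time, origin = "metropolitan")
  w <- normalisedBenefits(study)
  expect_equal(w["t_a", "knife"], 400 * 1e5 / 2e6)  # 20 per 100k

  # per-bed mode: admissions relative to beds per capita
  tabs$covariates$misuse_admissions[tabs$covariates$id == "t_b"] <- 500
  tabs$covariates$hospital_beds[tabs$covariates$id == "t_b"] <- 2000
  tabs$territories$population[tabs$territories$id == "t_b"] <- 1e6
  od <- odFromCoords(tabs$territories)
  study <- LinesStudy(tabs$territories, tabs$covariates, tabs$lines,
                      od$distance, od$travel_time, origin = "metropolitan")
  wb <- normalisedBenefits(study, admissions_mode = "per_bed")
  expect_equal(wb["t_b", "misuse"], 500 / (2000 / 1e6))  # 250000
  # non-admission covariates keep the per-100k rule in per_bed mode
  expect_equal(wb["t_b", "knife"], w["t_b", "knife"])

  # zero events are stored as zero rate (rejected later under a log)
  tabs$covariates$knife_crimes[tabs$covariates$id == "t_a"] <- 0
  study0 <- LinesStudy(tabs$territories, tabs$covariates, tabs$lines,
                       od$distance, od$travel_time, origin = "metropolitan")
  expect_equal(normalisedBenefits(study0)["t_a", "knife"], 0)

  # zero beds make per_bed mode invalid
  tabs$covariates$hospital_beds[tabs$covariates$id == "t_a"] <- 0
  studyz <- LinesStudy(tabs$territories, tabs$covariates, tabs$lines,
                       od$distance, od$travel_time, origin = "metropolitan")
  expect_error(normalisedBenefits(studyz, admissions_mode = "per_bed"),
               "beds")
})

test_that("normalisation is homogeneous in joint count/population scaling", {
  tabs <- tinyTables()
  tabs$lines <- tabs$lines[tabs$lines$origin == "metropolitan", ]
  od <- odFromCoords(tabs$territories)
  base <- normalisedBenefits(LinesStudy(tabs$territories, tabs$covariates,
                                        tabs$lines, od$distance,
                                        od$travel_time,
                                        origin = "metropolitan"))
  scaled <- tabs
  for (col in c("misuse_admissions", "poisoning_admissions",
                "police_officers", "gdhi", "knife_crimes", "hospital_beds"))
    scaled$covariates[[col]] <- scaled$covariates[[col]] * 3
  scaled$territories$population <- scaled$territories$population * 3
  w2 <- normalisedBenefits(LinesStudy(scaled$territories, scaled$covariates,
                                      scaled$lines, od$distance,
                                      od$travel_time,
                                      origin = "metropolitan"))
  expect_equal(w2, base, tolerance = 1e-12)
})

test_that("study construction enforces the container invariants", {
  tabs <- tinyTables()
  tabs$lines <- tabs$lines[tabs$lines$origin == "metropolitan", ]
  od <- odFromCoords(tabs$territories)
  expect_error(LinesStudy(tabs$territories, tabs$covariates, tabs$lines,
                          od$distance, od$travel_time, origin = "nowhere"),
               "not in the territory table")
  stranger <- tabs$lines
  stranger$destination[1] <- "atlantis"
  expect_error(LinesStudy(tabs$territories, tabs$covariates, stranger,
                          od$distance, od$travel_time,
                          origin = "metropolitan"),
               "unknown destination")
})
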