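test_that("retail variant enumeration spans all covariate subsets", {
  variants <- enumerateRetailVariants(loss = "poisson", train_year = "2019")
  expect_length(variants, 32)
  keys <- vapply(variants, specId, character(1))
  expect_equal(anyDuplicated(keys), 0L)
  sizes <- vapply(variants, function(s) length(s@covariates), integer(1))
  expect_equal(unname(table(sizes)), choose(5, 0:5), ignore_attr = TRUE)

  expect_length(enumerateRetailVariants(character(), "poisson", "2019"), 1)
  expect_length(enumerateRetailVariants(c("misuse", "knife"), "poisson",
                                        "2019"), 4)
  expect_error(enumerateRetailVariants(c("knife", "knife"), "poisson",
                                       "2019"), "duplicated")

  grid <- specGrid("gaussian", "2020")
  expect_length(grid, 34)
  expect_equal(vapply(grid[1:2], function(s) s@family, character(1)),
               c("gravity", "radiation"))
})

test_that("model specs validate their fields", {
  expect_error(ModelSpec("gravity", covariates = "knife", loss = "poisson",
                         train_year = "2019"), "retail")
  expect_error(ModelSpec("retail", covariates = "karate", loss = "poisson",
                         train_year = "2019"), "unknown covariate")
  expect_error(ModelSpec("retail", loss = "huber", train_year = "2019"),
               "loss")
})

test_that("fitted loss never exceeds the loss at theta = 0 or any start", {
  study <- smallSynthetic(seed = 4, n = 8)
  for (family in c("gravity", "retail")) {
    spec <- ModelSpec(family,
                      covariates = if (family == "retail") "knife"
                                   else character(),
                      loss = "poisson", train_year = "2019")
    fit <- fitModel(spec, study)
    expect_true(all(fit@trainLoss <= fit@diagnostics$start_values + 1e-8))
    data <- lineCounts(study)[, "2019"]
    theta0 <- setNames(rep(0, length(fit@theta)), names(fit@theta))
    loss0 <- poissonLoss(data,
                         predictFlows(family, theta0, study, sum(data)),
                         theta = theta0)
    expect_lte(fit@trainLoss, loss0 + 1e-8)
    # predictions conserve each year's outflow
    for (y in studyYears(study))
      expect_equal(sum(fit@flows[[y]]), sum(lineCounts(study)[, y]),
                   tolerance = 1e-9)
  }
})

test_that("symmetric destinations leave gravity tied and the ridge picks 0", {
  territories <- data.frame(
    id = c("o", "a", "b"), name = c("O", "A", "B"),
    population = c(5e6, 1e6, 1e6), lon = c(0, 10, -10), lat = c(0, 0, 0))
  covariates <- data.frame(
    id = territories$id, misuse_admissions = 1, poisoning_admissions = 1,
    police_officers = 1, gdhi = 1, knife_crimes = 1, hospital_beds = 1)
  lines <- data.frame(origin = "o", destination = c("a", "b", "a", "b"),
                      year = c("2019", "2019", "2020", "2020"),
                      count = c(10, 10, 10, 10))
  od <- odFromCoords(territories)
  study <- LinesStudy(territories, covariates, lines, od$distance,
                      od$travel_time, origin = "o")
  fit <- fitModel(ModelSpec("gravity", loss = "poisson",
                            train_year = "2019"), study)
  # equal masses and distances: any (b, c) fits; the penalty selects 0
  expect_equal(unname(fit@theta), c(0, 0), tolerance = 1e-4)
})

test_that("gravity calibration matches an exhaustive grid-search oracle", {
  study <- smallSynthetic(seed = 14, n = 3,
                          truth = list(family = "gravity", b = 0.8,
                                       c = -0.9))
  data <- lineCounts(study)[, "2019"]
  total <- sum(data)
  masses <- rowData(study)$population
  dvec <- odDistances(study)[studyOrigin(study), destinationIds(study)]
  # independent oracle: explicit arithmetic on a parameter grid
  grid_b <- seq(-1, 2, by = 0.05)
  grid_c <- seq(-2, 1, by = 0.05)
  oracle <- Inf; arg <- c(NA, NA)
  for (b in grid_b) for (cc in grid_c) {
    wts <- masses^b * dvec^cc
    m <- total * wts / sum(wts)
    loss <- sum(m - ifelse(data > 0, data * log(m), 0)) / length(data) +
      b^2 + cc^2
    if (loss < oracle) { oracle <- loss; arg <- c(b, cc) }
  }
  fit <- fitModel(ModelSpec("gravity", loss = "poisson",
                            train_year = "2019"), study)
  expect_lte(fit@trainLoss, oracle + 1e-9)
  expect_lt(max(abs(unname(fit@theta) - arg)), 0.06)
})

test_that("retail parameters are recovered from high-count synthetic data", {
  cfg <- syntheticConfig(seed = 31,
                         truth = list(family = "retail",
                                      alphas = c(knife = -0.013),
                                      beta = 0.014),
                         total_outflow = c("2019" = 1e5, "2020" = 1e5))
  study <- makeStudy(cfg)
  fit <- fitModel(ModelSpec("retail", "knife", "poisson", "2019"), study)
  expect_lt(abs(fit@theta[["beta"]] - 0.014) / 0.014, 0.2)
  expect_lt(fit@theta[["alpha_knife"]], 0)
})

test_that("twofold cross-validation keeps its fold bookkeeping straight", {
  # identical counts in both years: training and validation metrics coincide
  tabs <- tinyTables()
  merged <- mergeLondon(tabs$territories, tabs$covariates, tabs$lines)
  lines <- expand.grid(origin = "london", destination = c("t_a", "t_b"),
                       year = c("2019", "2020"), stringsAsFactors = FALSE)
  lines$count <- rep(c(40, 15), 2)
  od <- odFromCoords(merged$territories)
  study <- LinesStudy(merged$territories, merged$covariates, lines,
                      od$distance, od$travel_time, origin = "london")
  specs <- list(ModelSpec("gravity", loss = "poisson", train_year = "2019"),
                ModelSpec("gravity", loss = "poisson", train_year = "2020"))
  m <- crossValidate(specs, study)
  expect_equal(m$validate_year, c("2020", "2019"))
  expect_equal(m$train_loss[1], m$train_loss[2], tolerance = 1e-8)
  expect_equal(m$S[1], m$S[2], tolerance = 1e-8)
  # validation S equals the S of the training year here, by construction
  data <- lineCounts(study)[, "2019"]
  fit <- fitModel(specs[[1]], study)
  expect_equal(m$S[1], sorensenDice(data, fit@flows[["2019"]]),
               tolerance = 1e-8)

  expect_error(crossValidate(list(ModelSpec("gravity", loss = "poisson",
                                            train_year = "1999")), study),
               "absent")
})

test_that("the true family wins the validation Dice on synthetic studies", {
  wins <- 0L
  n_seeds <- 8
  S <- matrix(NA_real_, n_seeds, 3,
              dimnames = list(NULL, c("gravity", "radiation", "retail")))
  for (s in seq_len(n_seeds)) {
    study <- makeStudy(syntheticConfig(seed = 400 + s, n_destinations = 15))
    specs <- list(
      ModelSpec("gravity", loss = "poisson", train_year = "2019"),
      ModelSpec("radiation", loss = "poisson", train_year = "2019"),
      ModelSpec("retail", c("misuse", "knife"), "poisson", "2019"))
    m <- crossValidate(specs, study)
    S[s, ] <- m$S
  }
  med <- apply(S, 2, median)
  expect_equal(names(which.max(med)), "retail")
})
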