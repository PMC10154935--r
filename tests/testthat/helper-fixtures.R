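## Hand-built four-territory tables (two Greater London forces plus two
## destinations) used by the I/O and merge tests. All numbers are chosen to
## make sums and rates checkable by hand.
tinyTables <- function() {
  territories <- data.frame(
    id = c("metropolitan", "city_of_london", "t_a", "t_b"),
    name = c("Metropolitan", "City of London", "Territory A", "Territory B"),
    population = c(8.9e6, 1e4, 2e6, 1e6),
    lon = c(0, 1, 100, 200),
    lat = c(0, 1, 100, 50),
    region_tag = c("south", "south", "south", "other")
  )
  covariates <- data.frame(
    id = territories$id,
    misuse_admissions = c(9000, 100, 500, 800),
    poisoning_admissions = c(7000, 80, 400, 600),
    police_officers = c(30000, 700, 3000, 2000),
    gdhi = c(2.3e11, 5e8, 3.6e10, 1.7e10),
    knife_crimes = c(14000, 500, 400, 900),
    hospital_beds = c(20000, 300, 2000, 1500)
  )
  lines <- data.frame(
    origin = c("metropolitan", "metropolitan", "city_of_london",
               "metropolitan", "metropolitan"),
    destination = c("t_a", "t_b", "t_a", "t_a", "t_b"),
    year = c("2019", "2019", "2019", "2020", "2020"),
    count = c(40, 10, 5, 30, 12)
  )
  list(territories = territories, covariates = covariates, lines = lines)
}

## Square OD matrices from planar coordinates, optionally with a fixed
## time/distance ratio.
odFromCoords <- function(territories, speed = 1) {
  xy <- as.matrix(territories[, c("lon", "lat")])
  d <- as.matrix(dist(xy))
  dimnames(d) <- list(territories$id, territories$id)
  list(distance = d, travel_time = d / speed)
}

## Merged-London study used across tests: 'london' origin, two destinations.
tinyStudy <- function() {
  tabs <- tinyTables()
  merged <- mergeLondon(tabs$territories, tabs$covariates, tabs$lines)
  od <- odFromCoords(merged$territories)
  LinesStudy(merged$territories, merged$covariates, merged$lines,
             od$distance, od$travel_time, origin = "london")
}

## Synthetic study small enough for fast calibration tests.
smallSynthetic <- function(seed = 1, n = 10, ...) {
  makeStudy(syntheticConfig(seed = seed, n_destinations = n, ...))
}
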