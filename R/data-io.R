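#' Read and write the study's tabular inputs
#'
#' The on-disk layout is five UTF-8 CSV files: `territories.csv`
#' (`id,name,population,lon,lat[,region_tag]`), `covariates.csv` (`id` plus
#' the six raw covariate columns), `od_distance.csv` and
#' `od_travel_time.csv` (square matrices with a leading id column and id
#' header, km and minutes), and `lines.csv`
#' (`origin,destination,year,count`, long format). Distances and travel
#' times are between one representative point per territory (the most
#' populous place, in the motivating data); the package consumes them from
#' files and never computes routes.
#'
#' @param path file path.
#' @return `readTerritories` and `readCovariates` return validated
#'   data.frames; `readODMatrix` a square numeric matrix with id dimnames;
#'   `readLineCounts` a validated long-format data.frame.
#' @name study-io
NULL

#' @rdname study-io
#' @export
readTerritories <- function(path) {
  .checkTerritories(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname study-io
#' @export
readCovariates <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", unname(RAW_COVARIATE_COLUMNS))
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("covariate table is missing column(s): ", paste(miss, collapse = ", "))
  x$id <- as.character(x$id)
  vals <- as.matrix(x[unname(RAW_COVARIATE_COLUMNS)])
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("raw covariates must be finite and nonnegative")
  x
}

#' @param kind `"distance"` or `"travel_time"`; controls the error messages
#'   only, both kinds share the square-matrix format.
#' @param ids optional territory ids to reconcile the matrix against; an id
#'   set differing from the matrix header is an error.
#' @rdname study-io
#' @export
readODMatrix <- function(path, kind = c("distance", "travel_time"), ids = NULL) {
  kind <- match.arg(kind)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- as.character(raw[[1]])
  storage.mode(m) <- "double"
  if (!is.null(ids) && !setequal(rownames(m), ids))
    stop(kind, " matrix ids do not reconcile with the territory table")
  bad <- .validODMatrix(m, rownames(m), kind)
  if (!is.null(bad)) stop(bad)
  m
}

#' @rdname study-io
#' @export
readLineCounts <- function(path) {
  .checkLines(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @param dir directory holding the five CSVs (and optionally `truth.json`).
#' @param origin origin territory id.
#' @rdname study-io
#' @export
readStudy <- function(dir, origin = "london") {
  territories <- readTerritories(file.path(dir, "territories.csv"))
  covariates <- readCovariates(file.path(dir, "covariates.csv"))
  lines <- readLineCounts(file.path(dir, "lines.csv"))
  distance <- readODMatrix(file.path(dir, "od_distance.csv"), "distance",
                           ids = territories$id)
  travel_time <- readODMatrix(file.path(dir, "od_travel_time.csv"),
                              "travel_time", ids = territories$id)
  study <- LinesStudy(territories, covariates, lines, distance, travel_time,
                      origin = origin)
  truth_path <- file.path(dir, "truth.json")
  if (file.exists(truth_path)) {
    tr <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    for (field in c("theta", "alphas", "total_outflow"))
      if (!is.null(tr[[field]])) tr[[field]] <- unlist(tr[[field]])
    if (!is.null(tr$expected_flows))
      tr$expected_flows <- lapply(tr$expected_flows, unlist)
    metadata(study)$truth <- tr
  }
  study
}

#' @param study a [LinesStudy-class].
#' @rdname study-io
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ot <- metadata(study)$origin_territory
  rd <- as.data.frame(rowData(study))
  territories <- data.frame(
    id = c(studyOrigin(study), rownames(study)),
    name = c(ot$name, rd$name),
    population = c(ot$population, rd$population),
    lon = c(ot$lon, rd$lon), lat = c(ot$lat, rd$lat),
    region_tag = c(NA, as.character(rd$region_tag))
  )
  covariates <- data.frame(
    id = territories$id,
    rbind(as.data.frame(ot[unname(RAW_COVARIATE_COLUMNS)]),
          rd[, unname(RAW_COVARIATE_COLUMNS)]),
    row.names = NULL
  )
  counts <- lineCounts(study)
  lines <- do.call(rbind, lapply(colnames(counts), function(y) {
    data.frame(origin = studyOrigin(study), destination = rownames(counts),
               year = y, count = counts[, y])
  }))
  .writeODCsv <- function(m, path) {
    out <- data.frame(id = rownames(m), m, check.names = FALSE)
    utils::write.csv(out, path, row.names = FALSE)
  }
  utils::write.csv(territories, file.path(dir, "territories.csv"),
                   row.names = FALSE)
  utils::write.csv(covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  utils::write.csv(lines, file.path(dir, "lines.csv"), row.names = FALSE)
  .writeODCsv(odDistances(study), file.path(dir, "od_distance.csv"))
  .writeODCsv(odTravelTimes(study), file.path(dir, "od_travel_time.csv"))
  tr <- metadata(study)$truth
  if (!is.null(tr)) {
    # named atomic vectors would serialise as bare arrays; keep names
    for (field in c("theta", "alphas", "total_outflow"))
      if (!is.null(tr[[field]])) tr[[field]] <- as.list(tr[[field]])
    if (!is.null(tr$expected_flows))
      tr$expected_flows <- lapply(tr$expected_flows, as.list)
    jsonlite::write_json(tr, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Merge the two Greater London forces into a single origin territory
#'
#' The Metropolitan Police and City of London Police territories are merged
#' into one `london` territory whose population and every raw covariate is
#' the sum of the two, and whose line counts from either origin are summed
#' per destination and year. Normalised rates must be recomputed from the
#' summed raw values afterwards (via [normalisedBenefits()]), never averaged.
#'
#' @param territories,covariates,lines component tables as read by
#'   [readTerritories()] and friends.
#' @param met_id,city_id,merged_id ids of the two constituent territories and
#'   of the merged result. If either constituent is absent the tables are
#'   returned unchanged with a warning.
#' @param lon,lat centroid for the merged territory; defaults to the
#'   population-weighted mean of the two constituents.
#' @return list with elements `territories`, `covariates`, `lines`.
#' @export
mergeLondon <- function(territories, covariates, lines,
                        met_id = "metropolitan", city_id = "city_of_london",
                        merged_id = "london", lon = NULL, lat = NULL) {
  both <- c(met_id, city_id)
  if (!all(both %in% territories$id)) {
    warning("both '", met_id, "' and '", city_id,
            "' must be present; returning inputs unchanged")
    return(list(territories = territories, covariates = covariates,
                lines = lines))
  }
  sel <- match(both, territories$id)
  w <- territories$population[sel]
  merged_row <- data.frame(
    id = merged_id, name = "London",
    population = sum(territories$population[sel]),
    lon = if (is.null(lon)) sum(territories$lon[sel] * w) / sum(w) else lon,
    lat = if (is.null(lat)) sum(territories$lat[sel] * w) / sum(w) else lat
  )
  if ("region_tag" %in% names(territories))
    merged_row$region_tag <- territories$region_tag[sel[1]]
  territories <- rbind(merged_row,
                       territories[-sel, names(merged_row), drop = FALSE])

  csel <- match(both, covariates$id)
  merged_cov <- data.frame(id = merged_id)
  for (col in unname(RAW_COVARIATE_COLUMNS))
    merged_cov[[col]] <- sum(covariates[[col]][csel])
  covariates <- rbind(merged_cov,
                      covariates[-csel, names(merged_cov), drop = FALSE])

  lines$origin[lines$origin %in% both] <- merged_id
  lines$destination[lines$destination %in% both] <- merged_id
  lines <- stats::aggregate(count ~ origin + destination + year, data = lines,
                            FUN = sum)
  list(territories = territories, covariates = covariates, lines = lines)
}

#' Normalised benefit covariates
#'
#' Converts the raw destination covariates into the rates the retail model
#' consumes: every covariate is scaled by `1e5 / population` so it reads as a
#' rate per 100 000 inhabitants. In `per_bed` mode the two hospital-admission
#' covariates are instead divided by daytime hospital beds per capita
#' (`beds / population`), probing admissions relative to local hospital
#' capacity. Zero rates are permitted in the returned matrix but rejected at
#' model-build time for any covariate that enters a logarithm.
#'
#' @param study a [LinesStudy-class].
#' @param admissions_mode `"per_100k"` (default) or `"per_bed"`.
#' @return numeric matrix, destinations by the five benefit covariates
#'   `misuse`, `poisoning`, `police`, `gdhi`, `knife`.
#' @examples
#' study <- makeStudy(syntheticConfig(seed = 1, n_destinations = 6))
#' head(normalisedBenefits(study))
#' @export
normalisedBenefits <- function(study,
                               admissions_mode = c("per_100k", "per_bed")) {
  admissions_mode <- match.arg(admissions_mode)
  rd <- rowData(study)
  pop <- rd$population
  w <- sapply(BENEFIT_NAMES, function(n)
    rd[[RAW_COVARIATE_COLUMNS[[n]]]] * 1e5 / pop)
  rownames(w) <- rownames(study)
  if (admissions_mode == "per_bed") {
    beds <- rd[[RAW_COVARIATE_COLUMNS[["beds"]]]]
    if (any(beds <= 0))
      stop("per_bed normalisation requires positive hospital beds in ",
           "every territory")
    for (n in c("misuse", "poisoning"))
      w[, n] <- rd[[RAW_COVARIATE_COLUMNS[[n]]]] / (beds / pop)
  }
  w
}
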