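#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assayNames rowData colData
NULL

## Canonical names of the five benefit covariates (retail model) and the raw
## covariate columns they are derived from. Hospital beds enter only through
## the per-bed normalisation of the two admissions covariates.
BENEFIT_NAMES <- c("misuse", "poisoning", "police", "gdhi", "knife")

RAW_COVARIATE_COLUMNS <- c(
  misuse    = "misuse_admissions",
  poisoning = "poisoning_admissions",
  police    = "police_officers",
  gdhi      = "gdhi",
  knife     = "knife_crimes",
  beds      = "hospital_beds"
)

MODEL_FAMILIES <- c("gravity", "radiation", "retail")
LOSS_NAMES <- c("gaussian", "poisson")

#' Study container for origin-to-territory line counts
#'
#' `LinesStudy` extends [SummarizedExperiment::SummarizedExperiment] with the
#' origin-destination structure of a county-lines study. Rows are destination
#' police force territories, columns are year labels, and the `"lines"` assay
#' holds the observed counts of detected lines from the single origin (London
#' in the motivating data). Territory attributes (population, centroid, raw
#' covariates, region tag) live in `rowData`; the origin territory's own
#' attributes and any ground-truth record live in `metadata`. Pairwise
#' distances (km) and travel times (minutes) over all territories, origin
#' included, are stored as square matrix slots.
#'
#' @slot origin single territory id acting as the flow origin.
#' @slot distance square numeric matrix of pairwise distances in km, dimnames
#'   equal to all territory ids (origin plus destinations), zero diagonal.
#' @slot travelTime square numeric matrix of pairwise travel times in
#'   minutes, same layout as `distance`.
#'
#' @seealso [LinesStudy()] for construction, [makeStudy()] for synthetic
#'   studies, [fitModel()] and [crossValidate()] for calibration.
#' @export
setClass("LinesStudy",
  contains = "SummarizedExperiment",
  slots = c(origin = "character", distance = "matrix", travelTime = "matrix")
)

.validODMatrix <- function(m, ids, what) {
  if (!is.numeric(m)) return(sprintf("%s matrix must be numeric", what))
  if (nrow(m) != ncol(m)) return(sprintf("%s matrix must be square", what))
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !identical(rownames(m), colnames(m)))
    return(sprintf("%s matrix needs identical row and column ids", what))
  if (!setequal(rownames(m), ids))
    return(sprintf("%s matrix ids do not match the study territories", what))
  if (any(!is.finite(m))) return(sprintf("%s matrix has non-finite entries", what))
  if (any(diag(m) != 0)) return(sprintf("%s matrix must have a zero diagonal", what))
  off <- m[row(m) != col(m)]
  if (any(off <= 0))
    return(sprintf("%s matrix must be positive off the diagonal", what))
  NULL
}

setValidity("LinesStudy", function(object) {
  msgs <- character()
  dest <- rownames(object)
  if (length(object@origin) != 1L || is.na(object@origin))
    msgs <- c(msgs, "origin must be a single territory id")
  if (object@origin %in% dest)
    msgs <- c(msgs, "origin must not appear among the destinations")
  if (anyDuplicated(dest))
    msgs <- c(msgs, "duplicated destination ids")
  ids <- c(object@origin, dest)
  for (slotname in c("distance", "travelTime")) {
    bad <- .validODMatrix(slot(object, slotname), ids, slotname)
    if (!is.null(bad)) msgs <- c(msgs, bad)
  }
  rd <- rowData(object)
  if (!"population" %in% colnames(rd)) {
    msgs <- c(msgs, "rowData must contain a population column")
  } else if (any(rd$population <= 0)) {
    msgs <- c(msgs, "populations must be positive")
  }
  if (!"lines" %in% SummarizedExperiment::assayNames(object)) {
    msgs <- c(msgs, "assay 'lines' is required")
  } else {
    counts <- assay(object, "lines")
    if (any(counts < 0) || any(counts != round(counts)))
      msgs <- c(msgs, "line counts must be nonnegative integers")
  }
  op <- metadata(object)$origin_territory
  if (is.null(op) || is.null(op$population) || op$population <= 0)
    msgs <- c(msgs, "metadata$origin_territory with positive population is required")
  if (length(msgs)) msgs else TRUE
})

#' Construct a LinesStudy from its component tables
#'
#' Assembles validated territory, covariate, line-count and
#' origin-destination inputs into a [LinesStudy-class] object. Destination
#' territories are every territory except the origin, kept in territory-table
#' order; the count matrix has one column per year present in `lines`, with
#' missing origin-year-destination combinations filled with zero.
#'
#' @param territories data.frame with columns `id`, `name`, `population`,
#'   `lon`, `lat` and optionally `region_tag`.
#' @param covariates data.frame with column `id` plus the six raw covariate
#'   columns `misuse_admissions`, `poisoning_admissions`, `police_officers`,
#'   `gdhi`, `knife_crimes`, `hospital_beds`.
#' @param lines long-format data.frame with columns `origin`, `destination`,
#'   `year`, `count`.
#' @param distance,travel_time square numeric matrices over all territory
#'   ids (km and minutes respectively), zero diagonal, positive off-diagonal.
#' @param origin territory id of the flow origin (default `"london"`).
#'
#' @return a validated [LinesStudy-class].
#' @examples
#' study <- makeStudy(syntheticConfig(seed = 1, n_destinations = 8))
#' study
#' @export
LinesStudy <- function(territories, covariates, lines, distance, travel_time,
                       origin = "london") {
  territories <- .checkTerritories(territories)
  covariates <- .checkCovariates(covariates, territories$id)
  lines <- .checkLines(lines)
  if (!origin %in% territories$id)
    stop("origin '", origin, "' is not in the territory table")
  if (!all(lines$origin == origin))
    stop("line counts must all originate from '", origin, "'")
  dest <- setdiff(territories$id, origin)
  if (!all(lines$destination %in% dest))
    stop("line counts reference unknown destination territories: ",
         paste(setdiff(lines$destination, dest), collapse = ", "))

  years <- sort(unique(as.character(lines$year)))
  counts <- matrix(0L, nrow = length(dest), ncol = length(years),
                   dimnames = list(dest, years))
  for (k in seq_len(nrow(lines)))
    counts[lines$destination[k], as.character(lines$year[k])] <-
      counts[lines$destination[k], as.character(lines$year[k])] +
      as.integer(lines$count[k])

  ord <- match(dest, territories$id)
  cov_ord <- match(dest, covariates$id)
  rd <- DataFrame(
    name = territories$name[ord],
    population = territories$population[ord],
    lon = territories$lon[ord],
    lat = territories$lat[ord],
    region_tag = if ("region_tag" %in% names(territories))
      territories$region_tag[ord] else NA_character_,
    covariates[cov_ord, RAW_COVARIATE_COLUMNS, drop = FALSE],
    row.names = dest
  )
  oi <- match(origin, territories$id)
  oc <- match(origin, covariates$id)
  origin_territory <- c(
    list(id = origin, name = territories$name[oi],
         population = territories$population[oi],
         lon = territories$lon[oi], lat = territories$lat[oi]),
    as.list(covariates[oc, RAW_COVARIATE_COLUMNS])
  )
  se <- SummarizedExperiment(
    assays = list(lines = counts),
    rowData = rd,
    metadata = list(origin_territory = origin_territory)
  )
  new("LinesStudy", se, origin = origin,
      distance = distance[c(origin, dest), c(origin, dest)],
      travelTime = travel_time[c(origin, dest), c(origin, dest)])
}

.checkTerritories <- function(x) {
  need <- c("id", "name", "population", "lon", "lat")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("territory table is missing column(s): ", paste(miss, collapse = ", "))
  x$id <- as.character(x$id)
  if (anyDuplicated(x$id))
    stop("duplicated territory ids: ",
         paste(unique(x$id[duplicated(x$id)]), collapse = ", "))
  if (any(!is.finite(x$population)) || any(x$population <= 0))
    stop("territory populations must be positive")
  x
}

.checkCovariates <- function(x, ids) {
  need <- c("id", unname(RAW_COVARIATE_COLUMNS))
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("covariate table is missing column(s): ", paste(miss, collapse = ", "))
  x$id <- as.character(x$id)
  miss_ids <- setdiff(ids, x$id)
  if (length(miss_ids))
    stop("covariate table has no row for territories: ",
         paste(miss_ids, collapse = ", "))
  vals <- as.matrix(x[unname(RAW_COVARIATE_COLUMNS)])
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("raw covariates must be finite and nonnegative")
  x
}

.checkLines <- function(x) {
  need <- c("origin", "destination", "year", "count")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("line-count table is missing column(s): ", paste(miss, collapse = ", "))
  x$origin <- as.character(x$origin)
  x$destination <- as.character(x$destination)
  if (any(!is.finite(x$count)) || any(x$count < 0) || any(x$count != round(x$count)))
    stop("line counts must be nonnegative integers")
  x
}

#' Model specification
#'
#' A `ModelSpec` names one calibration task: a model family, the retail
#' benefit covariates included (empty for gravity/radiation and for the
#' travel-time-only retail variant), the loss used for calibration and the
#' year trained on. The travel-time cost parameter beta is always part of a
#' retail fit regardless of the covariate subset.
#'
#' @slot family one of `"gravity"`, `"radiation"`, `"retail"`.
#' @slot covariates character subset of
#'   `c("misuse", "poisoning", "police", "gdhi", "knife")`; retail only.
#' @slot loss `"gaussian"` or `"poisson"`.
#' @slot trainYear year label the model is calibrated on.
#' @export
setClass("ModelSpec", slots = c(
  family = "character", covariates = "character",
  loss = "character", trainYear = "character"
))

setValidity("ModelSpec", function(object) {
  msgs <- character()
  if (length(object@family) != 1L || !object@family %in% MODEL_FAMILIES)
    msgs <- c(msgs, "family must be one of gravity, radiation, retail")
  if (length(object@loss) != 1L || !object@loss %in% LOSS_NAMES)
    msgs <- c(msgs, "loss must be gaussian or poisson")
  if (length(object@trainYear) != 1L)
    msgs <- c(msgs, "trainYear must be a single label")
  if (anyDuplicated(object@covariates))
    msgs <- c(msgs, "duplicated covariate names")
  if (!all(object@covariates %in% BENEFIT_NAMES))
    msgs <- c(msgs, "unknown covariate names")
  if (length(object@covariates) && object@family != "retail")
    msgs <- c(msgs, "covariates are only meaningful for the retail family")
  if (length(msgs)) msgs else TRUE
})

#' @param family,covariates,loss,train_year see slot descriptions.
#' @return `ModelSpec()` returns a validated `ModelSpec`.
#' @rdname ModelSpec-class
#' @export
ModelSpec <- function(family, covariates = character(), loss = "poisson",
                      train_year) {
  new("ModelSpec", family = family, covariates = as.character(covariates),
      loss = loss, trainYear = as.character(train_year))
}

#' @export
#' @describeIn ModelSpec-class compact one-line identifier, e.g.
#'   `"retail[misuse+knife]/poisson/2019"`; used for ranking tie-breaks.
specId <- function(spec) {
  covs <- if (length(spec@covariates))
    paste(sort(spec@covariates), collapse = "+") else "none"
  sprintf("%s[%s]/%s/%s", spec@family,
          if (spec@family == "retail") covs else "-",
          spec@loss, spec@trainYear)
}

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec:", specId(object), "\n")
})

#' Calibration result
#'
#' Returned by [fitModel()]. Holds the fitted parameter vector, the penalised
#' training loss at the optimum, the unpenalised log-likelihood on the
#' training year, per-year predicted flow vectors (each scaled to that
#' year's observed total outflow) and optimiser diagnostics.
#'
#' @slot spec the [ModelSpec-class] fitted.
#' @slot theta named fitted parameter vector.
#' @slot trainLoss penalised loss at the optimum.
#' @slot logLik unpenalised training-year log-likelihood at the optimum.
#' @slot converged FALSE flags an optimiser that did not report convergence.
#' @slot flows list of named flow vectors, one per year of the study.
#' @slot diagnostics list: start points tried, best start, optimiser messages.
#' @export
setClass("ModelFit", slots = c(
  spec = "ModelSpec", theta = "numeric", trainLoss = "numeric",
  logLik = "numeric", converged = "logical", flows = "list",
  diagnostics = "list"
))

setMethod("show", "ModelFit", function(object) {
  cat("ModelFit:", specId(object@spec), "\n")
  cat("  theta:", paste(sprintf("%s=%.4g", names(object@theta), object@theta),
                        collapse = ", "), "\n")
  cat(sprintf("  train loss %.6g | logLik %.6g | converged %s\n",
              object@trainLoss, object@logLik, object@converged))
})

## --- accessors -------------------------------------------------------------

#' @describeIn LinesStudy-class id of the origin territory.
#' @param x a `LinesStudy`.
#' @export
studyOrigin <- function(x) x@origin

#' @describeIn LinesStudy-class destination territory ids, in row order.
#' @export
destinationIds <- function(x) rownames(x)

#' @describeIn LinesStudy-class year labels of the study.
#' @export
studyYears <- function(x) colnames(x)

#' @describeIn LinesStudy-class the destination-by-year observed count matrix.
#' @export
lineCounts <- function(x) assay(x, "lines")

#' @describeIn LinesStudy-class square distance matrix in km (origin included).
#' @export
odDistances <- function(x) x@distance

#' @describeIn LinesStudy-class square travel-time matrix in minutes.
#' @export
odTravelTimes <- function(x) x@travelTime

#' @describeIn LinesStudy-class named vector of all populations, origin first.
#' @export
allPopulations <- function(x) {
  p <- c(metadata(x)$origin_territory$population, rowData(x)$population)
  names(p) <- c(x@origin, rownames(x))
  p
}

setMethod("show", "LinesStudy", function(object) {
  cat(sprintf("LinesStudy: origin '%s', %d destinations, years %s\n",
              object@origin, nrow(object),
              paste(colnames(object), collapse = ", ")))
  tot <- colSums(assay(object, "lines"))
  cat("  total lines per year:",
      paste(sprintf("%s=%d", names(tot), tot), collapse = ", "), "\n")
  tr <- metadata(object)$truth
  if (!is.null(tr))
    cat("  synthetic study with stored ground truth (family '",
        tr$family, "')\n", sep = "")
})
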