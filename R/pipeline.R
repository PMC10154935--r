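#' Synthetic territory boundaries as GeoJSON
#'
#' Builds a square polygon around each territory centroid so
#' [differenceMap()] output can be exercised without real boundary files.
#' The polygons are schematic, not cartographic.
#'
#' @param study a [LinesStudy-class].
#' @param half_side half the square's side, in the centroid units.
#' @param out optional path to write the FeatureCollection to.
#' @return GeoJSON-style list (FeatureCollection keyed by territory id).
#' @export
makeBoundaries <- function(study, half_side = 8, out = NULL) {
  rd <- rowData(study)
  features <- lapply(seq_len(nrow(study)), function(k) {
    x <- rd$lon[k]; y <- rd$lat[k]; h <- half_side
    ring <- list(c(x - h, y - h), c(x + h, y - h), c(x + h, y + h),
                 c(x - h, y + h), c(x - h, y - h))
    list(type = "Feature",
         properties = list(id = rownames(study)[k], name = rd$name[k]),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  gj <- list(type = "FeatureCollection", features = features)
  if (!is.null(out))
    jsonlite::write_json(gj, out, auto_unbox = TRUE, digits = NA)
  gj
}

#' Run the full model-comparison study
#'
#' End-to-end pipeline: load (or simulate) a two-year study, build the full
#' specification grid -- one gravity, one radiation and the 32 retail
#' variants for every loss and training year -- cross-validate all of them,
#' rank the results, and write the outputs. Everything downstream of the
#' seed is deterministic, so reruns with the same config are reproducible.
#'
#' @param config either a YAML file path or a list with entries:
#'   `simulate` (arguments to [syntheticConfig()]) or `data_dir` (directory
#'   for [readStudy()]); optional `losses` (default both), `ranking_key`
#'   (default `"log_mse"`), `minimal` (default TRUE, the minimum-variable
#'   retail filter), `admissions_mode`, `lambda`, `outdir`, `boundaries`
#'   (GeoJSON path for difference maps), `seed` (overrides the simulate
#'   seed).
#' @return invisible list with `study`, `metrics` (full cross-validation
#'   table), `ranking`, and paths of files written.
#' @examples
#' \donttest{
#' res <- runStudy(list(simulate = list(seed = 1, n_destinations = 10),
#'                      losses = "poisson"))
#' head(res$ranking[, c("rank", "id", "S", "bic", "log_mse")])
#' }
#' @export
runStudy <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  losses <- config$losses %||% LOSS_NAMES
  key <- config$ranking_key %||% "log_mse"
  minimal <- config$minimal %||% TRUE
  lambda <- config$lambda %||% 1
  admissions_mode <- config$admissions_mode %||% "per_100k"

  if (!is.null(config$data_dir)) {
    study <- readStudy(config$data_dir)
  } else if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (!is.null(config$seed)) sim_args$seed <- config$seed
    study <- makeStudy(do.call(syntheticConfig, sim_args))
  } else stop("config needs either 'data_dir' or a 'simulate' block")

  years <- studyYears(study)
  specs <- unlist(lapply(losses, function(l)
    unlist(lapply(years, function(y) specGrid(l, y)), recursive = FALSE)),
    recursive = FALSE)
  metrics <- crossValidate(specs, study, lambda = lambda,
                           admissions_mode = admissions_mode)
  ranking <- rankModels(metrics, key = key, minimal = minimal)

  written <- character()
  outdir <- config$outdir
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    metrics_path <- file.path(outdir, "metrics.json")
    export <- metrics
    export$theta <- lapply(export$theta, as.list)
    jsonlite::write_json(export, metrics_path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
    ranking_path <- file.path(outdir, "ranking.csv")
    utils::write.csv(
      ranking[, c("rank", "family", "covariates", "loss", "train_year",
                  "params", "bic", "S", "log_mse")],
      ranking_path, row.names = FALSE)
    written <- c(metrics_path, ranking_path)
    if (!is.null(config$boundaries) || !is.null(config$simulate)) {
      gj <- if (!is.null(config$boundaries))
        jsonlite::read_json(config$boundaries) else makeBoundaries(study)
      best <- ranking[1, ]
      best_spec <- specs[[match(best$id,
                                vapply(specs, specId, character(1)))]]
      fit <- fitModel(best_spec, study, lambda = lambda,
                      admissions_mode = admissions_mode)
      for (y in years) {
        map_path <- file.path(outdir, sprintf("difference_%s.geojson", y))
        differenceMap(lineCounts(study)[, y], fit@flows[[y]], gj,
                      out = map_path)
        written <- c(written, map_path)
      }
    }
  }
  invisible(list(study = study, metrics = metrics, ranking = ranking,
                 files = written))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
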