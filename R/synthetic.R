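## Run code under a temporary RNG state so generators are deterministic
## without clobbering the caller's random stream.
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Derived sub-seed for independent sampling stages, kept inside 32-bit range.
.subseed <- function(seed, k) (as.numeric(seed) %% 1000000007 + k * 1000003) %% 2147483629 + 1

#' Configuration of a synthetic county-lines study
#'
#' Describes the generative model the synthetic studies follow: territory
#' centroids uniform in a planar box with Euclidean distances, travel times
#' proportional to distance up to multiplicative log-normal noise,
#' log-normal populations and per-100k covariate rates at magnitudes
#' realistic for English police force territories, and Poisson line counts
#' whose means follow a ground-truth flow model with a fixed total outflow
#' per year. The default truth is a retail model with the travel-time cost
#' and mildly repulsive misuse-admission and knife-crime covariates.
#'
#' @param seed integer seed; all sampling in [makeStudy()] derives from it.
#' @param n_destinations number of destination territories (>= 2).
#' @param origin_population origin population in persons.
#' @param population_law `c(meanlog, sdlog)` of destination populations.
#' @param covariate_laws named list of `c(meanlog, sdlog)` log-normal laws
#'   for per-100k rates of the five benefit covariates plus `beds`; `gdhi`
#'   is generated as an aggregate so its per-100k rate is income-scaled.
#' @param box_km side of the square box centroids are drawn in (km).
#' @param min_separation_km minimum pairwise centroid distance enforced by
#'   resampling.
#' @param speed km per minute converting distance to travel time.
#' @param time_noise standard deviation of the symmetric multiplicative
#'   log-normal noise on travel times (0 gives exact proportionality).
#' @param truth ground-truth list: `family` plus its parameters (`alphas`,
#'   `beta` for retail; `b`, `c` for gravity; `rho`, `r` for radiation).
#' @param total_outflow named vector of total lines per year label.
#' @param n_south number of origin-nearest destinations tagged `"south"`
#'   (mirrors the 16-territory southern set of the motivating data).
#' @return validated config list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(seed = 1,
                            n_destinations = 37,
                            origin_population = 8.9e6,
                            population_law = c(meanlog = log(1.1e6),
                                               sdlog = 0.45),
                            covariate_laws = list(
                              misuse    = c(meanlog = log(90),    sdlog = 0.5),
                              poisoning = c(meanlog = log(70),    sdlog = 0.5),
                              police    = c(meanlog = log(220),   sdlog = 0.2),
                              gdhi      = c(meanlog = log(1.9e9), sdlog = 0.15),
                              knife     = c(meanlog = log(50),    sdlog = 0.8),
                              beds      = c(meanlog = log(240),   sdlog = 0.25)),
                            box_km = 600,
                            min_separation_km = 10,
                            speed = 1,
                            time_noise = 0.15,
                            truth = list(
                              family = "retail",
                              alphas = c(misuse = -7.74e-3, knife = -0.013),
                              beta = 0.014),
                            total_outflow = c("2019" = 2000, "2020" = 1700),
                            n_south = 16) {
  cfg <- list(seed = seed, n_destinations = n_destinations,
              origin_population = origin_population,
              population_law = population_law,
              covariate_laws = covariate_laws, box_km = box_km,
              min_separation_km = min_separation_km, speed = speed,
              time_noise = time_noise, truth = truth,
              total_outflow = total_outflow, n_south = n_south)
  stopifnot(n_destinations >= 2, all(total_outflow > 0), speed > 0,
            origin_population > 0, time_noise >= 0, box_km > 0,
            truth$family %in% MODEL_FAMILIES,
            !is.null(names(total_outflow)))
  miss <- setdiff(c(BENEFIT_NAMES, "beds"), names(covariate_laws))
  if (length(miss))
    stop("covariate_laws missing: ", paste(miss, collapse = ", "))
  structure(cfg, class = "SyntheticConfig")
}

#' Sample territory geography: centroids and OD matrices
#'
#' Centroids are uniform in the box (resampled until every pair is at least
#' `min_separation_km` apart), the origin is the first territory, distances
#' are Euclidean (the synthetic `lon`/`lat` are planar km coordinates) and
#' travel times are `d / speed` times symmetric multiplicative noise
#' `exp(N(0, time_noise))`. Deterministic for a fixed config seed.
#'
#' @param config a [syntheticConfig()].
#' @param populations optional named populations (origin first); sampled
#'   from the config law if omitted.
#' @return list with `territories` data.frame, `distance` and `travel_time`
#'   matrices.
#' @export
generateGeography <- function(config, populations = NULL) {
  n <- config$n_destinations + 1L
  ids <- c("london", sprintf("territory_%02d", seq_len(config$n_destinations)))
  .withSeed(.subseed(config$seed, 1), {
    repeat {
      xy <- matrix(stats::runif(2 * n, 0, config$box_km), ncol = 2)
      d <- as.matrix(stats::dist(xy))
      if (min(d[row(d) != col(d)]) >= config$min_separation_km) break
    }
    dimnames(d) <- list(ids, ids)
    noise <- matrix(stats::rnorm(n * n, 0, config$time_noise), n)
    noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
    tt <- d / config$speed * exp(noise)
    diag(tt) <- 0
    dimnames(tt) <- dimnames(d)
    if (is.null(populations)) {
      pops <- c(config$origin_population,
                stats::rlnorm(config$n_destinations,
                              config$population_law[["meanlog"]],
                              config$population_law[["sdlog"]]))
    } else pops <- unname(populations[ids])
    south <- names(sort(d["london", ids[-1]]))[seq_len(
      min(config$n_south, config$n_destinations))]
    territories <- data.frame(
      id = ids,
      name = c("London", sprintf("Territory %02d",
                                 seq_len(config$n_destinations))),
      population = pops,
      lon = xy[, 1], lat = xy[, 2],
      region_tag = ifelse(ids %in% south, "south", "other")
    )
    list(territories = territories, distance = d, travel_time = tt)
  })
}

#' Poisson line-count draws with given means
#'
#' Independent Poisson draws, one per destination, with the expected flows
#' as means. Used by [makeStudy()] and directly in calibration experiments.
#'
#' @param flows named nonnegative expected lines per destination.
#' @param seed integer seed for the draw.
#' @return named integer vector of counts.
#' @examples
#' sampleLineCounts(c(a = 50, b = 30, c = 20), seed = 7)
#' @export
sampleLineCounts <- function(flows, seed) {
  if (any(flows < 0)) stop("Poisson means must be nonnegative")
  .withSeed(seed, {
    counts <- stats::rpois(length(flows), flows)
    names(counts) <- names(flows)
    counts
  })
}

.truthTheta <- function(truth) {
  switch(truth$family,
    retail = c(stats::setNames(truth$alphas,
                               paste0("alpha_", names(truth$alphas))),
               beta = truth$beta),
    gravity = c(b = truth$b, c = truth$c),
    radiation = c(rho = truth$rho, r = truth$r))
}

#' Generate a complete synthetic two-year study
#'
#' Samples geography, populations and covariates once, computes expected
#' flows from the ground-truth model (summing exactly to the configured
#' total outflow per year) and draws independent Poisson counts for each
#' year. The truth record -- family, parameters and expected flows -- is
#' stored in `metadata(study)$truth` for parameter-recovery tests.
#'
#' @param config a [syntheticConfig()].
#' @return a [LinesStudy-class] with two years of counts and stored truth.
#' @examples
#' study <- makeStudy(syntheticConfig(seed = 42, n_destinations = 10))
#' metadata(study)$truth$theta
#' @export
makeStudy <- function(config) {
  geo <- generateGeography(config)
  ids <- geo$territories$id
  pops <- geo$territories$population
  covariates <- .withSeed(.subseed(config$seed, 2), {
    out <- data.frame(id = ids)
    rate_of <- list(misuse = "misuse_admissions",
                    poisoning = "poisoning_admissions",
                    police = "police_officers", gdhi = "gdhi",
                    knife = "knife_crimes", beds = "hospital_beds")
    for (n in names(rate_of)) {
      law <- config$covariate_laws[[n]]
      rate <- stats::rlnorm(length(ids), law[["meanlog"]], law[["sdlog"]])
      out[[rate_of[[n]]]] <- rate * pops / 1e5
    }
    out
  })
  years <- names(config$total_outflow)
  zero_lines <- expand.grid(origin = "london", destination = ids[-1],
                            year = years, stringsAsFactors = FALSE)
  zero_lines$count <- 0L
  study <- LinesStudy(geo$territories, covariates, zero_lines,
                      geo$distance, geo$travel_time, origin = "london")
  theta <- .truthTheta(config$truth)
  if (config$truth$family == "retail" && length(config$truth$alphas)) {
    w <- normalisedBenefits(study)[, names(config$truth$alphas), drop = FALSE]
    if (any(w <= 0))
      stop("ground-truth retail covariates must be positive under the log")
  }
  flows <- lapply(years, function(y)
    predictFlows(config$truth$family, theta, study,
                 config$total_outflow[[y]]))
  names(flows) <- years
  counts <- do.call(cbind, lapply(seq_along(years), function(k)
    sampleLineCounts(flows[[k]], .subseed(config$seed, 10 + k))))
  dimnames(counts) <- list(names(flows[[1]]), years)
  SummarizedExperiment::assay(study, "lines") <- counts
  metadata(study)$truth <- list(family = config$truth$family,
                                theta = theta,
                                total_outflow = config$total_outflow,
                                expected_flows = flows)
  validObject(study)
  study
}
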