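#' Expected flows under the three spatial interaction models
#'
#' All three models allocate a fixed total outflow `T_i` from a single
#' origin across the destinations, so the flows always satisfy the outflow
#' constraint `sum_j T_ij = T_i`.
#'
#' * **Gravity**: `T_ij = T_i * m_j^b d_ij^c / sum_k m_k^b d_ik^c`. The
#'   distance exponent `c` is an unconstrained real, so both decaying
#'   (`c < 0`) and growing (`c > 0`) distance dependence are representable;
#'   the origin-mass factor cancels in the normalisation.
#' * **Retail** (entropy-maximising): destination utility
#'   `u_j = sum_n alpha_n log w_j^(n) - beta c_ij` with benefit rates `w`
#'   (per 100 000 inhabitants) and travel times `c_ij` in minutes;
#'   `T_ij = T_i softmax(u)_j`. Utilities are max-shifted before
#'   exponentiation for numerical stability (an identity of the softmax).
#' * **Radiation** (with intervening opportunities): opportunities are
#'   proportional to population, `n = rho * p`; the flow to `j` is
#'   proportional to the absorption probability
#'   `P(1 | n_i, n_j, n_ij)` of [absorptionProbability()], with `n_ij` the
#'   opportunities of territories strictly closer to the origin than `j`.
#'
#' @param total total outflow `T_i` to distribute (lines).
#' @param masses positive destination masses `m_j` (populations).
#' @param distances positive origin-to-destination distances `d_ij` (km).
#' @param b,c gravity exponents for mass and distance.
#' @return named nonnegative vector of expected flows summing to `total`.
#' @examples
#' gravityFlows(60, masses = c(a = 1, b = 8), distances = c(a = 10, b = 10),
#'              b = 1 / 3, c = 0)
#' retailFlows(100, benefits = matrix(0, 2, 0), travel_times = c(10, 20),
#'             alphas = numeric(), beta = 0.014)
#' @name flow-models
NULL

#' @rdname flow-models
#' @export
gravityFlows <- function(total, masses, distances, b, c) {
  stopifnot(length(masses) == length(distances), total >= 0)
  if (any(masses <= 0)) stop("gravity masses must be positive")
  if (any(distances <= 0)) stop("gravity distances must be positive")
  ## work in log space: m^b d^c can overflow for large populations
  lw <- b * log(masses) + c * log(distances)
  lw <- lw - max(lw)
  w <- exp(lw)
  out <- total * w / sum(w)
  names(out) <- names(masses)
  out
}

#' @param benefits numeric matrix of normalised benefit rates, destinations
#'   by covariates (see [normalisedBenefits()]); only the columns named in
#'   `alphas` are used, and those must be strictly positive.
#' @param travel_times origin-to-destination travel times in minutes.
#' @param alphas named vector of benefit exponents `alpha_n` (may be empty).
#' @param beta travel-time cost per minute.
#' @rdname flow-models
#' @export
retailFlows <- function(total, benefits, travel_times, alphas, beta) {
  n_dest <- length(travel_times)
  stopifnot(nrow(benefits) == n_dest || length(alphas) == 0L, total >= 0)
  if (any(travel_times <= 0)) stop("travel times must be positive")
  u <- -beta * travel_times
  if (length(alphas)) {
    missing_cov <- setdiff(names(alphas), colnames(benefits))
    if (length(missing_cov))
      stop("unknown benefit covariate(s): ", paste(missing_cov, collapse = ", "))
    for (n in names(alphas)) {
      wn <- benefits[, n]
      if (any(wn <= 0)) {
        bad <- rownames(benefits)[which(wn <= 0)[1]]
        stop("covariate '", n, "' is nonpositive for territory '",
             if (is.null(bad)) which(wn <= 0)[1] else bad,
             "' and cannot enter a logarithm")
      }
      u <- u + alphas[[n]] * log(wn)
    }
  }
  u <- u - max(u)
  w <- exp(u)
  out <- total * w / sum(w)
  names(out) <- names(travel_times)
  out
}

#' Intervening population between an origin and each destination
#'
#' The radiation model's intervening opportunities for destination `j` count
#' the population of every territory `k` other than the origin and `j`
#' lying strictly closer to the origin than `j` is (`d_ik < d_ij`, the
#' circle-of-radius-`d_ij` convention; ties are excluded).
#'
#' @param populations named vector of territory populations (all
#'   territories, origin included).
#' @param distances square distance matrix with matching dimnames.
#' @param origin origin territory id.
#' @param destination destination id; if `NULL`, returns the whole named
#'   vector over every non-origin territory.
#' @return intervening population(s), in persons.
#' @examples
#' d <- matrix(c(0, 5, 10, 5, 0, 5, 10, 5, 0), 3,
#'             dimnames = list(c("i", "k", "j"), c("i", "k", "j")))
#' interveningPopulation(c(i = 1, k = 7, j = 1), d, "i", "j")
#' @export
interveningPopulation <- function(populations, distances, origin,
                                  destination = NULL) {
  ids <- rownames(distances)
  stopifnot(!is.null(ids), origin %in% ids,
            setequal(names(populations), ids))
  populations <- populations[ids]
  dests <- if (is.null(destination)) setdiff(ids, origin) else destination
  d_from_origin <- distances[origin, ]
  out <- vapply(dests, function(j) {
    if (j == origin) stop("destination must differ from the origin")
    inside <- ids[d_from_origin < d_from_origin[j]]
    inside <- setdiff(inside, c(origin, j))
    sum(populations[inside])
  }, numeric(1))
  if (!is.null(destination) && length(destination) == 1L) unname(out) else out
}

#' Absorption probability of the radiation model
#'
#' Probability that a particle leaving a place with opportunities `n_i` is
#' absorbed at a destination with opportunities `n_j`, given intervening
#' opportunities `n_ij`, with absorption exponent `r`:
#' `[(n_i+n_j+n_ij)^r - (n_i+n_ij)^r] (n_i^r + 1) /
#'  {[(n_i+n_ij)^r + 1] [(n_i+n_j+n_ij)^r + 1]}`.
#' Vectorised over `n_j` and `n_ij`.
#'
#' @param n_i,n_j,n_ij nonnegative opportunity counts.
#' @param r positive absorption exponent.
#' @return probabilities in `[0, 1]`; zero when `n_j = 0`.
#' @examples
#' absorptionProbability(1, 1, 0, r = 1) # 1/3
#' @export
absorptionProbability <- function(n_i, n_j, n_ij, r) {
  stopifnot(r > 0, all(n_i >= 0), all(n_j >= 0), all(n_ij >= 0))
  a <- (n_i + n_ij)^r
  bfull <- (n_i + n_j + n_ij)^r
  (bfull - a) * (n_i^r + 1) / ((a + 1) * (bfull + 1))
}

#' @param populations named vector over all territories (origin included).
#' @param origin origin territory id (present in `populations` and in the
#'   dimnames of `distances`).
#' @param rho opportunities per person (`n = rho * population`).
#' @param r absorption exponent.
#' @rdname flow-models
#' @export
radiationFlows <- function(total, populations, distances, origin, rho, r) {
  stopifnot(rho > 0, r > 0, total >= 0)
  if (any(populations <= 0)) stop("populations must be positive")
  dests <- setdiff(rownames(distances), origin)
  p_ij <- interveningPopulation(populations, distances, origin)
  n_i <- rho * populations[[origin]]
  P <- absorptionProbability(n_i, rho * populations[dests],
                             rho * p_ij[dests], r)
  denom <- sum(P)
  if (denom <= 0) stop("all absorption probabilities are zero: ",
                       "degenerate geography")
  out <- total * P / denom
  names(out) <- dests
  out
}

#' Expected flows for a model specification on a study
#'
#' Evaluates the flow model named by `family` on the study's geography and
#' covariates, with the outflow fixed to `total`.
#'
#' @param family `"gravity"`, `"radiation"` or `"retail"`.
#' @param theta named parameter vector: `b`, `c` (gravity); `rho`, `r`
#'   (radiation); `alpha_<covariate>` entries plus `beta` (retail).
#' @param study a [LinesStudy-class].
#' @param total outflow to distribute.
#' @param benefits optional precomputed [normalisedBenefits()] matrix.
#' @return named flow vector over the study's destinations.
#' @export
predictFlows <- function(family, theta, study, total, benefits = NULL) {
  origin <- studyOrigin(study)
  dest <- destinationIds(study)
  switch(family,
    gravity = gravityFlows(
      total, masses = stats::setNames(rowData(study)$population, dest),
      distances = odDistances(study)[origin, dest],
      b = theta[["b"]], c = theta[["c"]]),
    radiation = radiationFlows(
      total, populations = allPopulations(study),
      distances = odDistances(study), origin = origin,
      rho = theta[["rho"]], r = theta[["r"]]),
    retail = {
      if (is.null(benefits)) benefits <- normalisedBenefits(study)
      anames <- grep("^alpha_", names(theta), value = TRUE)
      alphas <- stats::setNames(theta[anames], sub("^alpha_", "", anames))
      retailFlows(total, benefits = benefits,
                  travel_times = odTravelTimes(study)[origin, dest],
                  alphas = alphas, beta = theta[["beta"]])
    },
    stop("unknown model family '", family, "'")
  )
}
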