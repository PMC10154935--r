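#' Sorensen-Dice similarity between observed and modelled flows
#'
#' `S = 2 sum_j min(T_j^data, T_j^model) / (sum_j T_j^data + sum_j
#' T_j^model)`, the common-part-of-commuters statistic. `S = 1` iff the two
#' vectors are identical element-wise; `S = 0` for disjoint supports. The
#' index is symmetric in its arguments.
#'
#' @param data,model nonnegative vectors over the same destinations.
#' @return similarity in `[0, 1]`.
#' @examples
#' sorensenDice(c(2, 2), c(1, 3)) # 0.75
#' @export
sorensenDice <- function(data, model) {
  model <- .alignFlows(data, model)
  if (any(data < 0) || any(model < 0))
    stop("Sorensen-Dice inputs must be nonnegative")
  denom <- sum(data) + sum(model)
  if (denom == 0) stop("Sorensen-Dice is undefined when both totals are zero")
  2 * sum(pmin(data, model)) / denom
}

#' Bayesian information criterion
#'
#' `BIC = 2 log M - 2 log Lhat`, with `M` the sample size and `log Lhat`
#' the maximised log-likelihood. This is the exact form used for the flow
#' model comparison; the textbook `k log M - 2 log Lhat` (with `k` free
#' parameters) is available by supplying `k`, but is never the default.
#'
#' @param M sample size, at least 1.
#' @param loglik maximised log-likelihood (see [flowLogLik()]).
#' @param k optional parameter count switching to the `k log M` form.
#' @return the criterion value; lower is better.
#' @examples
#' bic(74, -120) # 2 log 74 + 240
#' @export
bic <- function(M, loglik, k = NULL) {
  stopifnot(M >= 1)
  if (is.null(k)) 2 * log(M) - 2 * loglik else k * log(M) - 2 * loglik
}

#' Mean squared error on the log scale
#'
#' `(1/N) sum_j (log(T_j^data + offset) - log(T_j^model + offset))^2`. The
#' additive offset (default 1) admits zero counts; with `offset = 0`
#' destinations where either side is zero are excluded from the mean, and
#' this exclusion is reported via an attribute.
#'
#' @param data,model nonnegative vectors over the same destinations.
#' @param offset nonnegative additive offset inside the logarithms.
#' @return the mean squared log error; with `offset = 0`, carries an
#'   `n_excluded` attribute.
#' @examples
#' logMSE(exp(1) - 1, exp(2) - 1) # 1
#' @export
logMSE <- function(data, model, offset = 1) {
  model <- .alignFlows(data, model)
  if (any(data < 0) || any(model < 0))
    stop("log-MSE inputs must be nonnegative")
  if (offset == 0) {
    keep <- data > 0 & model > 0
    if (!any(keep)) stop("no positive pairs to compare at offset 0")
    out <- mean((log(data[keep]) - log(model[keep]))^2)
    attr(out, "n_excluded") <- sum(!keep)
    return(out)
  }
  mean((log(data + offset) - log(model + offset))^2)
}

#' Rank cross-validation results
#'
#' Sorts a [crossValidate()] table by the chosen key (ascending for
#' `log_mse` and `bic`, descending for `S`), breaking ties by fewer
#' covariates and then lexicographic spec id, and assigns ranks 1, 2, ....
#'
#' With `minimal = TRUE` the retail rows are filtered to the
#' minimum-variable set before ranking: only variants whose covariate set is
#' a subset of the best retail variant's covariates are retained (so two
#' active covariates retain four rows: both, each alone, none), alongside
#' all non-retail rows. `active` overrides the automatically detected set.
#'
#' @param metrics data.frame from [crossValidate()].
#' @param key `"log_mse"`, `"S"` or `"bic"`.
#' @param minimal apply the minimum-variable retail filter.
#' @param active optional character vector of active covariates for the
#'   filter.
#' @return the (possibly filtered) rows, sorted, with a `rank` column.
#' @export
rankModels <- function(metrics, key = c("log_mse", "S", "bic"),
                       minimal = FALSE, active = NULL) {
  if (!nrow(metrics)) stop("no metrics rows to rank")
  key <- match.arg(key)
  if (minimal) {
    retail <- metrics$family == "retail"
    if (is.null(active)) {
      if (!any(retail)) stop("no retail rows to derive the active set from")
      cand <- metrics[retail, , drop = FALSE]
      ord <- .metricOrder(cand, key)
      active <- strsplit(cand$covariates[ord[1]], "+", fixed = TRUE)[[1]]
    }
    keep_retail <- vapply(strsplit(metrics$covariates, "+", fixed = TRUE),
                          function(s) all(s %in% c(active, "")), logical(1))
    metrics <- metrics[!retail | keep_retail, , drop = FALSE]
  }
  out <- metrics[.metricOrder(metrics, key), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

.metricOrder <- function(metrics, key) {
  primary <- if (key == "S") -metrics[[key]] else metrics[[key]]
  order(primary, metrics$n_covariates, metrics$id)
}

#' Share of lines concentrated in a subset of territories
#'
#' Fraction of the total observed lines falling in the given destinations;
#' used to quantify how strongly the flow concentrates in the 'south' set of
#' territories.
#'
#' @param counts named nonnegative vector of line counts per destination.
#' @param subset destination ids (must all be present in `counts`).
#' @return fraction in `[0, 1]`; an empty subset gives 0.
#' @examples
#' concentrationShare(c(A = 94, B = 6), "A")
#' @export
concentrationShare <- function(counts, subset) {
  if (length(setdiff(subset, names(counts))))
    stop("subset contains ids absent from the counts: ",
         paste(setdiff(subset, names(counts)), collapse = ", "))
  total <- sum(counts)
  if (total == 0) stop("concentration share is undefined for zero total")
  sum(counts[subset]) / total
}

#' Model-minus-data difference map
#'
#' Attaches per-territory attributes `observed`, `modelled` and `difference`
#' (`model - data`; positive means the model overestimates) to a GeoJSON
#' FeatureCollection keyed by territory id, and returns the attribute table.
#' Territories without a matching geometry are kept as attribute-only rows
#' with a warning; geometries are copied through untouched.
#'
#' @param data named observed counts per destination.
#' @param model named modelled flows per destination.
#' @param boundaries path to a GeoJSON FeatureCollection, or the
#'   already-parsed list; each feature needs `properties$id`. May be `NULL`
#'   for an attribute-only result.
#' @param out optional path to write the annotated GeoJSON to.
#' @return data.frame with columns `id`, `observed`, `modelled`,
#'   `difference`, `has_geometry`; the annotated FeatureCollection is
#'   attached as the `geojson` attribute when boundaries were supplied.
#' @export
differenceMap <- function(data, model, boundaries = NULL, out = NULL) {
  model <- .alignFlows(data, model)
  tab <- data.frame(id = names(data), observed = as.numeric(data),
                    modelled = as.numeric(model),
                    difference = as.numeric(model - data),
                    has_geometry = FALSE, stringsAsFactors = FALSE)
  gj <- NULL
  if (!is.null(boundaries)) {
    gj <- if (is.character(boundaries))
      jsonlite::read_json(boundaries) else boundaries
    if (is.null(gj$features))
      stop("boundaries must be a GeoJSON FeatureCollection")
    feat_ids <- vapply(gj$features, function(f)
      as.character(f$properties$id), character(1))
    for (k in seq_along(gj$features)) {
      row <- match(feat_ids[k], tab$id)
      if (is.na(row)) next
      tab$has_geometry[row] <- TRUE
      gj$features[[k]]$properties$observed <- tab$observed[row]
      gj$features[[k]]$properties$modelled <- tab$modelled[row]
      gj$features[[k]]$properties$difference <- tab$difference[row]
    }
    missing <- tab$id[!tab$has_geometry]
    if (length(missing))
      warning("no geometry for territories: ",
              paste(missing, collapse = ", "),
              "; kept as attribute-only rows")
    if (!is.null(out))
      jsonlite::write_json(gj, out, auto_unbox = TRUE, digits = NA)
    attr(tab, "geojson") <- gj
  }
  tab
}
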