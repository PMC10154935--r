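#' Enumerate the retail covariate variants
#'
#' All subsets of the benefit covariates, the empty (travel-time-only)
#' variant included, give `2^5 = 32` retail specifications for the default
#' five covariates. The travel-time cost `beta` is part of every variant.
#' Subsets are ordered by size, then lexicographically.
#'
#' @param covariates benefit covariate names (default the canonical five).
#' @param loss,train_year passed through to each [ModelSpec()].
#' @return list of [ModelSpec-class] objects.
#' @examples
#' length(enumerateRetailVariants(loss = "poisson", train_year = "2019"))
#' @export
enumerateRetailVariants <- function(covariates = BENEFIT_NAMES,
                                    loss = "poisson", train_year) {
  if (anyDuplicated(covariates))
    stop("duplicated covariate names")
  covariates <- sort(covariates)
  subsets <- list(character())
  for (k in seq_along(covariates))
    subsets <- c(subsets, utils::combn(covariates, k, simplify = FALSE))
  lapply(subsets, function(s)
    ModelSpec("retail", covariates = s, loss = loss, train_year = train_year))
}

#' Full model grid for one loss and training year
#'
#' One gravity, one radiation and the 32 retail variants.
#'
#' @inheritParams enumerateRetailVariants
#' @return list of 34 [ModelSpec-class] objects.
#' @export
specGrid <- function(loss, train_year, covariates = BENEFIT_NAMES) {
  c(list(ModelSpec("gravity", loss = loss, train_year = train_year),
         ModelSpec("radiation", loss = loss, train_year = train_year)),
    enumerateRetailVariants(covariates, loss, train_year))
}

## Parameter handling: the optimiser works on an unconstrained internal
## scale; radiation's rho and r are kept positive via a log transform. The
## ridge penalty always applies to the natural-scale parameters.
.paramSetup <- function(spec) {
  switch(spec@family,
    gravity = list(
      names = c("b", "c"),
      to_theta = identity, from_theta = identity,
      starts = as.matrix(expand.grid(b = c(0, 0.5, 1),
                                     c = c(-0.5, 0, 0.5)))),
    radiation = list(
      names = c("rho", "r"),
      to_theta = exp, from_theta = log,
      starts = log(as.matrix(expand.grid(rho = c(0.5, 2, 8),
                                         r = c(0.5, 1, 2))))),
    retail = {
      anames <- if (length(spec@covariates))
        paste0("alpha_", sort(spec@covariates)) else character()
      nm <- c(anames, "beta")
      beta0 <- c(0, 0.005, 0.02, 0.1)
      starts <- cbind(matrix(0, nrow = length(beta0), ncol = length(anames)),
                      beta0)
      colnames(starts) <- nm
      list(names = nm, to_theta = identity, from_theta = identity,
           starts = starts)
    }
  )
}

#' Calibrate one model specification on a study
#'
#' Minimises the penalised loss of the spec's training year by a
#' deterministic multi-start scheme: a fixed coarse grid of start points per
#' family (gravity exponents around zero; radiation `rho`, `r` over
#' \{0.5, 2, 8\} x \{0.5, 1, 2\}; retail alphas at zero with `beta` over
#' \{0, 0.005, 0.02, 0.1\}) each refined by [stats::nlminb()], and the best
#' refined point polished with Nelder-Mead. No randomness is involved, so
#' refits are reproducible. Non-convergence is flagged on the result, never
#' silent.
#'
#' @param spec a [ModelSpec-class].
#' @param study a [LinesStudy-class] containing the training year.
#' @param lambda ridge weight of the penalty (default 1).
#' @param admissions_mode normalisation for admissions covariates, see
#'   [normalisedBenefits()].
#' @param loss_tol convergence tolerance on the loss.
#' @return a [ModelFit-class] with predictions for every study year, each
#'   scaled to that year's observed total outflow.
#' @examples
#' study <- makeStudy(syntheticConfig(seed = 1, n_destinations = 10))
#' fitModel(ModelSpec("gravity", loss = "poisson", train_year = "2019"), study)
#' @export
fitModel <- function(spec, study, lambda = 1,
                     admissions_mode = "per_100k", loss_tol = 1e-8) {
  validObject(spec)
  if (!spec@trainYear %in% studyYears(study))
    stop("training year '", spec@trainYear, "' is absent from the study")
  data <- lineCounts(study)[, spec@trainYear]
  total <- sum(data)
  benefits <- if (spec@family == "retail")
    normalisedBenefits(study, admissions_mode) else NULL
  if (spec@family == "retail" && length(spec@covariates)) {
    w <- benefits[, sort(spec@covariates), drop = FALSE]
    if (any(w <= 0))
      stop("covariate '",
           colnames(w)[which(w <= 0, arr.ind = TRUE)[1, 2]],
           "' has a nonpositive rate and cannot enter a logarithm")
  }
  setup <- .paramSetup(spec)
  lossFun <- if (spec@loss == "gaussian") gaussianLoss else poissonLoss

  objective <- function(par) {
    theta <- setup$to_theta(par)
    names(theta) <- setup$names
    val <- tryCatch(
      lossFun(data, predictFlows(spec@family, theta, study, total, benefits),
              theta = theta, lambda = lambda),
      error = function(e) NA_real_)
    if (!is.finite(val)) 1e12 else val
  }

  ## nlminb flags success either with code 0 or with one of its convergence
  ## messages; "false"/"singular" convergence and the iteration limit are
  ## genuine failures.
  ok_message <- "relative convergence|X-convergence|absolute function convergence"
  refined <- lapply(seq_len(nrow(setup$starts)), function(i) {
    res <- stats::nlminb(setup$starts[i, ], objective,
                         control = list(abs.tol = loss_tol,
                                        rel.tol = 1e-10, iter.max = 500))
    list(par = res$par, value = res$objective,
         ok = res$convergence == 0 || grepl(ok_message, res$message),
         message = res$message)
  })
  values <- vapply(refined, `[[`, numeric(1), "value")
  best <- refined[[which.min(values)]]
  converged <- best$ok
  if (length(best$par) > 1L) {
    polish <- stats::optim(best$par, objective, method = "Nelder-Mead",
                           control = list(maxit = 2000, reltol = 1e-10))
    converged <- converged || polish$convergence == 0
    if (polish$value < best$value) {
      best$par <- polish$par
      best$value <- polish$value
    }
  }

  theta <- setup$to_theta(best$par)
  names(theta) <- setup$names
  totals <- colSums(lineCounts(study))
  flows <- lapply(studyYears(study), function(y)
    predictFlows(spec@family, theta, study, totals[[y]], benefits))
  names(flows) <- studyYears(study)
  new("ModelFit", spec = spec, theta = theta,
      trainLoss = best$value,
      logLik = flowLogLik(data, flows[[spec@trainYear]], spec@loss),
      converged = converged, flows = flows,
      diagnostics = list(n_starts = nrow(setup$starts),
                         start_values = unname(values),
                         messages = vapply(refined, `[[`, character(1),
                                           "message"),
                         lambda = lambda, admissions_mode = admissions_mode))
}

#' Twofold cross-validation over the study's two years
#'
#' Fits every specification on its training year and validates on the other
#' year: training on 2019 validates on 2020 and vice versa. Validation
#' predictions are rescaled to the validation year's observed total outflow
#' (the outflow constraint is part of every model). The BIC is computed as
#' `2 log M - 2 log Lhat` with, by default, the log-likelihood summed over
#' the whole modelled sample (both years, `M = 2 N` observations);
#' `bic_sample = "train_year"` restricts both to the training year
#' (`M = N`).
#'
#' @param specs list of [ModelSpec-class] (e.g. from [specGrid()]).
#' @param study a two-year [LinesStudy-class].
#' @inheritParams fitModel
#' @param bic_sample `"both_years"` (default) or `"train_year"`.
#' @param keep_fits if TRUE the [ModelFit-class] objects are attached as the
#'   `fits` attribute of the returned table.
#' @return data.frame with one row per spec: identification columns, fitted
#'   parameters (`theta` list-column and a formatted `params` string),
#'   training loss, validation Sorensen-Dice `S`, validation `log_mse`,
#'   validation losses under both forms, `loglik` and `bic`.
#' @export
crossValidate <- function(specs, study, lambda = 1,
                          admissions_mode = "per_100k",
                          bic_sample = c("both_years", "train_year"),
                          keep_fits = FALSE) {
  bic_sample <- match.arg(bic_sample)
  years <- studyYears(study)
  if (length(years) != 2L)
    stop("twofold cross-validation needs a study with exactly two years")
  counts <- lineCounts(study)
  rows <- vector("list", length(specs))
  fits <- if (keep_fits) vector("list", length(specs)) else NULL
  for (k in seq_along(specs)) {
    spec <- specs[[k]]
    if (!spec@trainYear %in% years)
      stop("spec ", specId(spec), " trains on a year absent from the study")
    fit <- fitModel(spec, study, lambda = lambda,
                    admissions_mode = admissions_mode)
    val_year <- setdiff(years, spec@trainYear)
    val_data <- counts[, val_year]
    val_flows <- fit@flows[[val_year]]
    ll <- if (bic_sample == "both_years")
      sum(vapply(years, function(y)
        flowLogLik(counts[, y], fit@flows[[y]], spec@loss), numeric(1)))
    else fit@logLik
    M <- if (bic_sample == "both_years") 2L * nrow(counts) else nrow(counts)
    rows[[k]] <- data.frame(
      id = specId(spec), family = spec@family,
      covariates = paste(sort(spec@covariates), collapse = "+"),
      n_covariates = length(spec@covariates),
      loss = spec@loss, train_year = spec@trainYear,
      validate_year = val_year,
      n_params = length(fit@theta),
      params = paste(sprintf("%s=%.4g", names(fit@theta), fit@theta),
                     collapse = ", "),
      converged = fit@converged,
      train_loss = fit@trainLoss,
      S = sorensenDice(val_data, val_flows),
      log_mse = logMSE(val_data, val_flows),
      val_gaussian = gaussianLoss(val_data, val_flows, theta = 0),
      val_poisson = poissonLoss(val_data, val_flows, theta = 0),
      loglik = ll,
      bic = bic(M, ll),
      stringsAsFactors = FALSE
    )
    rows[[k]]$theta <- I(list(fit@theta))
    if (keep_fits) fits[[k]] <- fit
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keep_fits) attr(out, "fits") <- fits
  out
}
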