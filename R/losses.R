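#' Penalised calibration losses
#'
#' Both losses compare observed counts `T_j^data` with modelled flows
#' `T_j^model` over the `N` destinations and add an L2 ridge penalty
#' `lambda * ||theta||^2` on the free parameter vector (all free parameters,
#' the travel-time cost included; `lambda = 1` by default).
#'
#' * Gaussian (mean-square):
#'   `(1/2N) sum_j (T_j^data - T_j^model)^2 + lambda ||theta||^2`.
#' * Poisson (negative log-likelihood up to data-only terms):
#'   `(1/N) sum_j [T_j^model - T_j^data log T_j^model] + lambda ||theta||^2`.
#'   A zero observed count contributes just `T_j^model`; a nonpositive
#'   modelled flow facing a positive count is an error.
#'
#' @param data named vector of observed counts.
#' @param flows named vector of modelled flows over the same destinations.
#' @param theta parameter vector entering the penalty (use `numeric()` or 0
#'   for an unpenalised comparison).
#' @param lambda ridge weight.
#' @return scalar loss.
#' @examples
#' gaussianLoss(c(1, 3), c(2, 2), theta = 0)          # 0.5
#' poissonLoss(2, 2, theta = 0)                       # 2 - 2 log 2
#' @name losses
NULL

.alignFlows <- function(data, flows) {
  if (length(data) != length(flows))
    stop("data and model cover different numbers of destinations")
  if (!is.null(names(data)) && !is.null(names(flows))) {
    if (!setequal(names(data), names(flows)))
      stop("data and model cover different destination sets")
    flows <- flows[names(data)]
  }
  flows
}

#' @rdname losses
#' @export
gaussianLoss <- function(data, flows, theta, lambda = 1) {
  flows <- .alignFlows(data, flows)
  sum((data - flows)^2) / (2 * length(data)) + lambda * sum(theta^2)
}

#' @rdname losses
#' @export
poissonLoss <- function(data, flows, theta, lambda = 1) {
  flows <- .alignFlows(data, flows)
  if (any(flows <= 0 & data > 0))
    stop("nonpositive modelled flow for a destination with observed lines")
  term <- flows - ifelse(data > 0, data * log(flows), 0)
  sum(term) / length(data) + lambda * sum(theta^2)
}

#' Unpenalised log-likelihoods at the calibrated parameters
#'
#' Used by [bic()]: the Gaussian form is the unit-variance normal
#' log-likelihood consistent with the mean-square loss; the Poisson form
#' includes the `log(T_j^data!)` term so the likelihood value is
#' well-defined (the term is constant in the parameters).
#'
#' @inheritParams losses
#' @param loss `"gaussian"` or `"poisson"`.
#' @return scalar log-likelihood.
#' @export
flowLogLik <- function(data, flows, loss = c("poisson", "gaussian")) {
  loss <- match.arg(loss)
  flows <- .alignFlows(data, flows)
  if (loss == "gaussian") {
    -0.5 * sum((data - flows)^2) - 0.5 * length(data) * log(2 * pi)
  } else {
    if (any(flows <= 0 & data > 0))
      stop("nonpositive modelled flow for a destination with observed lines")
    sum(ifelse(data > 0, data * log(flows), 0) - flows - lgamma(data + 1))
  }
}
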