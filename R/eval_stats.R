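#' Root mean square error
#'
#' @param p simulated values.
#' @param o observed values (same length, n >= 1).
#' @return RMSE, in the units of the variable.
#' @export
rmse <- function(p, o) {
  if (length(p) != length(o)) stop("p and o must have equal length")
  if (length(p) < 1) stop("need at least one pair")
  sqrt(sum((p - o)^2) / length(p))
}

#' Nash-Sutcliffe model efficiency
#'
#' `E = 1 - sum((O - P)^2) / sum((O - mean(O))^2)`; ranges from -Inf to 1,
#' with 1 a perfect simulation and 0 no better than the observed mean.
#' Undefined for constant observations.
#'
#' @param p simulated values.
#' @param o observed values (same length, n >= 2, not constant).
#' @return efficiency E.
#' @export
nse <- function(p, o) {
  if (length(p) != length(o)) stop("p and o must have equal length")
  if (length(o) < 2) stop("need at least two pairs")
  denom <- sum((o - mean(o))^2)
  if (denom == 0) stop("observations are constant; E is undefined")
  1 - sum((o - p)^2) / denom
}

#' Willmott index of agreement
#'
#' `d = 1 - sum((O - P)^2) / sum((|P - mean(O)| + |O - mean(O)|)^2)`;
#' bounded in \[0, 1\], with 1 a perfect simulation.
#'
#' @param p simulated values.
#' @param o observed values (same length, n >= 2).
#' @return agreement index d.
#' @export
agreement_d <- function(p, o) {
  if (length(p) != length(o)) stop("p and o must have equal length")
  if (length(o) < 2) stop("need at least two pairs")
  ob <- mean(o)
  denom <- sum((abs(p - ob) + abs(o - ob))^2)
  if (denom == 0) stop("degenerate series (all values equal); d is undefined")
  1 - sum((o - p)^2) / denom
}

#' Evaluation statistics for one prediction-observation pairing
#'
#' @param p simulated values.
#' @param o observed values.
#' @return list of class `eval_stats`: `rmse`, `nse`, `agreement`, `n`.
#' @export
eval_stats <- function(p, o) {
  structure(list(rmse = rmse(p, o), nse = nse(p, o),
                 agreement = agreement_d(p, o), n = length(o)),
            class = "eval_stats")
}

#' Simulation acceptance check
#'
#' An acceptable simulation requires E > 0.36 and d > 0.7 (both strict).
#'
#' @param stats an [eval_stats()] result (or any list with `nse` and
#'   `agreement`).
#' @return list: `pass_nse`, `pass_agreement`, `pass` (combined), and a
#'   `reasons` character vector for failures.
#' @export
acceptance_check <- function(stats) {
  pass_e <- stats$nse > 0.36
  pass_d <- stats$agreement > 0.7
  reasons <- character(0)
  if (!pass_e) reasons <- c(reasons,
    sprintf("E = %.3f is not > 0.36", stats$nse))
  if (!pass_d) reasons <- c(reasons,
    sprintf("d = %.3f is not > 0.7", stats$agreement))
  list(pass_nse = pass_e, pass_agreement = pass_d,
       pass = pass_e && pass_d, reasons = reasons)
}
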