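#' Staged coordinate grid calibration
#'
#' Deterministic replacement for manual trial-and-error calibration:
#' parameter groups (stages) are searched in a fixed order -- in this
#' package's workflow soil water parameters first, then N transformation
#' parameters, then crop parameters, mirroring the calibration order
#' soil water content, nitrate concentration, crop N uptake, yield, dry
#' matter. Within a stage each parameter is scanned over its grid while
#' the others are held at their current best (coordinate descent); the
#' full stage sequence is repeated `sweeps` times so that late-stage
#' adjustments can feed back into the earlier stages. Candidates with a
#' non-finite objective are rejected and logged in the trace.
#'
#' @param objective function taking a named list of parameter values and
#'   returning a scalar objective (e.g. weighted RMSE over observation
#'   variables); smaller is better.
#' @param stages named list of stages, in search order; each stage is a
#'   named list of numeric candidate grids
#'   (e.g. `list(water = list(drain_frac = c(.3, .5, .7)), ...)`).
#' @param start named list of starting values; defaults to the first grid
#'   point of each parameter.
#' @param sweeps passes over the full stage sequence (default 2).
#' @return list: `par` (best parameter list), `objective` (value at the
#'   optimum), `trace` (data.frame of every evaluation: stage, parameter,
#'   candidate value, objective, accepted flag).
#' @export
calibrate <- function(objective, stages, start = NULL, sweeps = 2) {
  params <- list()
  for (stage in stages) for (pn in names(stage))
    params[[pn]] <- stage[[pn]][1]
  if (!is.null(start)) params[names(start)] <- start
  if (length(params) == 0)
    return(list(par = if (is.null(start)) list() else start,
                objective = if (is.null(start)) NA_real_ else
                  objective(start),
                trace = data.frame()))
  best <- objective(params)
  if (!is.finite(best)) stop("objective is not finite at the start values")
  trace <- list()
  for (sweep in seq_len(sweeps)) {
    for (sn in names(stages)) {
      for (pn in names(stages[[sn]])) {
        for (v in stages[[sn]][[pn]]) {
          cand <- params
          cand[[pn]] <- v
          obj <- tryCatch(objective(cand), error = function(e) NaN)
          ok <- is.finite(obj)
          accept <- ok && obj < best
          trace[[length(trace) + 1]] <- data.frame(
            stage = sn, sweep = sweep, parameter = pn, value = v,
            objective = if (ok) obj else NA_real_, accepted = accept,
            stringsAsFactors = FALSE)
          if (accept) {
            best <- obj
            params <- cand
          }
        }
      }
    }
  }
  list(par = params, objective = best, trace = do.call(rbind, trace))
}
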