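#' Empirical seasonal N loss estimate
#'
#' The Expert-N loss term: `N_input x 0.019 x growing season (weeks)`,
#' where `N_input` is the farmer-practice N rate for the crop.
#'
#' @param n_input_farmer farmer-practice N fertilizer rate, kg N ha^-1.
#' @param season_weeks length of the growing season, weeks.
#' @return expected N loss, kg N ha^-1.
#' @examples
#' n_loss_estimate(450, 10)  # 85.5
#' @export
n_loss_estimate <- function(n_input_farmer, season_weeks) {
  if (any(n_input_farmer < 0) || any(season_weeks < 0))
    stop("inputs must be >= 0")
  n_input_farmer * 0.019 * season_weeks
}

#' Expert-N optimal fertilizer recommendation
#'
#' The recommended dose balances the expected crop uptake, the target
#' residual mineral N after harvest and the expected losses against the
#' mineral N already present at season start and the mineralization
#' credits from soil organic matter and crop residues:
#'
#' `N_opt = N_upt + N_res + N_loss - N_ini - N_hum - N_root`
#'
#' with `N_loss` from [n_loss_estimate()]. A negative result is clamped to
#' zero (no fertilizer needed).
#'
#' @param n_upt expected crop N uptake over the season, kg N ha^-1.
#' @param n_res target root-zone mineral N after harvest, kg N ha^-1.
#' @param n_ini root-zone mineral N at season start, kg N ha^-1.
#' @param n_hum soil organic N mineralization over the season, kg N ha^-1.
#' @param n_root N mineralized from crop residues, kg N ha^-1 (zero when
#'   residues are removed from the field).
#' @param n_input_farmer farmer-practice N rate, kg N ha^-1 (drives the
#'   loss term).
#' @param season_weeks growing season length, weeks (> 0).
#' @return list: `n_opt` (kg N ha^-1) and the `n_loss` component.
#' @examples
#' recommend_n(n_upt = 200, n_res = 50, n_ini = 100, n_hum = 30,
#'             n_root = 0, n_input_farmer = 450, season_weeks = 10)
#' @export
recommend_n <- function(n_upt, n_res, n_ini, n_hum, n_root = 0,
                        n_input_farmer, season_weeks) {
  vals <- c(n_upt, n_res, n_ini, n_hum, n_root, n_input_farmer)
  if (any(vals < 0)) stop("all N masses must be >= 0")
  if (season_weeks <= 0) stop("season_weeks must be > 0")
  n_loss <- n_loss_estimate(n_input_farmer, season_weeks)
  n_opt <- n_upt + n_res + n_loss - n_ini - n_hum - n_root
  list(n_opt = max(n_opt, 0), n_loss = n_loss)
}

#' Reduced fertilizer rate
#'
#' A proportionally reduced dose (e.g. the 80%-of-optimal treatment).
#'
#' @param n_opt recommended dose, kg N ha^-1.
#' @param fraction retained fraction in (0, 1\] (default 0.8).
#' @return reduced dose, kg N ha^-1.
#' @export
reduced_rate <- function(n_opt, fraction = 0.8) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  n_opt * fraction
}
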