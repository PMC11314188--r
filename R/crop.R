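#' Crop parameter set
#'
#' Parameters of the vegetable growth sub-model: expolinear potential dry
#' matter accumulation, a four-stage crop coefficient curve, linear root
#' deepening, a Greenwood-style critical N dilution curve with a luxury
#' consumption multiplier, and the dry-to-fresh yield conversion.
#'
#' The expolinear potential trajectory is
#' `W(t) = (cm / rm) * log(1 + exp(rm * (t - tb)))` (t ha^-1), i.e.
#' exponential growth at relative rate `rm` early on, turning linear at
#' maximum rate `cm` around day `tb`. Critical N concentration is
#' `a * DM^(-b)` percent of dry matter (constant at `seedling_max_pct`
#' below 1 t ha^-1), and maximum N concentration is `luxury` times
#' critical.
#'
#' @param name crop name.
#' @param kc a [kc_curve()].
#' @param max_root_depth cm.
#' @param root_rate root deepening rate, cm d^-1.
#' @param cm maximum daily dry matter gain, t ha^-1 d^-1.
#' @param rm relative growth rate of the exponential phase, d^-1.
#' @param tb day of the expolinear transition (days after sowing).
#' @param dilution_a,dilution_b dilution curve coefficients (a > 0,
#'   0 <= b < 1).
#' @param luxury luxury N consumption coefficient, >= 1.
#' @param seedling_max_pct cap of the critical concentration below
#'   1 t ha^-1 dry matter; defaults to `dilution_a`.
#' @param fresh_per_dry kg fresh yield per kg harvested dry matter.
#' @param harvest_index harvested fraction of dry matter.
#' @param init_dm dry matter at sowing/transplanting, t ha^-1.
#' @param init_root_depth rooting depth at sowing, cm.
#' @return object of class `crop_params`.
#' @export
crop_params <- function(name, kc = kc_curve(), max_root_depth = 40,
                        root_rate = 1, cm = 0.1, rm = 0.15, tb = 20,
                        dilution_a = 4.5, dilution_b = 0.25, luxury = 1.2,
                        seedling_max_pct = dilution_a, fresh_per_dry = 10,
                        harvest_index = 0.7, init_dm = 0.01,
                        init_root_depth = 5) {
  if (dilution_a <= 0 || dilution_b < 0 || dilution_b >= 1)
    stop("need dilution_a > 0 and 0 <= dilution_b < 1")
  if (luxury < 1) stop("luxury coefficient must be >= 1")
  if (fresh_per_dry <= 0 || harvest_index <= 0)
    stop("yield conversions must be > 0")
  structure(list(name = name, kc = kc, max_root_depth = max_root_depth,
                 root_rate = root_rate, cm = cm, rm = rm, tb = tb,
                 dilution_a = dilution_a, dilution_b = dilution_b,
                 luxury = luxury, seedling_max_pct = seedling_max_pct,
                 fresh_per_dry = fresh_per_dry,
                 harvest_index = harvest_index, init_dm = init_dm,
                 init_root_depth = init_root_depth),
            class = "crop_params")
}

#' Default parameter sets for the three rotation vegetables
#'
#' Starting values sized to the short Beijing seasons (transplanted
#' cauliflower ~55-65 d, direct-sown amaranth ~22-36 d, spinach
#' ~40-53 d) and to locally typical fresh yields and N uptakes; all
#' fields are free parameters for the calibration harness.
#'
#' @return named list of [crop_params()] for `cauliflower`, `amaranth`,
#'   `spinach`.
#' @export
default_crop_params <- function() {
  list(
    cauliflower = crop_params(
      "cauliflower", kc = kc_curve(0.7, 1.05, 0.95),
      max_root_depth = 50, root_rate = 1.0, cm = 0.12, rm = 0.12, tb = 25,
      dilution_a = 4.5, dilution_b = 0.25, luxury = 1.25,
      fresh_per_dry = 11, harvest_index = 0.45, init_dm = 0.05,
      init_root_depth = 10),
    amaranth = crop_params(
      "amaranth", kc = kc_curve(0.7, 1.0, 0.95),
      max_root_depth = 30, root_rate = 1.2, cm = 0.09, rm = 0.2, tb = 12,
      dilution_a = 4.0, dilution_b = 0.25, luxury = 1.1,
      fresh_per_dry = 12, harvest_index = 0.85, init_dm = 0.005,
      init_root_depth = 2),
    spinach = crop_params(
      "spinach", kc = kc_curve(0.7, 1.0, 0.95),
      max_root_depth = 30, root_rate = 1.0, cm = 0.09, rm = 0.15, tb = 18,
      dilution_a = 4.8, dilution_b = 0.25, luxury = 1.15,
      fresh_per_dry = 14, harvest_index = 0.9, init_dm = 0.005,
      init_root_depth = 2)
  )
}

#' Initial crop state
#'
#' @param params a [crop_params()].
#' @return list with `days_since_sowing`, `dm` (t ha^-1), `plant_n`
#'   (kg N ha^-1) and `root_depth` (cm).
#' @export
crop_state <- function(params) {
  n0 <- params$luxury * critical_n_pct(params$init_dm, params) *
    params$init_dm * 10
  list(days_since_sowing = 0, dm = params$init_dm, plant_n = n0,
       root_depth = params$init_root_depth)
}

# closed-form expolinear potential dry matter, t/ha, at t days after sowing
potential_dm <- function(t, params) {
  params$init_dm +
    (params$cm / params$rm) *
    (log1p(exp(params$rm * (t - params$tb))) -
       log1p(exp(params$rm * (0 - params$tb))))
}

# temperature growth factor: zero at/below 4 deg C, 1 at/above 20 deg C
growth_temp_factor <- function(temp, base = 4, opt = 20) {
  pmin(pmax((temp - base) / (opt - base), 0), 1)
}

#' Critical N concentration from the dilution curve
#'
#' `a * DM^(-b)` percent of dry matter, capped at the seedling maximum for
#' stands below 1 t ha^-1.
#'
#' @param dm dry matter, t ha^-1.
#' @param params a [crop_params()].
#' @return critical N concentration, % of dry matter.
#' @export
critical_n_pct <- function(dm, params) {
  if (any(dm < 0)) stop("dm must be >= 0")
  pct <- ifelse(dm < 1, params$seedling_max_pct,
                params$dilution_a * dm^(-params$dilution_b))
  pmin(pct, params$seedling_max_pct)
}

#' Daily crop N demand
#'
#' The N mass that would bring the plant to the luxury ceiling (luxury
#' coefficient times the critical dilution concentration) at tomorrow's
#' potential dry matter: `max(0, L * crit%N(DM') * DM' * 10 - plant_n)`
#' (the factor 10 converts t ha^-1 x % to kg ha^-1).
#'
#' @param state a [crop_state()].
#' @param params a [crop_params()].
#' @param temp today's mean temperature (slows potential growth), deg C.
#' @return demand, kg N ha^-1 d^-1.
#' @export
n_demand <- function(state, params, temp = 20) {
  ft <- growth_temp_factor(temp)
  inc <- (potential_dm(state$days_since_sowing + 1, params) -
            potential_dm(state$days_since_sowing, params)) * ft
  dm_next <- state$dm + inc
  ceiling_n <- params$luxury * critical_n_pct(dm_next, params) * dm_next * 10
  max(0, ceiling_n - state$plant_n)
}

#' Advance the crop by one day
#'
#' Dry matter grows by the potential expolinear increment scaled by the
#' temperature factor and by `min(water_stress, n_stress)`; roots deepen
#' linearly to the maximum; N taken up today is added to the plant and
#' clipped at the luxury ceiling.
#'
#' @param state a [crop_state()].
#' @param params a [crop_params()].
#' @param water_stress,n_stress stress factors in \[0, 1\] (1 = no
#'   stress).
#' @param n_uptake N actually taken up today, kg N ha^-1.
#' @param temp mean air temperature, deg C.
#' @return updated state.
#' @export
grow_daily <- function(state, params, water_stress = 1, n_stress = 1,
                       n_uptake = 0, temp = 20) {
  if (water_stress < 0 || water_stress > 1 || n_stress < 0 || n_stress > 1)
    stop("stress factors must be in [0, 1]")
  ft <- growth_temp_factor(temp)
  inc <- (potential_dm(state$days_since_sowing + 1, params) -
            potential_dm(state$days_since_sowing, params)) *
    ft * min(water_stress, n_stress)
  state$dm <- state$dm + inc
  state$plant_n <- state$plant_n + n_uptake
  ceiling_n <- params$luxury * critical_n_pct(state$dm, params) *
    state$dm * 10
  state$plant_n <- min(state$plant_n, ceiling_n)
  state$root_depth <- min(state$root_depth + params$root_rate * ft,
                          params$max_root_depth)
  state$days_since_sowing <- state$days_since_sowing + 1
  state
}

#' Nitrogen stress factor of the current stand
#'
#' Actual over critical N concentration, clipped to \[0, 1\].
#'
#' @param state a [crop_state()].
#' @param params a [crop_params()].
#' @return stress factor in \[0, 1\].
#' @export
n_stress_factor <- function(state, params) {
  if (state$dm <= 0) return(1)
  actual_pct <- state$plant_n / (state$dm * 10)
  min(max(actual_pct / critical_n_pct(state$dm, params), 0), 1)
}

#' Fresh marketable yield at harvest
#'
#' @param state a [crop_state()].
#' @param params a [crop_params()].
#' @return fresh yield, kg ha^-1
#'   (`DM * harvest_index * fresh_per_dry * 1000`).
#' @export
fresh_yield <- function(state, params) {
  state$dm * params$harvest_index * params$fresh_per_dry * 1000
}
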