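#' Simulation control parameters
#'
#' Tunable rate constants and coefficients of the daily simulator, all
#' exposed to the calibration harness. Defaults are the package's
#' uncalibrated starting values.
#'
#' @param curve_number NRCS curve number applied to rainfall (irrigation
#'   is assumed to infiltrate fully: furrow and micro-sprinkler water is
#'   confined to the plot).
#' @param drain_frac daily drainage fraction between field capacity and
#'   saturation (see [redistribute()]).
#' @param conc_irr nitrate concentration of irrigation water, mg N L^-1
#'   (back-calculated from the published Nirr/I ratio, about 3.9).
#' @param humus_k,manure_k first-order rate constants of the native humus
#'   and added organic (manure) pools, d^-1.
#' @param k_hydrolysis urea hydrolysis rate, d^-1.
#' @param k_nitrify nitrification rate, d^-1.
#' @param k_denitrify denitrification rate at saturation, d^-1.
#' @param wfps_threshold,denit_exponent denitrification onset and shape
#'   (see [denitrify()]).
#' @param vol_base_frac,vol_decay,vol_suppression ammonia volatilization
#'   parameters (see [volatilize()]).
#' @param extract_frac_n daily extractable fraction of rooted mineral N.
#' @param air_dry_frac surface air-dry limit as a fraction of wilting
#'   point.
#' @param soil_evap_coef soil evaporation coefficient applied to ET0 on
#'   bare ground.
#' @param cover_dm dry matter (t ha^-1) at which the canopy fully covers
#'   the ground.
#' @param immobilization fraction of gross humus mineralization
#'   immobilized again (net = gross x (1 - immobilization)).
#' @param humus_total_n per-layer native organic N, kg N ha^-1; `NULL`
#'   derives it from typical profile total-N contents.
#' @param no3_init,nh4_init initial per-layer mineral N, kg N ha^-1
#'   (recycled to the number of layers).
#' @return list of class `sim_params`.
#' @export
sim_params <- function(curve_number = 75, drain_frac = 0.5,
                       conc_irr = 3.9, humus_k = 8e-5, manure_k = 0.02,
                       k_hydrolysis = 0.36, k_nitrify = 0.2,
                       k_denitrify = 0.1, wfps_threshold = 0.6,
                       denit_exponent = 2, vol_base_frac = 0.15,
                       vol_decay = 0.35, vol_suppression = 0.1,
                       extract_frac_n = 0.1, air_dry_frac = 0.5,
                       soil_evap_coef = 0.6, cover_dm = 2,
                       immobilization = 0, humus_total_n = NULL,
                       no3_init = 12, nh4_init = 2) {
  structure(as.list(environment()), class = "sim_params")
}

# default humus N per layer from typical total-N profile (g kg^-1,
# decreasing with depth), converted with bulk density and thickness
default_humus_n <- function(profile) {
  mid <- (profile$top + profile$bottom) / 2
  tn <- ifelse(mid <= 30, 1.2, ifelse(mid <= 60, 0.8,
                                      ifelse(mid <= 90, 0.5, 0.3)))
  tn * profile$bulk_density * profile$thickness * 100
}

#' Assemble a rotation run configuration
#'
#' @param weather validated daily weather table covering the simulation
#'   span (see [validate_weather()]).
#' @param management event table: `date`, `type` (irrigation | urea |
#'   manure | sowing | harvest), `crop`, `amount`, `incorporated`.
#' @param calendar rotation calendar: `crop`, `sowing`, `harvest`.
#' @param site list with `latitude` (deg) and `altitude` (m).
#' @param profile a [soil_profile()].
#' @param crops named list of [crop_params()] keyed by crop name.
#' @param params a [sim_params()].
#' @param report_plane depth (cm) at which drainage and nitrate leaching
#'   are reported (default 90; the state may extend deeper).
#' @param start,end simulation span (defaults: 10 days before the first
#'   sowing to the last harvest).
#' @return list of class `run_config`.
#' @export
run_config <- function(weather, management, calendar,
                       site = list(latitude = 39.9, altitude = 50),
                       profile = reference_soil_profile(),
                       crops = default_crop_params(),
                       params = sim_params(), report_plane = 90,
                       start = NULL, end = NULL) {
  weather <- validate_weather(weather)
  calendar <- calendar[order(calendar$sowing), ]
  if (any(calendar$harvest <= calendar$sowing))
    stop("calendar: harvest must follow sowing")
  if (nrow(calendar) > 1 &&
      any(calendar$sowing[-1] <= calendar$harvest[-nrow(calendar)]))
    stop("calendar seasons overlap")
  if (is.null(start))
    start <- max(min(calendar$sowing) - 10, min(weather$date))
  if (is.null(end)) end <- max(calendar$harvest)
  span <- seq(as.Date(start), as.Date(end), by = "day")
  if (!all(span %in% weather$date))
    stop("weather does not cover the simulation span ",
         start, "..", end)
  if (!(report_plane %in% profile$bottom))
    stop("report_plane must coincide with a layer bottom")
  miss <- setdiff(calendar$crop, names(crops))
  if (length(miss)) stop("no crop parameters for: ",
                         paste(miss, collapse = ", "))
  structure(list(weather = weather, management = management,
                 calendar = calendar, site = site, profile = profile,
                 crops = crops, params = params,
                 report_plane = report_plane,
                 start = as.Date(start), end = as.Date(end)),
            class = "run_config")
}

#' Run the daily rotation simulation
#'
#' Executes the daily loop -- weather to ET demand, curve-number runoff
#' and infiltration, tipping-bucket redistribution, N transformations,
#' mixing-cell nitrate transport, crop water/N uptake and growth --
#' resetting the crop state at each sowing and carrying the soil state
#' across seasons. Water and N mass closure residuals are recorded every
#' day.
#'
#' @param config a [run_config()].
#' @return list of class `rotation_run`:
#'   `daily` (per-day states and fluxes, incl. closure residuals),
#'   `seasons` (per-season and annual ledger rows, see
#'   [season_water_balance()] / [season_n_balance()]),
#'   `final_state` (soil water and N pools at the end), and `config`.
#' @export
run_rotation <- function(config) {
  stopifnot(inherits(config, "run_config"))
  prof <- config$profile
  pp <- config$params
  nl <- nrow(prof)
  thick <- prof$thickness
  dates <- seq(config$start, config$end, by = "day")
  wx <- config$weather[match(dates, config$weather$date), ]
  mgmt <- config$management
  mgmt$date <- as.Date(mgmt$date)

  # state
  theta <- prof$theta_fc
  urea <- numeric(nl)
  nh4 <- rep_len(pp$nh4_init, nl)
  no3 <- rep_len(pp$no3_init, nl)
  humus <- if (is.null(pp$humus_total_n)) default_humus_n(prof) else
    rep_len(pp$humus_total_n, nl)
  manure <- numeric(nl)
  crop <- NULL; crop_name <- NA_character_; cparams <- NULL
  season_len <- NA_real_
  last_app <- -1e6; last_app_inc <- FALSE
  plane_idx <- which(prof$bottom == config$report_plane)
  # manure incorporation split over the top 20 cm by overlap
  inc_depth <- 20
  ov <- pmax(pmin(prof$bottom, inc_depth) - pmin(prof$top, inc_depth), 0)
  inc_frac <- ov / sum(ov)
  yields <- list()

  rows <- vector("list", length(dates))
  rep_iv <- cbind(c(0, 15, 30, 60, 90), c(15, 30, 60, 90, 120))
  rep_iv <- rep_iv[rep_iv[, 2] <= max(prof$bottom), , drop = FALSE]
  layer_60_90 <- which(prof$top >= 60 & prof$bottom <= 90)

  for (di in seq_along(dates)) {
    today <- dates[di]
    w <- wx[di, ]
    temp <- (w$tmax + w$tmin) / 2
    ev <- mgmt[mgmt$date == today, , drop = FALSE]

    storage0 <- sum(theta_to_mm(theta, thick))
    npool0 <- sum(urea, nh4, no3, humus, manure) +
      (if (!is.null(crop)) crop$plant_n else 0)

    # --- management events ---
    fert_in <- 0; manure_in <- 0; irr <- 0
    seed_n <- 0; harvest_n <- 0
    if (nrow(ev) > 0) {
      for (k in seq_len(nrow(ev))) {
        e <- ev[k, ]
        if (e$type == "sowing") {
          cparams <- config$crops[[e$crop]]
          crop <- crop_state(cparams)
          crop_name <- e$crop
          cal_row <- config$calendar[config$calendar$crop == e$crop &
                                       config$calendar$sowing == today, ]
          season_len <- as.numeric(
            (if (nrow(cal_row)) cal_row$harvest[1] else today + 60) - today)
          seed_n <- seed_n + crop$plant_n  # transplant/seed N input
        } else if (e$type == "harvest") {
          if (!is.null(crop)) {
            yields[[length(yields) + 1]] <- data.frame(
              date = today, crop = crop_name,
              yield = fresh_yield(crop, cparams),
              dm = crop$dm, plant_n = crop$plant_n,
              stringsAsFactors = FALSE)
            harvest_n <- harvest_n + crop$plant_n  # exported N output
            crop <- NULL; cparams <- NULL; crop_name <- NA_character_
          }
        } else if (e$type == "urea") {
          urea[1] <- urea[1] + e$amount
          fert_in <- fert_in + e$amount
          last_app <- di; last_app_inc <- isTRUE(e$incorporated)
        } else if (e$type == "manure") {
          manure <- manure + e$amount * inc_frac
          manure_in <- manure_in + e$amount
          last_app <- di; last_app_inc <- isTRUE(e$incorporated)
        } else if (e$type == "irrigation") {
          irr <- irr + e$amount
        }
      }
    }

    # --- surface water partition ---
    ro <- partition_runoff(w$rain, pp$curve_number)
    runoff <- ro$runoff
    infiltration <- ro$infiltration + irr   # irrigation fully infiltrates
    nirr <- n_mass_from_conc(irr, pp$conc_irr)
    no3[1] <- no3[1] + nirr

    # --- N transformations ---
    hyd <- hydrolyze_urea(urea[1], temp, pp$k_hydrolysis)
    urea[1] <- urea[1] - hyd
    nh4[1] <- nh4[1] + hyd
    vol <- volatilize(nh4[1], di - last_app, water_today = w$rain + irr,
                      incorporated = last_app_inc,
                      base_frac = pp$vol_base_frac, decay = pp$vol_decay,
                      suppression = pp$vol_suppression)
    nh4[1] <- nh4[1] - vol
    hum_gross <- mineralize(humus, pp$humus_k, temp, theta, prof)
    hum_net <- hum_gross * (1 - pp$immobilization)
    humus <- humus - hum_net
    man_min <- mineralize(manure, pp$manure_k, temp, theta, prof)
    manure <- manure - man_min
    nh4 <- nh4 + hum_net + man_min
    nit <- nitrify(nh4, temp, theta, prof, pp$k_nitrify)
    nh4 <- nh4 - nit
    no3 <- no3 + nit
    den <- denitrify(no3, theta, prof, temp, pp$k_denitrify,
                     pp$wfps_threshold, pp$denit_exponent)
    no3 <- no3 - den

    # --- water redistribution and nitrate advection ---
    water_pre <- theta_to_mm(theta, thick)
    rd <- redistribute(theta, infiltration, prof, pp$drain_frac)
    theta <- rd$theta
    ad <- advect_nitrate(no3, water_pre, infiltration, rd$flux_down)
    no3 <- ad$no3
    leach_plane <- ad$flux_mass[plane_idx]
    leach_bottom <- ad$leached
    drain_plane <- rd$flux_down[plane_idx]
    drain_bottom <- rd$drainage

    # --- ET demand and extraction ---
    et0 <- reference_et0(w$tmax, w$tmin, w$wind2, w$solar_rad,
                         as.integer(format(today, "%j")),
                         config$site$latitude, config$site$altitude,
                         rh_mean = w$rh_mean)
    if (!is.null(crop)) {
      frac_season <- min(crop$days_since_sowing / max(season_len, 1), 1)
      kc <- crop_kc(frac_season, cparams$kc)
      cover <- min(crop$dm / pp$cover_dm, 1)
      transp_demand <- cover * crop_et_demand(et0, kc)
      evap_demand <- (1 - cover) * pp$soil_evap_coef * et0
      root_depth <- crop$root_depth
    } else {
      transp_demand <- 0
      evap_demand <- pp$soil_evap_coef * et0
      root_depth <- 0
    }
    ex <- extract_et(theta, evap_demand, transp_demand, root_depth, prof,
                     pp$air_dry_frac)
    theta <- ex$theta

    # --- crop N uptake and growth ---
    uptake <- 0
    if (!is.null(crop)) {
      demand <- n_demand(crop, cparams, temp)
      rf <- root_fractions(crop$root_depth, prof)
      up <- plant_uptake_n(demand, nh4, no3, rf, pp$extract_frac_n)
      nh4 <- up$nh4; no3 <- up$no3
      uptake <- up$total
      water_stress <- if (transp_demand > 0)
        min(max(ex$transp / transp_demand, 0), 1) else 1
      probe <- crop; probe$plant_n <- probe$plant_n + uptake
      nstress <- n_stress_factor(probe, cparams)
      prev_n <- crop$plant_n
      crop <- grow_daily(crop, cparams, water_stress, nstress,
                         n_uptake = uptake, temp = temp)
      # growth may fall short of the potential the demand assumed; N
      # clipped at the luxury ceiling goes back to the rooted nitrate pool
      excess <- (prev_n + uptake) - crop$plant_n
      if (excess > 0) {
        shares <- if (uptake > 0) up$uptake_by_layer / uptake else
          rf / sum(rf)
        no3 <- no3 + excess * shares
        uptake <- uptake - excess
      }
    }

    # --- closure residuals ---
    storage1 <- sum(theta_to_mm(theta, thick))
    water_resid <- (w$rain + irr) -
      (runoff + ex$soil_evap + ex$transp + drain_bottom +
         (storage1 - storage0))
    npool1 <- sum(urea, nh4, no3, humus, manure) +
      (if (!is.null(crop)) crop$plant_n else 0)
    # uptake is an internal soil-to-plant transfer; harvest export and
    # transplant seed N cross the system boundary
    n_resid <- (fert_in + manure_in + nirr + seed_n) -
      (vol + sum(den) + leach_bottom + harvest_n + (npool1 - npool0))

    rep_theta <- report_profile(theta, prof, rep_iv)
    no3_conc <- conc_from_n_mass(sum(no3[layer_60_90]),
                                 sum(theta_to_mm(theta[layer_60_90],
                                                 thick[layer_60_90])))
    rows[[di]] <- data.frame(
      date = today, crop = crop_name,
      rain = w$rain, irrigation = irr, runoff = runoff,
      infiltration = infiltration, soil_evap = ex$soil_evap,
      transp = ex$transp, et0 = et0,
      drainage = drain_plane, drainage_bottom = drain_bottom,
      fert = fert_in, manure = manure_in, nirr = nirr,
      hydrolysis = hyd, volatilization = vol, denitrification = sum(den),
      nitrification = sum(nit), nnet = sum(hum_net),
      manure_min = sum(man_min), uptake = uptake,
      leach = leach_plane, leach_bottom = leach_bottom,
      dm = if (!is.null(crop)) crop$dm else NA_real_,
      plant_n = if (!is.null(crop)) crop$plant_n else NA_real_,
      root_depth = if (!is.null(crop)) crop$root_depth else NA_real_,
      water_resid = water_resid, n_resid = n_resid,
      no3_conc_60_90 = no3_conc,
      mineral_n = sum((urea + nh4 + no3)[seq_len(plane_idx)]),
      stringsAsFactors = FALSE)
    nm <- paste0("theta_", rep_iv[, 1], "_", rep_iv[, 2])
    for (j in seq_along(nm)) rows[[di]][[nm[j]]] <- rep_theta[j]
  }

  daily <- do.call(rbind, rows)
  yields <- if (length(yields)) do.call(rbind, yields) else
    data.frame(date = as.Date(character(0)), crop = character(0),
               yield = numeric(0), dm = numeric(0), plant_n = numeric(0))
  seasons <- build_season_ledger(daily, yields, config)
  structure(list(daily = daily, seasons = seasons,
                 final_state = list(theta = theta, urea = urea, nh4 = nh4,
                                    no3 = no3, humus = humus,
                                    manure = manure),
                 config = config),
            class = "rotation_run")
}

# per-season and annual ledger rows from the daily record
build_season_ledger <- function(daily, yields, config) {
  cal <- config$calendar
  mgmt <- config$management
  out <- list()
  for (i in seq_len(nrow(cal))) {
    crop <- cal$crop[i]
    inwin <- daily$date >= cal$sowing[i] & daily$date <= cal$harvest[i]
    d <- daily[inwin, ]
    mg <- mgmt[mgmt$crop == crop, , drop = FALSE]
    y <- yields$yield[yields$crop == crop]
    y <- if (length(y)) sum(y) else 0
    wb <- season_water_balance(
      RF = sum(d$rain), I = sum(mg$amount[mg$type == "irrigation"]),
      ET = sum(d$soil_evap + d$transp), D = sum(d$drainage), Y = y,
      treatment = attr(mgmt, "treatment") %||% NA_character_,
      crop = crop, year = as.integer(format(cal$sowing[i], "%Y")))
    nb <- season_n_balance(
      Manu = sum(mg$amount[mg$type == "manure"]),
      Fert = sum(mg$amount[mg$type == "urea"]),
      Nirr = sum(d$nirr), Nnet = sum(d$nnet), Nup = sum(d$uptake),
      Ngas = sum(d$volatilization + d$denitrification),
      Nlea = sum(d$leach), Y = y,
      treatment = attr(mgmt, "treatment") %||% NA_character_,
      crop = crop, year = as.integer(format(cal$sowing[i], "%Y")))
    out[[i]] <- cbind(wb, nb[, c("Manu", "Fert", "Nirr", "Nnet", "Nup",
                                 "Ngas", "Nlea", "NUE", "Nbalance")])
  }
  seasons <- do.call(rbind, out)
  rbind(seasons, aggregate_annual(seasons))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate one treatment-year scenario end to end
#'
#' Convenience wrapper binding the synthetic-data module to the
#' simulator: generates the seeded weather (published per-season rainfall
#' totals, or custom windows), the treatment's management schedule, and
#' runs the rotation on the measured soil profile.
#'
#' @param water,nitrogen,year treatment labels (see
#'   [generate_management()]).
#' @param seed integer seed for weather and schedule generation.
#' @param rain_windows optional custom rainfall windows (defaults to the
#'   published seasonal totals via [reference_rain_windows()]).
#' @param params a [sim_params()].
#' @param crops crop parameter list.
#' @return a `rotation_run` (see [run_rotation()]).
#' @export
simulate_treatment <- function(water = "W1", nitrogen = "N1", year = 2000,
                               seed = 1L, rain_windows = NULL,
                               params = sim_params(),
                               crops = default_crop_params()) {
  if (is.null(rain_windows)) rain_windows <- reference_rain_windows(year)
  wcfg <- weather_gen_config(year = year, rain_windows = rain_windows,
                             background_annual = 60, seed = seed)
  weather <- generate_weather(wcfg)
  mgmt <- generate_management(water, nitrogen, year, seed = seed + 1L)
  cfg <- run_config(weather = weather, management = mgmt,
                    calendar = reference_calendar(year), params = params,
                    crops = crops)
  run_rotation(cfg)
}
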