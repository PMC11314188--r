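#' Temperature response of microbial N transformations
#'
#' Q10-style factor, 1 at the reference temperature and capped at 1 above
#' it, so the factor lies in \[0, 1\].
#'
#' @param temp soil/air temperature, deg C.
#' @param q10 rate change per 10 deg C (default 2).
#' @param ref reference temperature (default 20 deg C).
#' @param base temperature below which activity stops (default -10; set
#'   higher to impose a hard floor).
#' @return factor in \[0, 1\].
#' @export
temp_factor <- function(temp, q10 = 2, ref = 20, base = -10) {
  f <- q10^((temp - ref) / 10)
  f[temp <= base] <- 0
  pmin(pmax(f, 0), 1)
}

#' Moisture response of microbial N transformations
#'
#' Piecewise-linear: zero at (and below) wilting point, rising to 1 at
#' field capacity, then declining linearly toward `wet_factor` at
#' saturation (waterlogging slows aerobic turnover).
#'
#' @param theta volumetric water content.
#' @param layer one row of a [soil_profile()] (or a list with `theta_wp`,
#'   `theta_fc`, `theta_s`).
#' @param wet_factor value at saturation (default 0.5).
#' @return factor in \[0, 1\].
#' @export
moisture_factor <- function(theta, layer, wet_factor = 0.5) {
  wp <- layer$theta_wp; fc <- layer$theta_fc; ts <- layer$theta_s
  f <- ifelse(theta <= wp, 0,
       ifelse(theta <= fc, (theta - wp) / (fc - wp),
              1 - (1 - wet_factor) * (theta - fc) / (ts - fc)))
  pmin(pmax(f, 0), 1)
}

#' First-order mineralization of organic N pools
#'
#' DAISY-style two-pool turnover: each organic pool (added organic matter
#' such as manure, and native humus) releases N at
#' `pool * k * f_T(temp) * f_theta(theta)` per day; released N enters the
#' ammonium pool of the same layer.
#'
#' @param pool_n organic pool N mass, kg N ha^-1 (vectorized over pools or
#'   layers).
#' @param k first-order rate constant, d^-1.
#' @param temp temperature, deg C.
#' @param theta volumetric water content of the layer.
#' @param layer retention landmarks of the layer (see [moisture_factor()]).
#' @return mineralization flux, kg N ha^-1 d^-1 (never exceeding the pool).
#' @export
mineralize <- function(pool_n, k, temp, theta, layer) {
  flux <- pool_n * k * temp_factor(temp) * moisture_factor(theta, layer)
  pmin(flux, pool_n)
}

#' Urea hydrolysis
#'
#' First-order, temperature-modified conversion of surface-applied urea N
#' to ammonium (AMOVOL-style, fast: default half-life under two days at
#' the reference temperature).
#'
#' @param urea_n urea-N mass, kg N ha^-1.
#' @param temp temperature, deg C.
#' @param k rate constant, d^-1 (default 0.36).
#' @return hydrolysis flux, kg N ha^-1 d^-1.
#' @export
hydrolyze_urea <- function(urea_n, temp, k = 0.36) {
  if (any(urea_n < 0)) stop("urea_n must be >= 0")
  pmin(urea_n * k * temp_factor(temp), urea_n)
}

#' Ammonia volatilization from surface-applied N
#'
#' A daily fraction of the surface ammonium pool is lost as ammonia. The
#' fraction decays exponentially with days since application (the
#' emission-potential decay of field volatilization models), is suppressed
#' on days with irrigation or rain above a threshold (water moves the
#' ammonium into the soil), and is reduced for incorporated applications.
#'
#' @param surface_nh4 ammonium-N in the surface layer, kg N ha^-1.
#' @param days_since_application days since the last surface application.
#' @param water_today surface water input today (irrigation + rain), mm.
#' @param incorporated was the application incorporated into the soil?
#' @param base_frac fraction lost on the application day (default 0.15).
#' @param decay per-day decay rate of the fraction (default 0.35 d^-1).
#' @param water_threshold mm of water that triggers suppression
#'   (default 5).
#' @param suppression multiplier applied on wet days (default 0.1).
#' @param incorporation_factor multiplier for incorporated applications
#'   (default 0.3).
#' @return volatilization flux, kg N ha^-1 d^-1.
#' @export
volatilize <- function(surface_nh4, days_since_application,
                       water_today = 0, incorporated = FALSE,
                       base_frac = 0.15, decay = 0.35,
                       water_threshold = 5, suppression = 0.1,
                       incorporation_factor = 0.3) {
  if (any(surface_nh4 < 0)) stop("surface_nh4 must be >= 0")
  frac <- base_frac * exp(-decay * days_since_application)
  if (water_today >= water_threshold) frac <- frac * suppression
  if (incorporated) frac <- frac * incorporation_factor
  pmin(frac * surface_nh4, surface_nh4)
}

#' Nitrification
#'
#' First-order NH4 -> NO3 oxidation with temperature and moisture factors.
#'
#' @param nh4_n ammonium-N, kg N ha^-1.
#' @param temp temperature, deg C.
#' @param theta volumetric water content.
#' @param layer retention landmarks (see [moisture_factor()]).
#' @param k rate constant, d^-1 (default 0.2).
#' @return nitrification flux, kg N ha^-1 d^-1.
#' @export
nitrify <- function(nh4_n, temp, theta, layer, k = 0.2) {
  pmin(nh4_n * k * temp_factor(temp) * moisture_factor(theta, layer), nh4_n)
}

#' Denitrification
#'
#' Zero below a water-filled pore space (WFPS = theta/theta_s) threshold;
#' above it, first-order in nitrate scaled by a power of the excess WFPS
#' (reaching 1 at saturation) and the temperature factor. Captures the
#' observation that aerated soils under reduced irrigation inhibit
#' denitrifier activity.
#'
#' @param no3_n nitrate-N, kg N ha^-1.
#' @param theta volumetric water content.
#' @param layer retention landmarks with `theta_s`.
#' @param temp temperature, deg C.
#' @param k rate constant at saturation, d^-1 (default 0.1).
#' @param wfps_threshold onset WFPS (default 0.6).
#' @param exponent power of the excess-WFPS scaling (default 2).
#' @return denitrification flux, kg N ha^-1 d^-1.
#' @export
denitrify <- function(no3_n, theta, layer, temp, k = 0.1,
                      wfps_threshold = 0.6, exponent = 2) {
  wfps <- theta / layer$theta_s
  scale <- ifelse(wfps <= wfps_threshold, 0,
                  ((wfps - wfps_threshold) / (1 - wfps_threshold))^exponent)
  pmin(no3_n * k * scale * temp_factor(temp), no3_n)
}

#' Mixing-cell nitrate advection
#'
#' Moves nitrate with the drainage cascade: each layer's outflow carries
#' the layer's fully mixed resident concentration, i.e. (nitrate mass +
#' mass arriving from above) / (water volume + inflow). Mass is conserved:
#' final pools plus leached mass equal initial pools plus the mass
#' entering from the surface.
#'
#' @param no3 per-layer nitrate-N, kg N ha^-1.
#' @param water_pre per-layer water volume before today's drainage, mm
#'   (i.e. content at the start of the redistribution step).
#' @param inflow_top water infiltrating the surface, mm.
#' @param flux_down per-layer water flux across each layer bottom, mm
#'   (from [redistribute()]).
#' @param n_in_top nitrate mass entering with the surface inflow,
#'   kg N ha^-1 (default 0).
#' @return list: `no3` (updated), `flux_mass` (kg N ha^-1 crossing each
#'   layer bottom), `leached` (mass leaving the deepest layer).
#' @export
advect_nitrate <- function(no3, water_pre, inflow_top, flux_down,
                           n_in_top = 0) {
  if (any(water_pre < 0)) stop("negative layer water volume")
  n <- length(no3)
  stopifnot(length(water_pre) == n, length(flux_down) == n)
  w_in <- c(inflow_top, flux_down[-n])
  mass_in <- n_in_top
  flux_mass <- numeric(n)
  for (i in seq_len(n)) {
    total_mass <- no3[i] + mass_in
    total_water <- water_pre[i] + w_in[i]
    out <- if (flux_down[i] > 0 && total_water > 0) {
      total_mass * flux_down[i] / total_water
    } else 0
    no3[i] <- total_mass - out
    flux_mass[i] <- out
    mass_in <- out
  }
  list(no3 = no3, flux_mass = flux_mass, leached = flux_mass[n])
}

#' Crop nitrogen uptake from the rooted profile
#'
#' Total uptake is the minimum of demand and the extractable mineral N of
#' the rooted layers (a configured fraction of ammonium + nitrate);
#' withdrawal is distributed across layers in proportion to per-layer
#' availability, and within a layer in proportion to the two mineral
#' pools.
#'
#' @param demand crop N demand, kg N ha^-1 d^-1.
#' @param nh4,no3 per-layer mineral N pools, kg N ha^-1.
#' @param root_frac per-layer root fraction (see rooting in
#'   [extract_et()]); uptake only where `root_frac > 0`.
#' @param extract_frac extractable fraction of rooted mineral N per day
#'   (default 0.1).
#' @return list: `uptake_by_layer`, `total`, and the updated `nh4`, `no3`.
#' @export
plant_uptake_n <- function(demand, nh4, no3, root_frac,
                           extract_frac = 0.1) {
  if (demand < 0) stop("demand must be >= 0")
  avail <- extract_frac * (nh4 + no3) * (root_frac > 0)
  total <- min(demand, sum(avail))
  uptake <- if (total > 0) total * avail / sum(avail) else numeric(length(nh4))
  pool <- nh4 + no3
  share_nh4 <- ifelse(pool > 0, nh4 / pool, 0)
  nh4 <- nh4 - uptake * share_nh4
  no3 <- no3 - uptake * (1 - share_nh4)
  list(uptake_by_layer = uptake, total = total, nh4 = nh4, no3 = no3)
}
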