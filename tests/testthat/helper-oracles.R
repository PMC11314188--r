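# Independent brute-force / closed-form oracles used by the unit and
# acceptance tests. These are deliberately separate, scalar, step-by-step
# transcriptions -- they never call the package's vectorized code paths.

# FAO-56 daily grass-reference ET, transcribed equation by equation
fao56_oracle <- function(tmax, tmin, rh, u2, rs, doy, lat, alt) {
  e0 <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))
  tmean <- (tmax + tmin) / 2
  slope <- 4098 * e0(tmean) / (tmean + 237.3)^2
  press <- 101.3 * ((293 - 0.0065 * alt) / 293)^5.26
  gam <- 0.000665 * press
  es <- (e0(tmax) + e0(tmin)) / 2
  ea <- rh / 100 * es
  phi <- lat * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi / 365 * doy)
  dec <- 0.409 * sin(2 * pi / 365 * doy - 1.39)
  ws <- acos(min(max(-tan(phi) * tan(dec), -1), 1))
  ra <- 24 * 60 / pi * 0.0820 * dr *
    (ws * sin(phi) * sin(dec) + cos(phi) * cos(dec) * sin(ws))
  rso <- (0.75 + 2e-5 * alt) * ra
  rns <- 0.77 * rs
  ratio <- min(rs / rso, 1)
  rnl <- 4.903e-9 * ((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2 *
    (0.34 - 0.14 * sqrt(ea)) * (max(1.35 * ratio - 0.35, 0))
  rn <- rns - rnl
  et <- (0.408 * slope * rn + gam * 900 / (tmean + 273) * u2 * (es - ea)) /
    (slope + gam * (1 + 0.34 * u2))
  max(et, 0)
}

# explicit per-layer fill-and-spill bookkeeping for the tipping bucket
tipping_oracle <- function(theta, infil, profile, drain_frac) {
  nl <- nrow(profile)
  res_theta <- numeric(nl)
  flux <- numeric(nl)
  carry <- infil
  for (i in 1:nl) {
    th <- profile$thickness[i]
    water <- theta[i] * th * 10 + carry
    carry <- 0
    sat <- profile$theta_s[i] * th * 10
    fc <- profile$theta_fc[i] * th * 10
    if (water > sat) { carry <- water - sat; water <- sat }
    if (water > fc) {
      d <- drain_frac * (water - fc)
      water <- water - d
      carry <- carry + d
    }
    flux[i] <- carry
    res_theta[i] <- water / (th * 10)
  }
  list(theta = res_theta, flux_down = flux, drainage = flux[nl])
}

# sequential mixing-cell ledger for nitrate advection
mixing_oracle <- function(no3, water_pre, inflow_top, flux_down,
                          n_in_top = 0) {
  nl <- length(no3)
  w_in <- c(inflow_top, flux_down[-nl])
  m_in <- n_in_top
  out_no3 <- numeric(nl)
  for (i in 1:nl) {
    mass <- no3[i] + m_in
    water <- water_pre[i] + w_in[i]
    m_out <- 0
    if (flux_down[i] > 0 && water > 0) m_out <- mass * flux_down[i] / water
    out_no3[i] <- mass - m_out
    m_in <- m_out
  }
  list(no3 = out_no3, leached = m_in)
}

# epsilon-increment simulation of capped proportional allocation
alloc_oracle <- function(demand, weights, caps, eps = 1e-4) {
  taken <- numeric(length(weights))
  remaining <- min(demand, sum(caps[weights > 0]))
  while (remaining > 1e-9) {
    open <- weights > 0 & taken < caps - 1e-12
    if (!any(open)) break
    step <- min(eps, remaining)
    add <- step * weights * open / sum(weights[open])
    add <- pmin(add, caps - taken)
    taken <- taken + add
    remaining <- remaining - sum(add)
  }
  taken
}

# small three-layer toy profile used across tests
toy_profile <- function() {
  soil_profile(top = c(0, 20, 50), bottom = c(20, 50, 90),
               bulk_density = c(1.3, 1.45, 1.5),
               theta_s = c(0.48, 0.45, 0.44),
               theta_fc = c(0.32, 0.34, 0.33),
               theta_wp = c(0.13, 0.15, 0.14))
}

# compact weather table for short simulator scenarios
make_weather <- function(dates, rain = 0, tmax = 26, tmin = 16, rh = 60,
                         wind = 2, rad = 18) {
  n <- length(dates)
  data.frame(date = dates, tmax = rep_len(tmax, n),
             tmin = rep_len(tmin, n), rh_mean = rep_len(rh, n),
             wind2 = rep_len(wind, n), solar_rad = rep_len(rad, n),
             rain = rep_len(rain, n), stringsAsFactors = FALSE)
}
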