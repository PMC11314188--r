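#' Validate a daily weather table
#'
#' A weather table has one row per day with columns `date` (Date or
#' ISO-8601 string), `tmax`, `tmin` (deg C), `rh_mean` (% relative
#' humidity) or `ea` (actual vapour pressure, kPa), `wind2` (m s^-1 at 2 m),
#' `solar_rad` (MJ m^-2 d^-1) and `rain` (mm d^-1). Missing values are
#' forbidden.
#'
#' @param weather data.frame to validate.
#' @return The validated data.frame with `date` coerced to `Date`,
#'   invisibly usable downstream.
#' @export
validate_weather <- function(weather) {
  req <- c("date", "tmax", "tmin", "wind2", "solar_rad", "rain")
  miss <- setdiff(req, names(weather))
  if (length(miss) > 0)
    stop("weather table is missing columns: ", paste(miss, collapse = ", "))
  if (!("rh_mean" %in% names(weather)) && !("ea" %in% names(weather)))
    stop("weather table must contain humidity as 'rh_mean' (%) or 'ea' (kPa)")
  weather$date <- as.Date(weather$date)
  num <- intersect(c("tmax", "tmin", "rh_mean", "ea", "wind2", "solar_rad", "rain"),
                   names(weather))
  for (cn in num) {
    if (anyNA(weather[[cn]]))
      stop("weather column '", cn, "' contains missing values")
  }
  if (any(weather$tmax < weather$tmin))
    stop("tmax < tmin on ", sum(weather$tmax < weather$tmin), " day(s)")
  if (any(weather$rain < 0)) stop("negative rainfall")
  if (any(weather$solar_rad < 0)) stop("negative solar radiation")
  if ("rh_mean" %in% names(weather) &&
      any(weather$rh_mean < 0 | weather$rh_mean > 100))
    stop("rh_mean outside [0, 100]")
  if (any(weather$wind2 < 0)) stop("negative wind speed")
  weather
}

# saturation vapour pressure (kPa) at air temperature T (deg C)
svp <- function(temp) 0.6108 * exp(17.27 * temp / (temp + 237.3))

#' Extraterrestrial radiation
#'
#' Daily extraterrestrial radiation Ra (MJ m^-2 d^-1) for a given day of
#' year and latitude, from solar geometry (solar constant 0.0820
#' MJ m^-2 min^-1, inverse relative Earth-Sun distance and solar
#' declination as smooth functions of the day of year).
#'
#' @param doy day of year (1--366).
#' @param latitude decimal degrees, |latitude| <= 90.
#' @return Ra in MJ m^-2 d^-1.
#' @export
extraterrestrial_radiation <- function(doy, latitude) {
  if (any(abs(latitude) > 90)) stop("|latitude| must be <= 90")
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  x <- pmin(pmax(-tan(phi) * tan(delta), -1), 1)
  ws <- acos(x)
  (24 * 60 / pi) * 0.0820 * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
}

#' FAO-56 Penman-Monteith reference evapotranspiration (daily)
#'
#' Grass-reference evapotranspiration ET0 from daily weather, following the
#' FAO-56 daily formulation: psychrometric constant from site altitude,
#' saturation vapour pressure averaged over the daily extremes, actual
#' vapour pressure from mean relative humidity (or given directly), net
#' radiation from measured solar radiation with albedo 0.23 and the
#' clear-sky/cloudiness longwave correction, soil heat flux zero at the
#' daily step.
#'
#' ET0 = (0.408 Delta (Rn - G) + gamma 900/(T+273) u2 (es - ea)) /
#'       (Delta + gamma (1 + 0.34 u2)), clamped below at zero.
#'
#' @param tmax,tmin daily maximum / minimum air temperature, deg C.
#' @param wind2 wind speed at 2 m, m s^-1.
#' @param solar_rad incoming solar radiation, MJ m^-2 d^-1.
#' @param doy day of year (for extraterrestrial radiation).
#' @param latitude,altitude site coordinates (decimal degrees, m).
#' @param rh_mean mean relative humidity, %. Either `rh_mean` or `ea` must
#'   be given.
#' @param ea actual vapour pressure, kPa (overrides `rh_mean`).
#' @param rn optional net radiation (MJ m^-2 d^-1) overriding the internal
#'   radiation sub-model (useful for controlled tests and coupling).
#' @return reference evapotranspiration, mm d^-1 (vectorized).
#' @examples
#' reference_et0(30, 20, wind2 = 2, solar_rad = 22, doy = 196,
#'               latitude = 39.9, altitude = 50, rh_mean = 60)
#' @export
reference_et0 <- function(tmax, tmin, wind2, solar_rad, doy, latitude,
                          altitude, rh_mean = NULL, ea = NULL, rn = NULL) {
  if (is.null(rh_mean) && is.null(ea))
    stop("humidity input required: give 'rh_mean' (%) or 'ea' (kPa)")
  if (is.null(solar_rad) || anyNA(solar_rad))
    stop("solar radiation input required")
  if (any(tmax < tmin)) stop("tmax < tmin")
  tmean <- (tmax + tmin) / 2
  es <- (svp(tmax) + svp(tmin)) / 2
  if (is.null(ea)) ea <- rh_mean / 100 * es
  delta <- 4098 * svp(tmean) / (tmean + 237.3)^2
  pressure <- 101.3 * ((293 - 0.0065 * altitude) / 293)^5.26
  gamma <- 0.000665 * pressure
  if (is.null(rn)) {
    ra <- extraterrestrial_radiation(doy, latitude)
    rso <- (0.75 + 2e-5 * altitude) * ra
    rns <- (1 - 0.23) * solar_rad
    rel <- ifelse(rso > 0, pmin(solar_rad / rso, 1), 0)
    cloud <- pmax(1.35 * rel - 0.35, 0)
    sigma <- 4.903e-9
    rnl <- sigma * ((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2 *
      (0.34 - 0.14 * sqrt(pmax(ea, 0))) * cloud
    rn <- rns - rnl
  }
  num <- 0.408 * delta * rn + gamma * 900 / (tmean + 273) * wind2 * (es - ea)
  et0 <- num / (delta + gamma * (1 + 0.34 * wind2))
  pmax(et0, 0)
}

#' Four-stage FAO-style crop coefficient curve
#'
#' @param kc_ini,kc_mid,kc_end plateau crop coefficients (dimensionless).
#' @param stages length-4 numeric: fractions of the season spent in the
#'   initial, development, mid and late stages; must be positive and sum
#'   to 1.
#' @return object of class `kc_curve`.
#' @export
kc_curve <- function(kc_ini = 0.7, kc_mid = 1.05, kc_end = 0.95,
                     stages = c(0.2, 0.3, 0.3, 0.2)) {
  if (any(c(kc_ini, kc_mid, kc_end) < 0)) stop("kc values must be >= 0")
  if (length(stages) != 4 || any(stages <= 0) ||
      abs(sum(stages) - 1) > 1e-8)
    stop("stages must be 4 positive fractions summing to 1")
  structure(list(kc_ini = kc_ini, kc_mid = kc_mid, kc_end = kc_end,
                 stages = stages), class = "kc_curve")
}

#' Crop coefficient at a point in the season
#'
#' Piecewise-linear staging: constant `kc_ini` over the initial stage, a
#' linear ramp to `kc_mid` over development, a `kc_mid` plateau, and a
#' linear ramp to `kc_end` over the late stage.
#'
#' @param day_of_season fraction of the season elapsed, in \[0, 1\]
#'   (vectorized).
#' @param curve a [kc_curve()].
#' @return crop coefficient (dimensionless).
#' @export
crop_kc <- function(day_of_season, curve) {
  stopifnot(inherits(curve, "kc_curve"))
  if (any(day_of_season < 0 | day_of_season > 1))
    stop("day_of_season must be in [0, 1]")
  b <- cumsum(curve$stages)  # stage boundaries
  vapply(day_of_season, function(f) {
    if (f <= b[1]) {
      curve$kc_ini
    } else if (f <= b[2]) {
      w <- (f - b[1]) / curve$stages[2]
      curve$kc_ini + w * (curve$kc_mid - curve$kc_ini)
    } else if (f <= b[3]) {
      curve$kc_mid
    } else {
      w <- (f - b[3]) / curve$stages[4]
      curve$kc_mid + w * (curve$kc_end - curve$kc_mid)
    }
  }, numeric(1))
}

#' Crop evapotranspiration demand
#'
#' @param et0 reference evapotranspiration, mm d^-1.
#' @param kc crop coefficient.
#' @return potential crop ET, mm d^-1.
#' @export
crop_et_demand <- function(et0, kc) {
  if (any(et0 < 0) || any(kc < 0)) stop("et0 and kc must be >= 0")
  et0 * kc
}
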