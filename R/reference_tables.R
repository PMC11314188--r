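#' Published seasonal water and nitrogen balances, Dongbeiwang rotation experiment
#'
#' Seasonal and annual water and nitrogen ledgers reported for the two-year
#' (2000--2001) open-field cauliflower--amaranth--spinach rotation experiment
#' at Dongbeiwang, Beijing, under six treatments: two irrigation regimes
#' (W1 conventional furrow, W2 optimized micro-sprinkler) crossed with three
#' fertilizer regimes (N1 farmer practice, N2 Expert-N optimal rate, N3
#' reduced rate). Component columns are in mm (water), kg ha^-1 (fresh
#' yield) and kg N ha^-1 (nitrogen); the derived columns WUE, IWUE
#' (kg m^-3), Wbalance (mm), NUE (kg kg^-1) and Nbalance (kg N ha^-1) are
#' reproduced as printed so that the accounting identities can be checked
#' against them.
#'
#' @return A data.frame with one row per treatment x year x season plus the
#'   annual "total" rows. Columns: `year`, `treatment`, `crop` (with
#'   `"total"` for the annual row), water side `RF`, `I`, `ET`, `D`, `Y`,
#'   `WUE`, `IWUE`, `Wbalance`, nitrogen side `Manu`, `Fert`, `Nirr`,
#'   `Nnet`, `Nup`, `Ngas`, `Nlea`, `NUE`, `Nbalance`.
#' @seealso [season_water_balance()], [season_n_balance()],
#'   [aggregate_annual()]
#' @export
reference_balances <- function() {
  # columns: year treatment crop RF I ET D Y WUE IWUE Wb | Manu Fert Nirr Nnet Nup Ngas Nlea NUE Nb
  rows <- rbind(
    list(2000, "W1N1", "cauliflower", 45.1, 294.1, 327.8, 20.4, 23400, 7.1, 8.0, -9.0,
         75, 450.0, 11.5, 25.0, 162.5, 141.3, 7.8, 75.1, 249.9),
    list(2000, "W1N1", "amaranth", 151.0, 85.5, 104.0, 111.5, 14300, 13.8, 16.7, 21.0,
         0, 100.0, 3.3, 23.5, 46.9, 24.9, 129.2, 71.1, -74.2),
    list(2000, "W1N1", "spinach", 65.6, 128.2, 130.2, 34.6, 34800, 26.7, 27.1, 29.0,
         0, 309.0, 5.0, 32.2, 120.0, 46.7, 58.7, 154.4, 120.8),
    list(2000, "W1N1", "total", 261.7, 507.8, 562.0, 166.5, 72500, 12.9, 14.3, 41.0,
         75, 859.0, 19.8, 80.7, 329.4, 212.9, 195.7, 98.2, 296.5),
    list(2000, "W1N2", "cauliflower", 45.1, 294.1, 323.1, 20.7, 19600, 6.1, 6.7, -4.6,
         75, 165.9, 11.5, 24.5, 158.6, 65.8, 6.9, 84.7, 45.6),
    list(2000, "W1N2", "amaranth", 151.0, 85.5, 99.4, 108.7, 13700, 13.8, 16.0, 28.4,
         0, 26.0, 3.3, 21.6, 44.1, 12.7, 79.0, 100.9, -84.9),
    list(2000, "W1N2", "spinach", 65.6, 128.2, 128.5, 37.1, 32900, 25.6, 25.7, 28.2,
         0, 81.4, 5.0, 32.5, 113.7, 16.1, 29.4, 206.7, -40.3),
    list(2000, "W1N2", "total", 261.7, 507.8, 551.0, 166.5, 66200, 12.0, 13.0, 52.0,
         75, 273.3, 19.8, 78.6, 316.4, 94.6, 115.3, 125.8, -79.6),
    list(2000, "W1N3", "cauliflower", 45.1, 294.1, 319.2, 19.5, 20500, 6.4, 7.0, 0.5,
         75, 189.8, 11.5, 24.6, 163.6, 79.2, 6.3, 82.3, 51.8),
    list(2000, "W1N3", "amaranth", 151.0, 85.5, 95.8, 108.6, 10800, 11.3, 12.6, 32.1,
         0, 26.2, 3.3, 21.4, 33.2, 14.6, 88.9, 79.0, -85.8),
    list(2000, "W1N3", "spinach", 65.6, 128.2, 127.7, 40.2, 36400, 28.5, 28.4, 25.9,
         0, 72.0, 5.0, 32.0, 117.7, 16.0, 32.4, 219.1, -57.1),
    list(2000, "W1N3", "total", 261.7, 507.8, 542.7, 168.3, 67700, 12.5, 13.3, 58.5,
         75, 288.0, 19.8, 78.0, 314.5, 109.8, 127.6, 122.7, -91.1),
    list(2000, "W2N1", "cauliflower", 45.1, 208.5, 281.2, 2.9, 21400, 7.6, 10.3, -30.5,
         75, 450.0, 8.1, 24.0, 159.8, 116.4, 0.8, 77.3, 280.1),
    list(2000, "W2N1", "amaranth", 151.0, 68.3, 100.9, 35.8, 13100, 13.0, 19.2, 82.6,
         0, 100.0, 2.7, 28.7, 44.9, 20.1, 22.0, 150.6, 44.4),
    list(2000, "W2N1", "spinach", 65.6, 89.3, 114.8, 4.0, 33100, 28.8, 37.1, 36.1,
         0, 309.0, 3.5, 32.7, 122.9, 38.5, 6.6, 197.0, 177.2),
    list(2000, "W2N1", "total", 261.7, 366.1, 496.9, 42.7, 67600, 13.6, 18.5, 88.2,
         75, 859.0, 14.3, 85.4, 327.6, 175.0, 29.4, 127.1, 501.7),
    list(2000, "W2N2", "cauliflower", 45.1, 208.5, 273.3, 1.2, 19700, 7.2, 9.4, -20.9,
         75, 83.6, 8.1, 24.1, 165.3, 32.0, 0.3, 99.7, -6.8),
    list(2000, "W2N2", "amaranth", 151.0, 68.3, 100.4, 38.0, 15200, 15.1, 22.3, 80.9,
         0, 25.7, 2.7, 28.3, 49.6, 15.2, 15.5, 189.3, -23.6),
    list(2000, "W2N2", "spinach", 65.6, 89.3, 115.3, 4.1, 32500, 28.2, 36.4, 35.5,
         0, 83.9, 3.5, 34.1, 118.3, 12.2, 3.3, 242.9, -12.3),
    list(2000, "W2N2", "total", 261.7, 366.1, 489.0, 43.3, 67400, 13.8, 18.4, 95.5,
         75, 193.2, 14.3, 86.5, 333.2, 59.4, 19.1, 163.7, -42.7),
    list(2000, "W2N3", "cauliflower", 45.1, 208.5, 284.8, 0.1, 18100, 6.4, 8.9, -31.3,
         75, 101.7, 8.1, 23.8, 164.7, 36.4, 0.0, 90.0, 7.5),
    list(2000, "W2N3", "amaranth", 151.0, 68.3, 101.1, 30.7, 16500, 16.3, 24.2, 87.5,
         0, 31.5, 2.7, 28.2, 57.1, 9.0, 8.2, 222.1, -11.9),
    list(2000, "W2N3", "spinach", 65.6, 89.3, 115.4, 6.8, 33900, 29.4, 38.0, 32.7,
         0, 55.4, 3.5, 32.7, 116.3, 8.1, 4.0, 264.0, -36.8),
    list(2000, "W2N3", "total", 261.7, 366.1, 501.3, 37.6, 68500, 13.7, 18.7, 88.9,
         75, 188.6, 14.3, 84.7, 338.1, 53.5, 12.2, 169.6, -41.2),
    list(2001, "W1N1", "cauliflower", 21.9, 290.7, 310.5, 30.5, 19200, 6.2, 6.6, -28.4,
         120, 450.0, 11.3, 32.8, 156.8, 113.3, 26.6, 64.7, 317.4),
    list(2001, "W1N1", "amaranth", 69.1, 107.4, 127.7, 0.0, 22500, 17.6, 20.9, 48.8,
         0, 100.0, 4.2, 33.9, 61.6, 16.0, 0.0, 289.9, 60.5),
    list(2001, "W1N1", "spinach", 52.7, 123.4, 121.3, 24.4, 30100, 24.8, 24.4, 30.4,
         0, 309.0, 4.8, 36.0, 104.2, 49.9, 30.4, 163.1, 165.3),
    list(2001, "W1N1", "total", 143.7, 521.5, 559.5, 54.9, 71800, 12.8, 13.8, 50.8,
         120, 859.0, 20.3, 102.7, 322.6, 179.2, 57.0, 128.5, 543.2),
    list(2001, "W1N2", "cauliflower", 21.9, 290.7, 304.3, 31.0, 16200, 5.3, 5.6, -22.7,
         120, 109.5, 11.3, 33.5, 135.8, 44.0, 13.8, 83.7, 80.7),
    list(2001, "W1N2", "amaranth", 69.1, 107.4, 129.6, 0.0, 18600, 14.4, 17.3, 46.9,
         0, 0.0, 4.2, 34.6, 55.6, 7.0, 0.0, 297.1, -23.8),
    list(2001, "W1N2", "spinach", 52.7, 123.4, 118.0, 16.8, 30200, 25.6, 24.5, 41.3,
         0, 126.3, 4.8, 35.0, 102.9, 22.9, 8.4, 225.0, 31.9),
    list(2001, "W1N2", "total", 143.7, 521.5, 551.9, 47.8, 65000, 11.8, 12.5, 65.5,
         120, 235.8, 20.3, 103.1, 294.3, 73.9, 22.2, 166.5, 88.8),
    list(2001, "W1N3", "cauliflower", 21.9, 290.7, 297.1, 29.5, 14500, 4.9, 5.0, -14.0,
         120, 71.6, 11.3, 29.4, 122.6, 34.4, 8.2, 87.8, 67.1),
    list(2001, "W1N3", "amaranth", 69.1, 107.4, 128.1, 0.0, 18300, 14.3, 17.0, 48.4,
         0, 0.0, 4.2, 34.0, 53.0, 8.5, 0.0, 297.6, -23.3),
    list(2001, "W1N3", "spinach", 52.7, 123.4, 118.0, 26.9, 31400, 26.6, 15.4, 31.2,
         0, 99.6, 4.8, 35.4, 102.5, 19.3, 15.2, 229.2, 2.8),
    list(2001, "W1N3", "total", 143.7, 521.5, 543.2, 56.4, 64200, 11.8, 12.3, 65.6,
         120, 171.2, 20.3, 98.8, 278.1, 62.2, 23.4, 176.5, 46.6),
    list(2001, "W2N1", "cauliflower", 21.9, 207.6, 258.0, 0.9, 19300, 7.5, 9.3, -29.4,
         120, 450.0, 8.1, 30.5, 156.6, 81.9, 1.1, 80.6, 369.0),
    list(2001, "W2N1", "amaranth", 69.1, 74.0, 112.7, 0.0, 22400, 19.9, 30.3, 30.4,
         0, 100.0, 2.9, 33.7, 62.4, 19.5, 0.0, 273.5, 54.7),
    list(2001, "W2N1", "spinach", 52.7, 84.6, 117.3, 0.4, 31600, 26.9, 37.4, 19.6,
         0, 309.0, 3.3, 34.0, 112.9, 32.1, 0.6, 217.0, 200.7),
    list(2001, "W2N1", "total", 143.7, 366.2, 488.0, 1.3, 73300, 15.0, 20.0, 20.6,
         120, 859.0, 14.3, 98.2, 331.9, 133.5, 1.7, 156.9, 624.4),
    list(2001, "W2N2", "cauliflower", 21.9, 207.6, 257.6, 0.2, 19000, 7.4, 9.2, -28.3,
         120, 62.0, 8.1, 30.5, 141.1, 22.2, 0.0, 116.4, 57.3),
    list(2001, "W2N2", "amaranth", 69.1, 74.0, 114.0, 0.0, 21200, 18.6, 28.6, 29.1,
         0, 0.0, 2.9, 33.2, 64.4, 3.2, 0.0, 313.6, -31.5),
    list(2001, "W2N2", "spinach", 52.7, 84.6, 118.9, 1.7, 25900, 21.8, 30.6, 16.7,
         0, 98.9, 3.3, 35.0, 108.1, 12.1, 0.5, 214.6, 16.5),
    list(2001, "W2N2", "total", 143.7, 366.2, 490.5, 1.9, 66100, 13.5, 18.1, 17.5,
         120, 160.9, 14.3, 98.7, 313.6, 37.5, 0.5, 188.0, 42.3),
    list(2001, "W2N3", "cauliflower", 21.9, 207.6, 254.9, 0.6, 18600, 7.3, 9.0, -26.0,
         120, 68.5, 8.1, 29.4, 139.8, 25.7, 0.2, 112.3, 60.3),
    list(2001, "W2N3", "amaranth", 69.1, 74.0, 113.7, 0.0, 15200, 13.4, 20.5, 29.4,
         0, 0.0, 2.9, 33.1, 51.8, 4.5, 0.0, 270.0, -20.3),
    list(2001, "W2N3", "spinach", 52.7, 84.6, 117.6, 9.5, 30400, 25.9, 35.9, 10.2,
         0, 71.8, 3.3, 34.5, 112.3, 10.6, 3.5, 240.5, -16.8),
    list(2001, "W2N3", "total", 143.7, 366.2, 486.2, 10.1, 64200, 13.2, 17.5, 13.6,
         120, 140.3, 14.3, 97.0, 303.9, 40.8, 3.7, 184.3, 23.2)
  )
  out <- data.frame(
    year = unlist(rows[, 1]),
    treatment = unlist(rows[, 2]),
    crop = unlist(rows[, 3]),
    RF = unlist(rows[, 4]), I = unlist(rows[, 5]), ET = unlist(rows[, 6]),
    D = unlist(rows[, 7]), Y = unlist(rows[, 8]), WUE = unlist(rows[, 9]),
    IWUE = unlist(rows[, 10]), Wbalance = unlist(rows[, 11]),
    Manu = unlist(rows[, 12]), Fert = unlist(rows[, 13]),
    Nirr = unlist(rows[, 14]), Nnet = unlist(rows[, 15]),
    Nup = unlist(rows[, 16]), Ngas = unlist(rows[, 17]),
    Nlea = unlist(rows[, 18]), NUE = unlist(rows[, 19]),
    Nbalance = unlist(rows[, 20]),
    stringsAsFactors = FALSE
  )
  out
}

#' Measured soil profile of the experimental site
#'
#' Layered physical properties of the Calcaric Cambisol at the Dongbeiwang
#' site, measured on a 120 cm profile pit in 30 cm increments: bulk density
#' and the water retention landmarks (saturation, field capacity at -33 kPa,
#' wilting point at -1500 kPa).
#'
#' @param subdivide_top If `TRUE` (default) the 0--30 cm layer is split into
#'   0--15 and 15--30 cm simulation layers so that the surface reporting
#'   depths used for TDR comparison are native layers.
#' @return A `soil_profile` data.frame (see [soil_profile()]).
#' @export
reference_soil_profile <- function(subdivide_top = TRUE) {
  top <- c(0, 30, 60, 90)
  bottom <- c(30, 60, 90, 120)
  bd <- c(1.33, 1.52, 1.43, 1.62)
  fc <- c(0.33, 0.35, 0.35, 0.33)
  wp <- c(0.14, 0.15, 0.14, 0.14)
  ts <- c(0.50, 0.43, 0.44, 0.43)
  if (subdivide_top) {
    top <- c(0, 15, top[-1]); bottom <- c(15, 30, bottom[-1])
    bd <- c(bd[1], bd); fc <- c(fc[1], fc); wp <- c(wp[1], wp); ts <- c(ts[1], ts)
  }
  soil_profile(top = top, bottom = bottom, bulk_density = bd,
               theta_s = ts, theta_fc = fc, theta_wp = wp)
}

#' Rotation calendar of the experiment
#'
#' Sowing and harvest dates of the three consecutive vegetables
#' (cauliflower, amaranth, spinach) in 2000 and 2001.
#'
#' @param year 2000 or 2001.
#' @return data.frame with columns `crop`, `sowing`, `harvest` (Date).
#' @export
reference_calendar <- function(year) {
  year <- match.arg(as.character(year), c("2000", "2001"))
  if (year == "2000") {
    data.frame(
      crop = c("cauliflower", "amaranth", "spinach"),
      sowing = as.Date(c("2000-04-03", "2000-07-01", "2000-09-04")),
      harvest = as.Date(c("2000-06-06", "2000-07-30", "2000-10-14")),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      crop = c("cauliflower", "amaranth", "spinach"),
      sowing = as.Date(c("2001-04-13", "2001-06-24", "2001-09-06")),
      harvest = as.Date(c("2001-06-06", "2001-07-22", "2001-10-29")),
      stringsAsFactors = FALSE
    )
  }
}

#' Reported validation statistics for soil water and nitrate
#'
#' RMSE, Nash-Sutcliffe efficiency E, and Willmott agreement index d of the
#' simulated versus measured soil water content per reporting depth and of
#' nitrate concentration at the 60--90 cm layer, pooled over the five
#' validation treatments.
#'
#' @return data.frame with `variable`, `layer`, `rmse`, `nse`, `agreement`.
#' @export
reference_eval_stats <- function() {
  data.frame(
    variable = c(rep("soil_water", 5), "no3_concentration"),
    layer = c("0-15", "15-30", "30-60", "60-90", "90-120", "60-90"),
    rmse = c(0.04, 0.02, 0.01, 0.01, 0.01, 13.41),
    nse = c(0.38, 0.47, 0.46, 0.86, 0.92, 0.87),
    agreement = c(0.83, 0.87, 0.88, 0.97, 0.98, 0.97),
    stringsAsFactors = FALSE
  )
}
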