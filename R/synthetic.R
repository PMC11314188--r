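#' Weather generator configuration
#'
#' Configuration for a Beijing-like temperate monsoon daily weather
#' series: annual temperature sinusoid (default mean 11.5 deg C, the
#' long-term site mean), radiation sinusoid, humidity and wind baselines
#' with jitter, and rainfall prescribed as exact totals over date windows
#' (rain outside configured windows is controlled by `background_annual`,
#' allocated over the remaining days of the year).
#'
#' @param year calendar year to generate.
#' @param rain_windows data.frame with columns `start`, `end` (Date) and
#'   `total` (mm): each window's rainfall sums exactly to `total`.
#' @param background_annual rainfall outside the windows, mm (default 0).
#' @param events_per_window range (length 2) of the number of rain events
#'   sampled per window.
#' @param temp_mean,temp_amplitude annual mean and seasonal amplitude of
#'   daily mean temperature, deg C.
#' @param temp_range diurnal range (tmax - tmin), deg C.
#' @param temp_sd day-to-day temperature jitter, deg C.
#' @param rad_mean,rad_amplitude radiation sinusoid, MJ m^-2 d^-1.
#' @param rh_mean_base,rh_sd humidity baseline (%) and jitter.
#' @param wind_base,wind_sd wind baseline (m s^-1) and jitter.
#' @param seed integer random seed fixing the full series.
#' @return list of class `weather_gen_config`.
#' @export
weather_gen_config <- function(year = 2000, rain_windows = NULL,
                               background_annual = 0,
                               events_per_window = c(4, 10),
                               temp_mean = 11.5, temp_amplitude = 14.5,
                               temp_range = 10, temp_sd = 2,
                               rad_mean = 14, rad_amplitude = 8,
                               rh_mean_base = 60, rh_sd = 10,
                               wind_base = 2.2, wind_sd = 0.8,
                               seed = 1L) {
  if (is.null(rain_windows))
    rain_windows <- data.frame(start = as.Date(character(0)),
                               end = as.Date(character(0)),
                               total = numeric(0))
  if (any(rain_windows$total < 0)) stop("rainfall totals must be >= 0")
  structure(list(year = year, rain_windows = rain_windows,
                 background_annual = background_annual,
                 events_per_window = events_per_window,
                 temp_mean = temp_mean, temp_amplitude = temp_amplitude,
                 temp_range = temp_range, temp_sd = temp_sd,
                 rad_mean = rad_mean, rad_amplitude = rad_amplitude,
                 rh_mean_base = rh_mean_base, rh_sd = rh_sd,
                 wind_base = wind_base, wind_sd = wind_sd,
                 seed = as.integer(seed)),
            class = "weather_gen_config")
}

# allocate `total` over `n` sampled event days so the sum is exact:
# random weights, cumulative-breakpoint construction with the final
# breakpoint pinned at `total`
allocate_events <- function(total, n) {
  if (total <= 0 || n == 0) return(numeric(n))
  u <- sort(stats::runif(n - 1))
  cuts <- c(0, total * u, total)
  diff(cuts)
}

#' Generate a daily weather series
#'
#' Smooth annual sinusoids for temperature and radiation plus seeded
#' jitter; rainfall placed on randomly sampled event days within each
#' configured window so that the window totals are met exactly (monsoon
#' concentration is expressed by putting large totals in the summer
#' windows). Fully reproducible from the config seed.
#'
#' @param config a [weather_gen_config()].
#' @return validated weather data.frame (see [validate_weather()]).
#' @export
generate_weather <- function(config) {
  stopifnot(inherits(config, "weather_gen_config"))
  days <- seq(as.Date(paste0(config$year, "-01-01")),
              as.Date(paste0(config$year, "-12-31")), by = "day")
  nd <- length(days)
  doy <- as.integer(format(days, "%j"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  # temperature: coldest around late January, warmest late July
  tmean <- config$temp_mean -
    config$temp_amplitude * cos(2 * pi * (doy - 25) / 365) +
    stats::rnorm(nd, 0, config$temp_sd)
  tmax <- tmean + config$temp_range / 2
  tmin <- tmean - config$temp_range / 2
  rad <- pmax(config$rad_mean -
                config$rad_amplitude * cos(2 * pi * (doy - 10) / 365) +
                stats::rnorm(nd, 0, 1), 0.5)
  rh <- pmin(pmax(config$rh_mean_base + stats::rnorm(nd, 0, config$rh_sd),
                  10), 100)
  wind <- pmax(config$wind_base + stats::rnorm(nd, 0, config$wind_sd), 0.1)
  rain <- numeric(nd)
  win <- config$rain_windows
  in_window <- rep(FALSE, nd)
  if (nrow(win) > 0) {
    for (i in seq_len(nrow(win))) {
      s <- as.Date(win$start[i]); e <- as.Date(win$end[i])
      idx <- which(days >= s & days <= e)
      if (length(idx) == 0)
        stop("rain window ", s, "..", e, " outside the generated year")
      in_window[idx] <- TRUE
      if (win$total[i] <= 0) next
      n_ev <- sample(seq(config$events_per_window[1],
                         config$events_per_window[2]), 1)
      n_ev <- min(n_ev, length(idx))
      ev_days <- sort(sample(idx, n_ev))
      rain[ev_days] <- rain[ev_days] + allocate_events(win$total[i], n_ev)
    }
  }
  if (config$background_annual > 0) {
    idx <- which(!in_window)
    n_ev <- min(max(8, length(idx) %/% 20), length(idx))
    ev_days <- sort(sample(idx, n_ev))
    rain[ev_days] <- rain[ev_days] +
      allocate_events(config$background_annual, n_ev)
  }
  validate_weather(data.frame(date = days, tmax = tmax, tmin = tmin,
                              rh_mean = rh, wind2 = wind, solar_rad = rad,
                              rain = rain, stringsAsFactors = FALSE))
}

# save/restore .Random.seed so generators are reproducible without
# clobbering the caller's RNG stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a management schedule for a treatment-year
#'
#' Builds the irrigation and fertilization event schedule of one
#' treatment-year from the published seasonal totals: manure as base
#' dressing before cauliflower; urea split into three equal applications
#' (at sowing, plus topdressings at the end of April and mid-May for
#' cauliflower, mid-September and early October for spinach); amaranth
#' receives its whole (possibly zero) dose at sowing; irrigation events
#' (few large furrow events under W1, more and smaller micro-sprinkler
#' events under W2) summing exactly to the seasonal totals, with an
#' irrigation event placed on every urea day (urea was broadcast and
#' immediately watered in).
#'
#' @param water "W1" (conventional furrow) or "W2" (optimized
#'   micro-sprinkler).
#' @param nitrogen "N1" (farmer practice), "N2" (Expert-N optimal) or
#'   "N3" (reduced).
#' @param year 2000 or 2001.
#' @param seed integer seed for event placement.
#' @return data.frame of events: `date`, `type` (irrigation | urea |
#'   manure | sowing | harvest), `crop`, `amount` (mm for irrigation,
#'   kg N ha^-1 otherwise), `incorporated` (logical).
#' @export
generate_management <- function(water = c("W1", "W2"),
                                nitrogen = c("N1", "N2", "N3"),
                                year = 2000, seed = 1L) {
  water <- match.arg(water)
  nitrogen <- match.arg(nitrogen)
  treatment <- paste0(water, nitrogen)
  cal <- reference_calendar(year)
  ref <- reference_balances()
  ref <- ref[ref$year == year & ref$treatment == treatment &
               ref$crop != "total", ]
  if (nrow(ref) != 3) stop("unknown treatment-year: ", treatment, " ", year)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_ev_range <- if (water == "W1") 4:6 else 8:12
  events <- list()
  add <- function(date, type, crop, amount, incorporated = FALSE) {
    events[[length(events) + 1]] <<- data.frame(
      date = as.Date(date), type = type, crop = crop, amount = amount,
      incorporated = incorporated, stringsAsFactors = FALSE)
  }
  for (i in seq_len(3)) {
    crop <- cal$crop[i]
    sow <- cal$sowing[i]; harv <- cal$harvest[i]
    r <- ref[ref$crop == crop, ]
    add(sow, "sowing", crop, 0)
    add(harv, "harvest", crop, 0)
    if (crop == "cauliflower" && r$Manu > 0)
      add(sow - 1, "manure", crop, r$Manu, incorporated = TRUE)
    # urea events
    urea_days <- as.Date(character(0))
    if (r$Fert > 0) {
      if (crop == "cauliflower") {
        urea_days <- c(sow, as.Date(paste0(year, "-04-28")),
                       as.Date(paste0(year, "-05-15")))
        urea_days <- pmin(pmax(urea_days, sow), harv)
        add_amounts <- rep(r$Fert / 3, 3)
      } else if (crop == "spinach") {
        urea_days <- c(sow, as.Date(paste0(year, "-09-15")),
                       as.Date(paste0(year, "-10-05")))
        urea_days <- pmin(pmax(urea_days, sow), harv)
        add_amounts <- rep(r$Fert / 3, 3)
      } else {
        urea_days <- sow
        add_amounts <- r$Fert
      }
      for (k in seq_along(urea_days))
        add(urea_days[k], "urea", crop, add_amounts[k])
    }
    # irrigation: events on urea days plus sampled days, exact total
    if (r$I > 0) {
      n_extra <- sample(n_ev_range, 1)
      season_days <- seq(sow, harv, by = "day")
      pool <- setdiff(as.integer(season_days), as.integer(urea_days))
      n_extra <- min(n_extra, length(pool))
      extra_days <- as.Date(sort(sample(pool, n_extra)),
                            origin = "1970-01-01")
      irr_days <- sort(c(as.Date(urea_days), extra_days))
      amounts <- allocate_events(r$I, length(irr_days))
      for (k in seq_along(irr_days))
        add(irr_days[k], "irrigation", crop, amounts[k])
    }
  }
  out <- do.call(rbind, events)
  out <- out[order(out$date, out$type), ]
  rownames(out) <- NULL
  attr(out, "treatment") <- treatment
  attr(out, "year") <- year
  out
}

#' Generate noisy pseudo-observations from simulator output
#'
#' Samples the simulated truth at a fixed cadence (soil water every two
#' days, as by TDR; nitrate concentration of the 60-90 cm layer every
#' 7-15 days, as by suction cups), adds Gaussian noise, and clips to
#' physical bounds. Reproducible from the seed.
#'
#' @param daily simulator daily output (from [run_rotation()]`$daily`):
#'   must contain `date`, the reporting-depth water content columns
#'   (`theta_0_15`, ...) and `no3_conc_60_90`.
#' @param noise_sd_theta Gaussian noise sd for water content (default
#'   0.02 cm^3 cm^-3).
#' @param noise_sd_no3 noise sd for nitrate concentration (default
#'   5 mg N L^-1).
#' @param cadence_theta,cadence_no3 sampling cadences, days.
#' @param theta_max physical upper bound for clipping water content
#'   (default 0.55, just above the loosest layer's saturation).
#' @param seed integer seed.
#' @return list of class `observation_set`: `water` (data.frame date x
#'   depth columns), `no3` (data.frame date, conc), and the noise sds
#'   used.
#' @export
generate_observations <- function(daily, noise_sd_theta = 0.02,
                                  noise_sd_no3 = 5, cadence_theta = 2,
                                  cadence_no3 = 10, theta_max = 0.55,
                                  seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  theta_cols <- grep("^theta_", names(daily), value = TRUE)
  idx_w <- seq(1, nrow(daily), by = cadence_theta)
  water <- daily[idx_w, c("date", theta_cols)]
  for (cn in theta_cols) {
    water[[cn]] <- pmin(pmax(water[[cn]] +
      stats::rnorm(nrow(water), 0, noise_sd_theta), 0), theta_max)
  }
  idx_n <- seq(1, nrow(daily), by = cadence_no3)
  no3 <- data.frame(date = daily$date[idx_n],
                    conc = daily$no3_conc_60_90[idx_n])
  no3 <- no3[!is.na(no3$conc), ]
  no3$conc <- pmax(no3$conc + stats::rnorm(nrow(no3), 0, noise_sd_no3), 0)
  structure(list(water = water, no3 = no3,
                 noise_sd_theta = noise_sd_theta,
                 noise_sd_no3 = noise_sd_no3),
            class = "observation_set")
}

#' Default rainfall windows for the two experimental years
#'
#' The per-season rainfall totals of the experiment (e.g. 151 mm during
#' the 2000 amaranth season against 69.1 mm in 2001) attached to the
#' rotation calendar, for driving [generate_weather()].
#'
#' @param year 2000 or 2001.
#' @return data.frame of `start`, `end`, `total` suitable for
#'   [weather_gen_config()].
#' @export
reference_rain_windows <- function(year) {
  cal <- reference_calendar(year)
  ref <- reference_balances()
  ref <- ref[ref$year == year & ref$treatment == "W1N1" &
               ref$crop != "total", ]
  data.frame(start = cal$sowing, end = cal$harvest,
             total = ref$RF[match(cal$crop, ref$crop)])
}
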