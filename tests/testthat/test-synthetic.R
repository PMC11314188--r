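test_that("generated weather honours window rainfall totals and the seed", {
  win <- data.frame(start = as.Date(c("2000-07-01", "2000-09-04")),
                    end = as.Date(c("2000-07-30", "2000-10-14")),
                    total = c(151.0, 65.6))
  cfg <- weather_gen_config(year = 2000, rain_windows = win, seed = 21)
  wx <- generate_weather(cfg)
  expect_equal(nrow(wx), 366)  # leap year
  in1 <- wx$date >= win$start[1] & wx$date <= win$end[1]
  in2 <- wx$date >= win$start[2] & wx$date <= win$end[2]
  expect_equal(sum(wx$rain[in1]), 151.0, tolerance = 1e-9)
  expect_equal(sum(wx$rain[in2]), 65.6, tolerance = 1e-9)
  expect_equal(sum(wx$rain[!in1 & !in2]), 0)
  # determinism and weather validity
  expect_identical(wx, generate_weather(cfg))
  expect_silent(validate_weather(wx))
  # zero-rain configuration
  dry <- generate_weather(weather_gen_config(year = 2001, seed = 3))
  expect_true(all(dry$rain == 0))
  # window outside the year errors
  bad <- weather_gen_config(year = 2000, rain_windows = data.frame(
    start = as.Date("2002-01-01"), end = as.Date("2002-02-01"), total = 10))
  expect_error(generate_weather(bad), "outside")
})

test_that("summer rainfall is monsoon-concentrated and temperatures seasonal", {
  wx <- generate_weather(weather_gen_config(
    year = 2000, rain_windows = reference_rain_windows(2000),
    background_annual = 60, seed = 4))
  july <- format(wx$date, "%m") == "07"
  jan <- format(wx$date, "%m") == "01"
  expect_gt(mean(wx$tmax[july]), mean(wx$tmax[jan]) + 15)
  expect_true(all(wx$tmax >= wx$tmin))
})

test_that("management schedules reproduce the published seasonal totals exactly", {
  m <- generate_management("W1", "N1", 2000, seed = 2)
  expect_equal(sum(m$amount[m$type == "irrigation"]), 507.8,
               tolerance = 1e-9)
  expect_equal(sum(m$amount[m$type == "urea"]), 859.0, tolerance = 1e-9)
  expect_equal(sum(m$amount[m$type == "manure"]), 75)
  # cauliflower and spinach get three equal urea splits, amaranth one dose
  caul <- m$amount[m$type == "urea" & m$crop == "cauliflower"]
  expect_length(caul, 3)
  expect_equal(caul, rep(450 / 3, 3))
  expect_length(m$amount[m$type == "urea" & m$crop == "amaranth"], 1)
  # optimized amaranth season in 2001 received no fertilizer
  m2 <- generate_management("W2", "N2", 2001, seed = 2)
  expect_equal(sum(m2$type == "urea" & m2$crop == "amaranth"), 0)
  # event hygiene: non-negative amounts, dates inside the season
  cal <- reference_calendar(2000)
  for (i in 1:3) {
    ei <- m[m$crop == cal$crop[i] & m$type %in% c("irrigation", "urea"), ]
    expect_true(all(ei$amount >= 0))
    expect_true(all(ei$date >= cal$sowing[i] & ei$date <= cal$harvest[i]))
  }
  expect_identical(m, generate_management("W1", "N1", 2000, seed = 2))
  expect_error(generate_management("W3", "N1", 2000))
})

test_that("observation generation closes the loop with the evaluator", {
  dates <- seq(as.Date("2000-05-01"), as.Date("2000-06-30"), by = "day")
  wx <- make_weather(dates, rain = rep_len(c(0, 0, 8, 0), length(dates)))
  cal <- data.frame(crop = "amaranth", sowing = as.Date("2000-05-05"),
                    harvest = as.Date("2000-06-25"))
  ev <- data.frame(date = cal$sowing, type = "sowing", crop = "amaranth",
                   amount = 0, incorporated = FALSE)
  run <- run_rotation(run_config(wx, ev, cal))
  # zero noise: observations equal the simulated truth, perfect statistics
  obs0 <- generate_observations(run$daily, noise_sd_theta = 0,
                                noise_sd_no3 = 0, seed = 8)
  truth <- run$daily$theta_0_15[match(obs0$water$date, run$daily$date)]
  expect_equal(obs0$water$theta_0_15, truth)
  st <- eval_stats(truth, obs0$water$theta_0_15)
  expect_equal(st$rmse, 0)
  expect_equal(st$nse, 1)
  expect_equal(st$agreement, 1)
  # determinism
  obs1 <- generate_observations(run$daily, seed = 8)
  expect_identical(obs1, generate_observations(run$daily, seed = 8))
})

test_that("observation noise matches its nominal standard deviation", {
  # long synthetic truth series so the empirical sd is well estimated
  daily <- data.frame(date = seq(as.Date("2000-01-01"), by = "day",
                                 length.out = 500),
                      theta_0_15 = 0.30, no3_conc_60_90 = 40)
  obs <- generate_observations(daily, noise_sd_theta = 0.02,
                               cadence_theta = 1, seed = 12)
  resid <- obs$water$theta_0_15 - 0.30
  expect_gt(length(resid), 200)
  expect_lt(abs(sd(resid) - 0.02) / 0.02, 0.2)
})

test_that("every treatment-year scenario runs the simulator without error", {
  for (yr in c(2000, 2001)) {
    for (w in c("W1", "W2")) {
      for (n in c("N1", "N2", "N3")) {
        run <- simulate_treatment(w, n, yr, seed = 5)
        expect_s3_class(run, "rotation_run")
        expect_true(all(is.finite(run$seasons$ET)))
      }
    }
  }
})
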