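test_that("evaluation statistics reproduce hand-computed values", {
  o <- c(1, 2, 3, 4)
  expect_equal(rmse(o, o), 0)
  expect_equal(nse(o, o), 1)
  expect_equal(agreement_d(o, o), 1)
  # P - O = (3, -4): RMSE = sqrt(25/2)
  expect_equal(rmse(c(4, 0), c(1, 4)), sqrt(12.5))
  # predicting the observed mean gives E = 0
  expect_equal(nse(rep(mean(o), 4), o), 0)
  # O = (0, 2), P = (2, 0): numerator 8, denominator 8
  expect_equal(agreement_d(c(2, 0), c(0, 2)), 0)
  expect_error(rmse(1:3, 1:4), "length")
  expect_error(nse(c(1, 2), c(3, 3)), "constant")
})

test_that("statistics match brute-force loops on random vectors", {
  set.seed(9)
  for (k in 1:10) {
    n <- sample(3:40, 1)
    o <- rnorm(n, 10, 4); p <- o + rnorm(n, 0, 2)
    sse <- 0; for (i in 1:n) sse <- sse + (p[i] - o[i])^2
    expect_equal(rmse(p, o), sqrt(sse / n), tolerance = 1e-12)
    ob <- sum(o) / n
    sso <- 0; for (i in 1:n) sso <- sso + (o[i] - ob)^2
    expect_equal(nse(p, o), 1 - sse / sso, tolerance = 1e-12)
    pot <- 0; for (i in 1:n) pot <- pot + (abs(p[i] - ob) + abs(o[i] - ob))^2
    expect_equal(agreement_d(p, o), 1 - sse / pot, tolerance = 1e-12)
  }
})

test_that("E is affine-invariant, d shift-invariant, RMSE scales linearly", {
  set.seed(10)
  o <- rnorm(20, 50, 10); p <- o + rnorm(20, 0, 5)
  a <- 2.5; b <- -7
  expect_equal(nse(a * p + b, a * o + b), nse(p, o), tolerance = 1e-12)
  expect_equal(agreement_d(p + b, o + b), agreement_d(p, o),
               tolerance = 1e-12)
  expect_equal(rmse(a * p, a * o), a * rmse(p, o), tolerance = 1e-12)
})

test_that("the acceptance rule applies E > 0.36 and d > 0.7 strictly", {
  expect_true(acceptance_check(list(nse = 0.92, agreement = 0.98))$pass)
  at <- acceptance_check(list(nse = 0.36, agreement = 0.7))
  expect_false(at$pass_nse); expect_false(at$pass_agreement)
  r <- acceptance_check(list(nse = 0.5, agreement = 0.6))
  expect_true(r$pass_nse); expect_false(r$pass); expect_length(r$reasons, 1)
})

test_that("season water ledger reproduces published efficiency cells", {
  # conventional-irrigation annual row, 2000
  wb <- season_water_balance(RF = 261.7, I = 507.8, ET = 562.0, D = 166.5,
                             Y = 72500)
  expect_equal(wb$Wbalance, 41.0, tolerance = 0.15)
  expect_equal(wb$WUE, 12.9, tolerance = 0.15)
  expect_equal(wb$IWUE, 14.3, tolerance = 0.15)
  # spinach under reduced irrigation and fertilizer, 2000
  expect_equal(season_water_balance(65.6, 89.3, 115.4, 6.8, 33900)$WUE,
               29.4, tolerance = 0.15)
  # undefined efficiencies are NA, not zero
  z <- season_water_balance(0, 0, 0, 0, 0)
  expect_equal(z$Wbalance, 0)
  expect_true(is.na(z$WUE) && is.na(z$IWUE))
})

test_that("season N ledger reproduces published NUE and residuals", {
  nb <- season_n_balance(Manu = 75, Fert = 859.0, Nirr = 19.8,
                         Nnet = 80.7, Nup = 329.4, Ngas = 212.9,
                         Nlea = 195.7, Y = 72500)
  expect_equal(nb$NUE, 98.2, tolerance = 0.15)
  expect_equal(nb$Nbalance, 296.5, tolerance = 0.15)
  nb2 <- season_n_balance(120, 160.9, 14.3, 98.7, 313.6, 37.5, 0.5, 66100)
  expect_equal(nb2$NUE, 188.0, tolerance = 0.15)
  z <- season_n_balance(0, 0, 0, 0, 0, 0, 0, 0)
  expect_equal(z$Nbalance, 0)
  expect_true(is.na(z$NUE))
})

test_that("annual aggregation sums components and recomputes ratios", {
  ref <- reference_balances()
  w1n1 <- ref[ref$year == 2000 & ref$treatment == "W1N1" &
                ref$crop != "total", ]
  seasons <- do.call(rbind, lapply(seq_len(3), function(i) {
    r <- w1n1[i, ]
    cbind(season_water_balance(r$RF, r$I, r$ET, r$D, r$Y, r$treatment,
                               r$crop, r$year),
          season_n_balance(r$Manu, r$Fert, r$Nirr, r$Nnet, r$Nup, r$Ngas,
                           r$Nlea, r$Y)[, c("Manu", "Fert", "Nirr",
                                            "Nnet", "Nup", "Ngas",
                                            "Nlea", "NUE", "Nbalance")])
  }))
  tot <- aggregate_annual(seasons)
  prt <- ref[ref$year == 2000 & ref$treatment == "W1N1" &
               ref$crop == "total", ]
  for (cn in c("RF", "I", "ET", "D", "Y", "WUE", "IWUE", "Wbalance",
               "Manu", "Fert", "Nirr", "Nnet", "Nup", "Ngas", "Nlea",
               "NUE", "Nbalance"))
    expect_equal(tot[[cn]], prt[[cn]], tolerance = 0.15,
                 label = paste("total", cn))
  # the ratio is recomputed from sums, not averaged over seasons
  expect_gt(abs(mean(seasons$NUE) - tot$NUE), 1)
  # single season aggregates to itself; doubling doubles extensives only
  expect_equal(aggregate_annual(seasons[1, ])$WUE, seasons$WUE[1])
  two <- aggregate_annual(rbind(seasons[1, ], seasons[1, ]))
  expect_equal(two$ET, 2 * seasons$ET[1])
  expect_equal(two$WUE, seasons$WUE[1])
  seasons2 <- seasons; seasons2$treatment[2] <- "W2N1"
  expect_error(aggregate_annual(seasons2), "mixed")
})

test_that("balance tables round-trip through the report writer", {
  ref <- reference_balances()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_balance_table(ref[1:4, ], path)
  back <- read.delim(path)
  expect_equal(back$ET, ref$ET[1:4])
  write_balance_table(ref[1:4, ], path, rounded = TRUE)
  back <- read.delim(path)
  expect_equal(back$Y, ref$Y[1:4])  # yields already at printed precision
})

test_that("staged coordinate calibration finds grid optima deterministically", {
  truth <- c(a = 2, b = -1, c = 0.5)
  obj <- function(p) (p$a - 2)^2 + (p$b + 1)^2 + (p$c - 0.5)^2
  stages <- list(
    water = list(a = seq(-3, 3, by = 0.5)),
    nitrogen = list(b = seq(-3, 3, by = 0.5)),
    crop = list(c = seq(-1, 1, by = 0.25))
  )
  fit <- calibrate(obj, stages)
  expect_equal(unlist(fit$par), truth, tolerance = 1e-12)
  expect_equal(fit$objective, 0)
  # the trace records every evaluation
  expect_true(all(c("stage", "parameter", "value", "objective",
                    "accepted") %in% names(fit$trace)))
  # empty space returns the start unchanged
  empty <- calibrate(obj, list(), start = list(a = 1, b = 0, c = 0))
  expect_equal(empty$par, list(a = 1, b = 0, c = 0))
  # optimum never worse than the defaults
  start <- list(a = -3, b = 3, c = -1)
  fit2 <- calibrate(obj, stages, start = start)
  expect_lte(fit2$objective, obj(start))
  # non-finite candidates are rejected and logged
  obj_bad <- function(p) if (p$a < 0) NaN else (p$a - 1)^2
  fit3 <- calibrate(obj_bad, list(s = list(a = c(1, -1, 2))))
  expect_equal(fit3$par$a, 1)
  expect_true(any(is.na(fit3$trace$objective)))
})
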