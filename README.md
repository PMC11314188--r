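# vegrotN

Daily soil–water–nitrogen–crop simulation for open-field vegetable
rotations, with the Expert-N optimal fertilizer recommendation, seasonal
water/N ledger accounting, model-evaluation statistics, and a
synthetic-data module.

## The problem

Intensive vegetable rotations in the North China Plain grow three crops a
year (a spring cauliflower, a summer amaranth, an autumn spinach) under
heavy irrigation and fertilization. Shallow-rooted vegetables leave much
of that water and nitrogen unused, so the fields lose water as drainage,
and nitrogen as nitrate leaching and gaseous emission (ammonia
volatilization plus denitrification). Quantifying those fates requires a
soil–crop model, because drainage and leaching below the root zone are
not directly measurable at field scale.

`vegrotN` implements that machinery as a tested R package, for
agronomists and modellers who want to trace water and N budgets of
vegetable rotations, audit efficiency indices, or experiment with
fertilizer recommendation rules:

* **Reference evapotranspiration** — FAO-56 Penman–Monteith at a daily
  step, with four-stage crop coefficient curves
  (`reference_et0()`, `crop_kc()`).
* **Soil water** — a layered tipping-bucket: NRCS curve-number runoff
  (S = 25400/CN − 254, initial abstraction 0.2 S), fill-and-spill
  redistribution with a Ritchie-style drainage coefficient, root-zone
  extraction, drainage reported at the 0.9 m plane
  (`partition_runoff()`, `redistribute()`, `extract_et()`).
* **Soil nitrogen** — first-order two-pool mineralization (native humus
  and added manure), fast urea hydrolysis, ammonia volatilization with
  emission-potential decay and wet-day suppression, nitrification,
  WFPS-gated denitrification, and mixing-cell nitrate advection
  (`mineralize()`, `volatilize()`, `denitrify()`, `advect_nitrate()`).
* **Crop growth** — expolinear dry-matter accumulation,
  W(t) = (c_m/r_m)·ln(1 + e^{r_m (t − t_b)}), with a Greenwood-style
  critical N dilution curve %N_crit = a·DM^(−b), luxury uptake up to
  L·%N_crit, linear root deepening, and fresh-yield conversion
  (`grow_daily()`, `critical_n_pct()`, `fresh_yield()`).
* **Expert-N recommendation** —
  N_opt = N_upt + N_res + N_loss − N_ini − N_hum − N_root with
  N_loss = N_input × 0.019 × weeks (`recommend_n()`).
* **Accounting** — seasonal ledgers with WUE = Y/ET, IWUE = Y/I,
  Wbalance = RF + I − ET − D, NUE = Y/(Nup + Nlea + Ngas) and
  Nbalance = inputs − outputs; annual totals recompute ratios from
  summed components (`season_water_balance()`, `season_n_balance()`,
  `aggregate_annual()`).
* **Evaluation** — RMSE, Nash–Sutcliffe efficiency E, Willmott agreement
  d, and the acceptance rule E > 0.36 and d > 0.7 (`eval_stats()`,
  `acceptance_check()`), plus a staged coordinate-search calibration
  harness (`calibrate()`).
* **Synthetic data** — seeded monsoon-climate weather with exact
  window rainfall totals, management schedules reproducing the published
  seasonal irrigation/fertilizer totals of the Dongbeiwang experiment,
  and noisy pseudo-observations (`generate_weather()`,
  `generate_management()`, `generate_observations()`).

The published seasonal balance tables, soil profile, rotation calendar
and validation statistics of the two-year Dongbeiwang (Beijing)
experiment ship as in-code reference tables (`reference_balances()` and
friends) and anchor the test suite.

## Worked example

Recompute the annual water/N ledger of the conventional treatment
(W1N1, 2000) from its seasonal components:

```r
library(vegrotN)

ref <- reference_balances()
r <- subset(ref, year == 2000 & treatment == "W1N1" & crop == "total")
wb <- season_water_balance(r$RF, r$I, r$ET, r$D, r$Y)
nb <- season_n_balance(r$Manu, r$Fert, r$Nirr, r$Nnet,
                       r$Nup, r$Ngas, r$Nlea, r$Y)
round(c(WUE = wb$WUE, IWUE = wb$IWUE, Wbalance = wb$Wbalance,
        NUE = nb$NUE, Nbalance = nb$Nbalance), 1)
#>      WUE     IWUE Wbalance      NUE Nbalance
#>     12.9     14.3     41.0     98.2    296.5
```

WUE and IWUE are kg of fresh yield per m³ of evapotranspired and
irrigated water; Wbalance (mm) and Nbalance (kg N ha⁻¹) are the residual
storage changes of the 0.9 m profile; NUE is fresh yield per kg of N
leaving the system.

Ask the Expert-N rule for an optimal dose:

```r
recommend_n(n_upt = 200, n_res = 50, n_ini = 100, n_hum = 30,
            n_root = 0, n_input_farmer = 450, season_weeks = 10)
#> $n_opt
#> [1] 205.5
#> $n_loss
#> [1] 85.5
```

Simulate a full synthetic treatment-year and inspect its season ledger:

```r
run <- simulate_treatment("W1", "N1", year = 2000, seed = 1)
run$seasons[, c("crop", "RF", "I", "ET", "D", "Nup", "Ngas", "Nlea")]
max(abs(run$daily$water_resid))   # daily closure, ~1e-13 mm
```

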