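---
title: "Model description and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model description and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`vegrotN` simulates the daily fate of water and nitrogen in an
open-field vegetable rotation — the cauliflower–amaranth–spinach
sequence grown at Dongbeiwang (Beijing) is the reference system — and
wraps that simulator with accounting, evaluation, calibration and
fertilizer-recommendation tools. This vignette records the model
structure, the assumptions behind it, and the design decisions that were
genuinely open.

## Daily loop

For each day the simulator executes, in order:

1. management events (sowing, harvest, manure, urea, irrigation);
2. surface partition: rainfall through the NRCS curve-number relation
   (potential retention S = 25400/CN − 254 mm, initial abstraction
   0.2 S); irrigation infiltrates fully, since furrow and
   micro-sprinkler water is confined to the plot;
3. nitrogen transformations: urea hydrolysis, ammonia volatilization,
   two-pool mineralization, nitrification, denitrification;
4. tipping-bucket redistribution and mixing-cell nitrate advection;
5. reference ET (FAO-56 Penman–Monteith), partitioned into soil
   evaporation and transpiration by canopy cover, then extracted from
   the profile;
6. crop N demand, root uptake, and expolinear growth under the minimum
   of the water and N stress factors.

Every day the loop records closure residuals. Water:
rain + irrigation = runoff + ΔS + E_s + T + drainage, and nitrogen:
fertilizer + manure + N_irr + seed N = volatilization + denitrification
+ bottom leaching + harvest export + Δ(all pools). The test suite
requires both residuals below 10⁻⁹ (mm, kg N ha⁻¹) on every simulated
day of 100 randomized scenarios; in practice they sit at rounding level
(~10⁻¹³).

## State and geometry

The soil is the measured 120 cm profile in five layers (0–15, 15–30,
30–60, 60–90, 90–120 cm; the top two share the measured 0–30 cm
properties). Depths are cm positive downward, water contents
cm³ cm⁻³, water fluxes mm, N masses kg N ha⁻¹ (1 mm over 1 ha = 10 m³,
so 1 mg N L⁻¹ in 1 mm of water is 0.01 kg N ha⁻¹). Although the state
extends to 120 cm, drainage and nitrate leaching are *reported* at the
90 cm plane, because the experiment's balances are drawn for the 0.9 m
profile while its water-content measurements reach 120 cm. Whether the
original model simulated below 90 cm is not stated anywhere; carrying a
90–120 cm buffer layer under a 90 cm reporting plane reconciles the two
domains and is flagged here as this package's choice.

Season ledgers attribute weather-driven fluxes (rain, ET, drainage,
leaching, mineralization) to a season by date window (sowing–harvest)
and management inputs by the crop label of the event, so the manure
dressed one day before transplanting still books to the cauliflower
season. Fallow-gap fluxes belong to no season; annual rows sum the
season rows and recompute every ratio from the summed components — the
published totals follow that arithmetic (e.g. an annual NUE of
72,500/7,380 ≈ 98.2, not the mean of the three seasonal NUEs).

## Sub-models and their tunable parameters

**Reference ET.** FAO-56 daily grass reference: psychrometric constant
from altitude, saturation vapour pressure averaged over the daily
extremes, actual vapour pressure from mean RH (or supplied as kPa), net
radiation from measured solar radiation with albedo 0.23 and the
clear-sky longwave correction, soil heat flux zero. Humidity may come as
RH or vapour pressure because weather sources differ. A daily (not
sub-daily) step is used throughout: the study system is managed and
reported at daily/seasonal resolution.

**Crop coefficients.** Four-stage FAO-style curves (initial,
development ramp, mid plateau, late ramp). The stage plateaus are free
parameters per crop; the experiment's own coefficients were calibrated
against yield and N uptake and never printed, so the defaults here
(k_c 0.7/1.0–1.05/0.95) are standard vegetable values and are exposed
to `calibrate()`.

**Soil water.** Ritchie-style bucket: water above saturation spills
instantly; of the water held between field capacity and saturation a
fraction `drain_frac` (default 0.5 d⁻¹, calibratable — tipping-bucket
models need a drainage coefficient and none is published for this soil)
moves down per day. Evaporation draws the surface layer down to an
air-dry limit (default half of wilting point). Transpiration is
withdrawn from rooted layers proportionally to root fraction × available
water, with water-filling re-allocation when a layer runs dry; the root
density profile is triangular (linearly decreasing to zero at the root
front) because no measured profile exists for these crops.

**Soil nitrogen.** All transformations are first-order with a
Q10 = 2 temperature factor (reference 20 °C, capped at 1) and a
piecewise-linear moisture factor (0 at wilting point, 1 at field
capacity, declining to 0.5 at saturation) — the standard shapes of
DAISY-family models, since none are printed. Defaults: humus pool
8×10⁻⁵ d⁻¹ (sized so that a ~5,000–7,000 kg N ha⁻¹ profile store
releases some 80–100 kg N ha⁻¹ yr⁻¹, the reported net-mineralization
range), manure pool 0.02 d⁻¹, hydrolysis 0.36 d⁻¹ (half-life under two
days), nitrification 0.2 d⁻¹, denitrification 0.1 d⁻¹ at saturation
gated by water-filled pore space > 0.6 with a squared excess-WFPS
response — reduced irrigation keeps the soil aerated and shuts
denitrifiers down, which is the mechanism behind the reported gaseous-N
savings under optimized irrigation. Volatilization removes a fraction of
surface ammonium that starts at 0.15 on the application day, decays at
0.35 d⁻¹, is multiplied by 0.1 on days with ≥ 5 mm of surface water
(urea was broadcast and immediately watered in) and by 0.3 when the
application is incorporated (manure). The ledger's "net mineralization"
is the humus-pool release only (times 1 − immobilization, default 0);
manure-derived mineralization is booked with the manure input, because
the published ledger lists manure and net mineralization as separate
sources. Gaseous N is reported as one total but the simulator keeps
volatilization and denitrification separate; no printed value
constrains their split.

**Irrigation-water N.** N_irr = 0.01 × concentration × depth. The
concentration is not published; back-calculating from the ledger's
N_irr/I ratios (19.8 kg N ha⁻¹ per 507.8 mm, and likewise in every
treatment-year) gives ≈ 3.9 mg N L⁻¹, the default.

**Crop growth.** The vegetable growth module follows the N_ABLE
lineage in structure — the original equations are not republished, so
the package substitutes the documented-equivalent form: expolinear
potential growth W(t) = (c_m/r_m)·ln(1 + e^{r_m(t − t_b)}), daily
increments scaled by a temperature factor (linear between a 4 °C base
and a 20 °C optimum — the short 22–65-day seasons make a single rate
parameter per crop identifiable, so no thermal-time tables) and by
min(water stress, N stress). N demand pulls the plant to the luxury
ceiling L × %N_crit at tomorrow's potential biomass, with
%N_crit = a·DM^(−b) (constant below 1 t ha⁻¹). The N stress factor is
actual over critical concentration, clipped to [0, 1]. Transplanted
cauliflower starts from a nonzero dry matter; sown crops from ~0. All
coefficients are placeholders for calibration, sized to local yields
(~20 t ha⁻¹ cauliflower, ~14–20 t amaranth, ~30–34 t spinach) — they
are not assertions about the original calibrated values, which were
never printed.

## Expert-N recommendation

`recommend_n()` evaluates
N_opt = N_upt + N_res + N_loss − N_ini − N_hum − N_root with
N_loss = N_input × 0.019 × weeks, clamped below at zero — a negative
dose is meaningless, and the optimized schedules do contain
zero-fertilizer seasons. N_ini and N_hum may be read off a simulation
(`run$daily$mineral_n`, seasonal `nnet` sums), closing the loop between
recommendation and soil state. The reduced treatment is a per-crop
fraction (default 0.8): the study text describes the reduction once as
80% of optimal generally and once as spinach-only, so the package
exposes the fraction rather than hard-coding either reading.

## Evaluation and calibration

RMSE, Nash–Sutcliffe E and Willmott d follow their standard
definitions; E is undefined for constant observations and d for fully
degenerate series, and both raise errors rather than returning a
number. The acceptance rule is strict: E > 0.36 and d > 0.7.

"Trial and error" calibration is not reproducible, so `calibrate()` is
a deterministic staged coordinate search: parameter groups are scanned
in the calibration order of the study workflow (soil water first, then
N transformations, then crop), each parameter over a fixed grid with
the others held at their current best, and the full stage sequence is
swept twice so that late-stage adjustments feed back. Non-finite
objectives reject the candidate and are logged in the returned trace.
The self-consistency test generates observations from the simulator at
known parameters and recovers them: exactly at zero noise, within one
grid step (10% grids) at the default observation noise
(σ_θ = 0.02 cm³ cm⁻³, matching the reported sub-surface water-content
RMSEs of 0.01–0.02; 5% on yield and N uptake).

## Synthetic data: what it does and does not emulate

No weather record or per-event management table was published. The
weather generator produces a Beijing-like temperate-monsoon year:
annual mean 11.5 °C with a 14.5 °C seasonal amplitude, radiation and
humidity baselines with seeded jitter, and rainfall allocated over
sampled event days inside configured windows so that window totals are
met to machine precision — the study's contrast of a 151 mm amaranth
season (2000) against 69.1 mm (2001) is expressed this way. Management
schedules reproduce the published seasonal irrigation and fertilizer
totals exactly, with the documented timing rules: manure before
cauliflower, urea in three equal splits for cauliflower (sowing, late
April, mid May) and spinach (sowing, mid September, early October),
none for amaranth beyond its sowing dose, an irrigation event on every
urea day, and 4–6 large furrow events (W1) versus 8–12 smaller
micro-sprinkler events (W2) per season. A rule-based W2 mode
(trigger at 50% of field capacity, refill to 80%) is available for
scenario experiments but the table-reproduction mode holds the printed
totals fixed.

What the generator does *not* emulate: real storm intensity and
inter-annual correlation, the actual (unpublished) event dates and
amounts, spatial variability, and instrument error structure beyond
i.i.d. Gaussian noise. Consequently, passing tests demonstrate internal
consistency — conservation, directional responses, parameter
recovery — not agreement with the original daily trajectories. The
study's per-treatment drainage, leaching and ET magnitudes depend on
the unpublished weather record and are deliberately not asserted; the
package instead checks the reproducible layer: the ledger identities on
the published tables, and the directional responses (wet year drains
and leaches more than a dry year; reduced fertilizer lowers gaseous N;
reduced irrigation lowers leaching) on matched synthetic scenarios.

## Numerical choices and degenerate inputs

* Efficiency indices with zero denominators (ET = 0, I = 0, zero N
  outputs) are `NA`, never 0.
* The ledger-identity fixture uses a 0.15 printed-unit tolerance to
  absorb table rounding. Two published cells are internally
  inconsistent with their own printed components (both IWUE cells; one
  reads 15.4 where yield/irrigation gives 25.4) and are excluded as
  misprints.
* The multi-day closed form used as the oracle for first-order decay is
  the geometric solution of the daily step, pool₀·(1 − (1 − k)^t); at
  the package's rate constants it is indistinguishable from the
  continuous exponential at far better than the 10⁻⁶ test tolerance.
* Mixing-cell advection computes each layer's outflow concentration
  from mass and water *after* mixing the inflow, which makes the
  cascade exactly mass-conserving; outflow can never exceed resident
  mass because drainage never exceeds resident water.
* Proportional allocations (transpiration, N uptake) cap at per-layer
  availability and re-allocate the remainder among unsaturated layers;
  ties need no special handling because weights are continuous.
* Curve number 100 means zero retention (all surface water runs off);
  the relation is evaluated in its algebraic form otherwise.

## Problem sizes

The test suite simulates short (30–60 day) single-season scenarios for
property tests, full ~205-day treatment-years for the fixture and
directional checks, 100 randomized scenarios for the conservation
suite, and a 43-day season for the calibration recovery (about 40
simulator runs); the whole suite completes in about one to two minutes
on a single core. These sizes were chosen to exercise every code path
with comfortable margins rather than to mimic production workloads.

## Known limitations

* No Richards flow, macropores, water table or hysteresis; drainage
  timing is as sharp as a bucket cascade makes it.
* No N₂O/N₂ partitioning, microbial biomass, dissolved organic N or
  ammonium sorption; the gaseous split is structurally present but
  unconstrained by data.
* Crop phenology is a single expolinear trajectory per crop; no
  photoperiod, vernalization or pest effects.
* The growth, dilution and coefficient defaults are sized to reported
  yield magnitudes, not fitted to the (unpublished) original data; any
  quantitative use should start from `calibrate()` on local
  observations.
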