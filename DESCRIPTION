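Package: vegrotN
Title: Water and Nitrogen Fate Simulation for Intensive Vegetable Rotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Daily soil-water-nitrogen-crop simulation for open-field
    vegetable rotations in the style of the EU-Rotate_N model family:
    FAO-56 Penman-Monteith reference evapotranspiration with staged crop
    coefficients, a layered tipping-bucket water balance with curve-number
    runoff and mixing-cell nitrate transport, first-order nitrogen
    transformations (mineralization, urea hydrolysis, volatilization,
    nitrification, denitrification), expolinear vegetable growth with
    dilution-curve nitrogen demand and luxury uptake, the Expert-N optimal
    fertilizer recommendation, seasonal water and nitrogen ledgers with
    efficiency indices, model-evaluation statistics (RMSE, Nash-Sutcliffe
    efficiency, Willmott agreement index), a staged calibration harness,
    and a synthetic-data module generating monsoon-climate weather,
    management schedules and noisy pseudo-observations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
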