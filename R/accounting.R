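#' Seasonal water balance and efficiency indices
#'
#' Fills the water side of a season ledger from its components: water use
#' efficiency WUE = Y/ET and irrigation water use efficiency IWUE = Y/I
#' (kg m^-3, converting mm over 1 ha to 10 m^3), and the storage residual
#' Wbalance = RF + I - ET - D (mm). Efficiencies with a zero denominator
#' are reported as `NA` (undefined), never as zero.
#'
#' @param RF seasonal rainfall, mm.
#' @param I seasonal irrigation, mm.
#' @param ET seasonal evapotranspiration, mm.
#' @param D seasonal drainage past the reporting plane, mm.
#' @param Y fresh yield, kg ha^-1.
#' @param treatment,crop,year optional labels.
#' @return one-row data.frame with the components and `WUE`, `IWUE`,
#'   `Wbalance`.
#' @export
season_water_balance <- function(RF, I, ET, D, Y, treatment = NA_character_,
                                 crop = NA_character_, year = NA_integer_) {
  if (any(c(RF, I, ET, D, Y) < 0)) stop("water components must be >= 0")
  data.frame(
    year = year, treatment = treatment, crop = crop,
    RF = RF, I = I, ET = ET, D = D, Y = Y,
    WUE = if (ET > 0) Y / mm_to_m3_ha(ET) else NA_real_,
    IWUE = if (I > 0) Y / mm_to_m3_ha(I) else NA_real_,
    Wbalance = RF + I - ET - D,
    stringsAsFactors = FALSE
  )
}

#' Seasonal nitrogen balance and use efficiency
#'
#' Fills the nitrogen side of a season ledger: nitrogen use efficiency
#' NUE = Y / (Nup + Nlea + Ngas) (kg fresh yield per kg N, the table-note
#' definition) and the residual Nbalance = (Manu + Fert + Nirr + Nnet) -
#' (Nup + Ngas + Nlea), kg N ha^-1.
#'
#' @param Manu manure N applied, kg N ha^-1.
#' @param Fert fertilizer N applied, kg N ha^-1.
#' @param Nirr N input with irrigation water, kg N ha^-1.
#' @param Nnet net mineralization of native soil organic N, kg N ha^-1.
#' @param Nup crop N uptake, kg N ha^-1.
#' @param Ngas gaseous N emission (volatilization + denitrification),
#'   kg N ha^-1.
#' @param Nlea nitrate leaching past the reporting plane, kg N ha^-1.
#' @param Y fresh yield, kg ha^-1.
#' @param treatment,crop,year optional labels.
#' @return one-row data.frame with the components and `NUE`, `Nbalance`.
#' @export
season_n_balance <- function(Manu, Fert, Nirr, Nnet, Nup, Ngas, Nlea, Y,
                             treatment = NA_character_,
                             crop = NA_character_, year = NA_integer_) {
  if (any(c(Manu, Fert, Nirr, Nnet, Nup, Ngas, Nlea, Y) < 0))
    stop("N components must be >= 0")
  outputs <- Nup + Nlea + Ngas
  data.frame(
    year = year, treatment = treatment, crop = crop,
    Manu = Manu, Fert = Fert, Nirr = Nirr, Nnet = Nnet,
    Nup = Nup, Ngas = Ngas, Nlea = Nlea, Y = Y,
    NUE = if (outputs > 0) Y / outputs else NA_real_,
    Nbalance = (Manu + Fert + Nirr + Nnet) - outputs,
    stringsAsFactors = FALSE
  )
}

#' Annual aggregation of season ledgers
#'
#' Sums the extensive fields of several season rows of one treatment-year
#' and recomputes the ratio indices (WUE, IWUE, NUE) and residuals from
#' the summed components -- never as averages of per-season ratios.
#'
#' @param seasons data.frame of season rows (water and/or N columns as
#'   produced by [season_water_balance()] / [season_n_balance()], possibly
#'   merged).
#' @return one-row data.frame labelled `crop = "total"`.
#' @export
aggregate_annual <- function(seasons) {
  if (nrow(seasons) < 1) stop("no season rows")
  tr <- unique(seasons$treatment[!is.na(seasons$treatment)])
  yr <- unique(seasons$year[!is.na(seasons$year)])
  if (length(tr) > 1 || length(yr) > 1)
    stop("cannot aggregate mixed treatments or years")
  s <- function(cn) if (cn %in% names(seasons)) sum(seasons[[cn]]) else NULL
  out <- data.frame(year = if (length(yr)) yr else NA_integer_,
                    treatment = if (length(tr)) tr else NA_character_,
                    crop = "total", stringsAsFactors = FALSE)
  water <- all(c("RF", "I", "ET", "D") %in% names(seasons))
  nitro <- all(c("Manu", "Fert", "Nirr", "Nnet", "Nup", "Ngas", "Nlea") %in%
                 names(seasons))
  if (water) {
    wb <- season_water_balance(s("RF"), s("I"), s("ET"), s("D"), s("Y"))
    out <- cbind(out, wb[, c("RF", "I", "ET", "D", "Y", "WUE", "IWUE",
                             "Wbalance")])
  }
  if (nitro) {
    nb <- season_n_balance(s("Manu"), s("Fert"), s("Nirr"), s("Nnet"),
                           s("Nup"), s("Ngas"), s("Nlea"), s("Y"))
    cols <- c("Manu", "Fert", "Nirr", "Nnet", "Nup", "Ngas", "Nlea",
              "NUE", "Nbalance")
    if (!water) cols <- c(cols, "Y")
    out <- cbind(out, nb[, cols])
  }
  out
}

#' Write a balance report table
#'
#' Writes season/annual ledgers as delimited text in the column order of
#' the published balance tables, either at full precision or rounded to
#' the printed precision (one decimal; yields to the nearest 100 kg).
#'
#' @param balances data.frame of ledger rows.
#' @param path output file.
#' @param rounded write the paper-rounded view (default `FALSE`).
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_balance_table <- function(balances, path, rounded = FALSE,
                                sep = "\t") {
  water_cols <- c("RF", "I", "ET", "D", "Y", "WUE", "IWUE", "Wbalance")
  n_cols <- c("Manu", "Fert", "Nirr", "Nnet", "Nup", "Ngas", "Nlea",
              "NUE", "Nbalance")
  keep <- c("year", "treatment", "crop",
            intersect(c(water_cols, n_cols), names(balances)))
  out <- balances[, keep]
  if (rounded) {
    for (cn in setdiff(keep, c("year", "treatment", "crop", "Y")))
      out[[cn]] <- round(out[[cn]], 1)
    if ("Y" %in% keep) out$Y <- round(out$Y / 100) * 100
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
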