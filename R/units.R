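#' Unit conversions used throughout the simulator
#'
#' All depths of water are mm, nitrogen masses kg N ha^-1, soil layer
#' geometry cm (positive downward), volumetric water content cm^3 cm^-3.
#' One mm of water over one hectare is 10 m^3 (10,000 L).
#'
#' @param mm water depth in mm.
#' @name units
NULL

#' @describeIn units water depth (mm over 1 ha) to volume (m^3 ha^-1).
#' @export
mm_to_m3_ha <- function(mm) mm * 10

#' @describeIn units dissolved N mass (kg N ha^-1) carried by `mm` of water
#'   at concentration `conc_mg_l` (mg N L^-1).
#' @param conc_mg_l concentration in mg N per litre.
#' @export
n_mass_from_conc <- function(mm, conc_mg_l) 0.01 * conc_mg_l * mm

#' @describeIn units concentration (mg N L^-1) of `mass_kg_ha` kg N ha^-1
#'   dissolved in `mm` of water.
#' @param mass_kg_ha N mass in kg N ha^-1.
#' @export
conc_from_n_mass <- function(mass_kg_ha, mm) {
  ifelse(mm > 0, 100 * mass_kg_ha / mm, NA_real_)
}

#' @describeIn units volumetric water content over a layer thickness (cm)
#'   expressed as a depth of water (mm).
#' @param theta volumetric water content (cm^3 cm^-3).
#' @param thickness_cm layer thickness in cm.
#' @export
theta_to_mm <- function(theta, thickness_cm) theta * thickness_cm * 10

#' @describeIn units depth of water (mm) in a layer back to volumetric
#'   content.
#' @export
mm_to_theta <- function(mm, thickness_cm) mm / (thickness_cm * 10)
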