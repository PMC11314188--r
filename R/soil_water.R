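#' Layered soil profile
#'
#' Constructor/validator for the layered soil description used by the
#' tipping-bucket water balance. Depths are cm, positive downward; water
#' retention landmarks are volumetric contents (cm^3 cm^-3) and must be
#' ordered 0 < wilting point < field capacity < saturation < 1.
#'
#' @param top,bottom layer bounds, cm.
#' @param bulk_density g cm^-3.
#' @param theta_s,theta_fc,theta_wp saturation, field capacity, wilting
#'   point.
#' @return data.frame of class `soil_profile` with a `thickness` column
#'   (cm).
#' @export
soil_profile <- function(top, bottom, bulk_density, theta_s, theta_fc,
                         theta_wp) {
  p <- data.frame(top = top, bottom = bottom, bulk_density = bulk_density,
                  theta_s = theta_s, theta_fc = theta_fc,
                  theta_wp = theta_wp)
  if (any(p$bottom <= p$top)) stop("layer bottom must exceed top")
  if (nrow(p) > 1 && any(p$top[-1] != p$bottom[-nrow(p)]))
    stop("layers must be contiguous and ordered")
  ok <- p$theta_wp > 0 & p$theta_wp < p$theta_fc &
    p$theta_fc < p$theta_s & p$theta_s < 1
  if (!all(ok)) stop("need 0 < theta_wp < theta_fc < theta_s < 1 per layer")
  p$thickness <- p$bottom - p$top
  class(p) <- c("soil_profile", "data.frame")
  p
}

#' NRCS curve-number runoff partition
#'
#' Partitions surface water input into runoff and infiltration with the
#' curve-number relation: potential retention S = 25400/CN - 254 (mm),
#' initial abstraction 0.2 S, runoff Q = (P - 0.2S)^2 / (P + 0.8S) for
#' P > 0.2S, else zero.
#'
#' @param water_in surface water arriving, mm.
#' @param curve_number dimensionless CN in (0, 100]; CN = 100 means zero
#'   retention (all water runs off).
#' @return list with `runoff` and `infiltration` (mm); they sum to
#'   `water_in`.
#' @export
partition_runoff <- function(water_in, curve_number) {
  if (water_in < 0) stop("water_in must be >= 0")
  if (curve_number <= 0 || curve_number > 100)
    stop("curve_number must be in (0, 100]")
  s <- 25400 / curve_number - 254
  ia <- 0.2 * s
  runoff <- if (water_in > ia) (water_in - ia)^2 / (water_in - ia + s) else 0
  if (s == 0) runoff <- water_in
  list(runoff = runoff, infiltration = water_in - runoff)
}

#' Tipping-bucket redistribution of infiltrated water
#'
#' Cascades water through the profile top-down. Each layer first receives
#' the inflow from above; water above saturation is passed on immediately;
#' of the water held between field capacity and saturation, a fixed
#' fraction (`drain_frac`) drains to the layer below per day. The outflow
#' of the deepest layer is profile-bottom drainage.
#'
#' @param theta per-layer volumetric water content.
#' @param infiltration water entering the surface, mm.
#' @param profile a [soil_profile()].
#' @param drain_frac daily drainage fraction of water held between field
#'   capacity and saturation (Ritchie-style drainage coefficient),
#'   default 0.5.
#' @return list: `theta` (updated), `flux_down` (mm crossing the bottom of
#'   each layer), `drainage` (mm leaving the deepest layer).
#' @export
redistribute <- function(theta, infiltration, profile, drain_frac = 0.5) {
  if (infiltration < 0) stop("infiltration must be >= 0")
  n <- nrow(profile)
  thick <- profile$thickness
  w <- theta_to_mm(theta, thick)
  ws <- theta_to_mm(profile$theta_s, thick)
  wfc <- theta_to_mm(profile$theta_fc, thick)
  flux <- numeric(n)
  inflow <- infiltration
  for (i in seq_len(n)) {
    w[i] <- w[i] + inflow
    inflow <- 0
    if (w[i] > ws[i]) {            # instantaneous spill of supersaturation
      inflow <- w[i] - ws[i]
      w[i] <- ws[i]
    }
    if (w[i] > wfc[i]) {           # slow drainage of the gravity water
      drain <- drain_frac * (w[i] - wfc[i])
      w[i] <- w[i] - drain
      inflow <- inflow + drain
    }
    flux[i] <- inflow
  }
  list(theta = mm_to_theta(w, thick), flux_down = flux, drainage = flux[n])
}

# triangular root density: linearly decreasing to zero at root_depth;
# returns the fraction of roots in each layer (sums to 1 when root_depth>0)
root_fractions <- function(root_depth, profile) {
  if (root_depth <= 0) return(numeric(nrow(profile)))
  cdf <- function(z) {
    z <- pmin(pmax(z, 0), root_depth)
    2 * z / root_depth - (z / root_depth)^2
  }
  cdf(profile$bottom) - cdf(profile$top)
}

# proportional allocation of a demand over layers with weights w_i and
# per-layer caps; water-filling: capped layers drop out and the remainder
# is re-allocated among the rest
allocate_proportional <- function(demand, weights, caps) {
  n <- length(weights)
  taken <- numeric(n)
  active <- weights > 0 & caps > 0
  remaining <- min(demand, sum(caps[weights > 0]))
  while (remaining > 1e-15 && any(active)) {
    share <- weights * active / sum(weights[active])
    alloc <- remaining * share
    over <- active & (taken + alloc >= caps - 1e-15)
    if (!any(over)) {
      taken <- taken + alloc
      remaining <- 0
    } else {
      grab <- pmin(alloc, caps - taken)
      grab[over] <- (caps - taken)[over]
      taken <- taken + grab
      remaining <- remaining - sum(grab)
      active <- active & !over
    }
  }
  taken
}

#' Extract soil evaporation and transpiration from the profile
#'
#' Soil evaporation is drawn from the surface layer only, limited by the
#' water held above a configured air-dry limit. Transpiration is drawn
#' from rooted layers in proportion to root fraction times plant-available
#' water (above wilting point), with per-layer availability caps
#' (water-filling re-allocation when a layer runs dry). Actual never
#' exceeds demand.
#'
#' @param theta per-layer volumetric water content.
#' @param soil_evap_demand,transp_demand mm d^-1, both >= 0.
#' @param root_depth rooting depth, cm.
#' @param profile a [soil_profile()].
#' @param air_dry_frac the air-dry limit of the surface layer as a fraction
#'   of wilting point (default 0.5).
#' @return list: `theta`, `soil_evap`, `transp`, `transp_by_layer` (mm).
#' @export
extract_et <- function(theta, soil_evap_demand, transp_demand, root_depth,
                       profile, air_dry_frac = 0.5) {
  if (soil_evap_demand < 0 || transp_demand < 0) stop("demands must be >= 0")
  thick <- profile$thickness
  w <- theta_to_mm(theta, thick)
  # evaporation: top layer, down to the air-dry limit
  w_airdry <- theta_to_mm(air_dry_frac * profile$theta_wp[1], thick[1])
  evap <- min(soil_evap_demand, max(w[1] - w_airdry, 0))
  w[1] <- w[1] - evap
  # transpiration: rooted layers, above wilting point
  rf <- root_fractions(root_depth, profile)
  avail <- pmax(w - theta_to_mm(profile$theta_wp, thick), 0)
  weights <- rf * avail
  caps <- avail * (rf > 0)
  taken <- allocate_proportional(transp_demand, weights, caps)
  w <- w - taken
  list(theta = mm_to_theta(w, thick), soil_evap = evap,
       transp = sum(taken), transp_by_layer = taken)
}

#' Thickness-weighted water content over reporting intervals
#'
#' Averages the simulated layer water contents over arbitrary reporting
#' depth intervals (e.g. the TDR depths 0-15, 15-30, 30-60, 60-90,
#' 90-120 cm), weighting by the overlap thickness.
#'
#' @param theta per-layer volumetric water content.
#' @param profile a [soil_profile()].
#' @param intervals two-column matrix or data.frame of (top, bottom) in cm.
#' @return numeric vector, one mean content per interval.
#' @export
report_profile <- function(theta, profile, intervals) {
  intervals <- as.matrix(intervals)
  apply(intervals, 1, function(iv) {
    a <- iv[1]; b <- iv[2]
    if (a < min(profile$top) - 1e-9 || b > max(profile$bottom) + 1e-9 || b <= a)
      stop("reporting interval [", a, ", ", b, "] outside simulated domain")
    ov <- pmin(profile$bottom, b) - pmax(profile$top, a)
    ov <- pmax(ov, 0)
    sum(theta * ov) / sum(ov)
  })
}
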