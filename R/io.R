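#' Read and write simulator input files
#'
#' All input files are delimited text (tab-separated, header row, ISO-8601
#' dates). The weather file carries one row per day with the columns of
#' [validate_weather()]; the soil file mirrors the measured profile table
#' (layer bounds, bulk density and retention landmarks); the management
#' file lists dated events.
#'
#' @param path file path.
#' @name io
NULL

#' @describeIn io read and validate a weather file.
#' @export
read_weather_file <- function(path) {
  validate_weather(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @describeIn io write a weather table.
#' @param weather a validated weather data.frame.
#' @export
write_weather_file <- function(weather, path) {
  utils::write.table(validate_weather(weather), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @describeIn io read a soil profile file (columns `top`, `bottom`,
#'   `bulk_density`, `theta_fc`, `theta_wp`, `theta_s`; extra columns such
#'   as texture fractions or pH are carried along).
#' @export
read_soil_file <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("top", "bottom", "bulk_density", "theta_s", "theta_fc",
           "theta_wp")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("soil file missing columns: ",
                         paste(miss, collapse = ", "))
  soil_profile(d$top, d$bottom, d$bulk_density, d$theta_s, d$theta_fc,
               d$theta_wp)
}

#' @describeIn io write a soil profile.
#' @param profile a [soil_profile()].
#' @export
write_soil_file <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @describeIn io read a management event file (columns `date`, `type`,
#'   `crop`, `amount`, `incorporated`).
#' @export
read_management_file <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("date", "type", "crop", "amount")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("management file missing columns: ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unique(d$type),
                 c("irrigation", "urea", "manure", "sowing", "harvest"))
  if (length(bad)) stop("unknown event types: ", paste(bad, collapse = ", "))
  if (any(d$amount < 0)) stop("negative event amounts")
  d$date <- as.Date(d$date)
  if (!("incorporated" %in% names(d))) d$incorporated <- FALSE
  d$incorporated <- as.logical(d$incorporated)
  d
}

#' @describeIn io write a management event table.
#' @param management event data.frame.
#' @export
write_management_file <- function(management, path) {
  utils::write.table(management, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @describeIn io write the daily simulation record of a
#'   [run_rotation()] result.
#' @param run a `rotation_run`.
#' @export
write_daily_output <- function(run, path) {
  utils::write.table(run$daily, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
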