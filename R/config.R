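#' Analysis configuration
#'
#' Bundles the tunable constants of the analysis chain. Defaults
#' reflect the drive-hunt monitoring design: dual GPS regimes (2-min
#' fixes on hunt days, hourly otherwise), day defined as 08:00-18:00
#' local clock time, dawn at 08:00, a 6-day (144 h) censoring horizon
#' for return times and a 72-h short-return threshold.
#'
#' @param tz study time zone in which civil clock times (dawn,
#'   day/night bounds) are evaluated; timestamps themselves are UTC.
#' @param day_start_hour,day_end_hour local clock hours bounding the
#'   "day" period (day = `[day_start_hour, day_end_hour)`, night the
#'   complement).
#' @param dawn_hour local clock hour of dawn, the endpoint of the
#'   delayed-phase window.
#' @param censor_horizon_h censoring horizon for return times, hours.
#' @param short_return_h threshold splitting short vs long return
#'   times, hours; must not exceed `censor_horizon_h`.
#' @param immediate_interval_min nominal fix interval during hunts,
#'   minutes.
#' @param delayed_interval_min nominal fix interval outside hunt
#'   windows, minutes.
#' @param gap_tolerance_factor a step longer than this multiple of the
#'   nominal interval is flagged as spanning a fix gap.
#' @param ud_cell_m utilization-distribution grid cell size, metres.
#' @param ud_bandwidth `"reference"` for the ad hoc bivariate normal
#'   rule, or `"fixed_value"` with `ud_bandwidth_value`.
#' @param ud_bandwidth_value fixed kernel sd in metres when
#'   `ud_bandwidth = "fixed_value"`.
#' @param delayed_from origin of the delayed-distance window:
#'   `"hunt_start"` (default) or `"hunt_end"`.
#' @param boundary_buffer_m classification buffer: a fix counts as
#'   outside the hunted area only beyond this distance from the
#'   boundary (e.g. the GPS location error, 5.8 m). Default 0.
#' @param min_fix_fraction events whose hunt window holds fewer than
#'   this fraction of expected fixes are left unclassified.
#' @param crs_id identifier of the projected CRS the coordinates are
#'   expressed in (metadata only; coordinates must already be metric).
#' @return an object of class `hm_config` (a named list).
#' @export
analysis_config <- function(tz = "Europe/Paris",
                            day_start_hour = 8, day_end_hour = 18,
                            dawn_hour = 8,
                            censor_horizon_h = 144,
                            short_return_h = 72,
                            immediate_interval_min = 2,
                            delayed_interval_min = 60,
                            gap_tolerance_factor = 2,
                            ud_cell_m = 10,
                            ud_bandwidth = c("reference", "fixed_value"),
                            ud_bandwidth_value = NULL,
                            delayed_from = c("hunt_start", "hunt_end"),
                            boundary_buffer_m = 0,
                            min_fix_fraction = 0.5,
                            crs_id = "EPSG:2154") {
  ud_bandwidth <- match.arg(ud_bandwidth)
  delayed_from <- match.arg(delayed_from)
  stopifnot(censor_horizon_h > 0, short_return_h > 0,
            short_return_h <= censor_horizon_h,
            immediate_interval_min > 0, delayed_interval_min > 0,
            gap_tolerance_factor > 0, ud_cell_m > 0,
            min_fix_fraction >= 0, min_fix_fraction <= 1,
            boundary_buffer_m >= 0)
  if (ud_bandwidth == "fixed_value" &&
      (is.null(ud_bandwidth_value) || ud_bandwidth_value <= 0))
    stop("ud_bandwidth_value must be a positive bandwidth in metres")
  structure(list(
    tz = tz, day_start_hour = day_start_hour, day_end_hour = day_end_hour,
    dawn_hour = dawn_hour, censor_horizon_h = censor_horizon_h,
    short_return_h = short_return_h,
    immediate_interval_min = immediate_interval_min,
    delayed_interval_min = delayed_interval_min,
    gap_tolerance_factor = gap_tolerance_factor,
    ud_cell_m = ud_cell_m, ud_bandwidth = ud_bandwidth,
    ud_bandwidth_value = ud_bandwidth_value,
    delayed_from = delayed_from, boundary_buffer_m = boundary_buffer_m,
    min_fix_fraction = min_fix_fraction, crs_id = crs_id),
    class = "hm_config")
}

#' @exportS3Method base::print
print.hm_config <- function(x, ...) {
  cat("<hm_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-24s %s\n", nm,
                if (is.null(v)) "NULL" else paste(format(v), collapse = ", ")))
  }
  invisible(x)
}

# local clock hour (fractional) of UTC timestamps in the study tz
local_hour <- function(t, config) {
  lt <- as.POSIXlt(t, tz = config$tz)
  lt$hour + lt$min / 60 + lt$sec / 3600
}

# first timestamp at local clock `hour` strictly after `t`
next_local_hour <- function(t, hour, config) {
  lt <- as.POSIXlt(t, tz = config$tz)
  cand <- as.POSIXct(sprintf("%04d-%02d-%02d %02d:00:00",
                             lt$year + 1900L, lt$mon + 1L, lt$mday, hour),
                     tz = config$tz)
  if (as.numeric(cand) <= as.numeric(t)) cand <- cand + 86400
  as.POSIXct(as.numeric(cand), origin = "1970-01-01", tz = "UTC")
}
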