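# Step-level and window-level movement metrics.

#' Build a step series from a trajectory window
#'
#' A step joins two consecutive valid fixes. Steps whose duration
#' exceeds `gap_tolerance_factor` times the nominal fix interval are
#' flagged `spans_gap`; turning angles are defined only between
#' consecutive non-gap steps (a composite step across a missing fix
#' would bias the angle distribution).
#'
#' @param traj an `hm_traj`.
#' @param from,to optional window bounds (POSIXct, inclusive).
#' @param nominal_interval_min nominal fix interval in minutes.
#' @param gap_tolerance_factor multiple of the nominal interval beyond
#'   which a step is flagged as spanning a gap.
#' @return an object of class `hm_steps`: data frame with columns
#'   `t0`, `t1`, `duration_min`, `length_m`, `heading`, `turn`
#'   (radians in `(-pi, pi]`, `NA` where undefined) and `spans_gap`.
#'   Fewer than two valid fixes yield a zero-row series, not an error.
#' @export
build_steps <- function(traj, from = NULL, to = NULL,
                        nominal_interval_min = 2,
                        gap_tolerance_factor = 2) {
  vf <- valid_fixes(traj, from, to)
  empty <- data.frame(t0 = as.POSIXct(character(), tz = "UTC"),
                      t1 = as.POSIXct(character(), tz = "UTC"),
                      duration_min = numeric(0), length_m = numeric(0),
                      heading = numeric(0), turn = numeric(0),
                      spans_gap = logical(0))
  n <- nrow(vf)
  if (n < 2L) {
    class(empty) <- c("hm_steps", "data.frame")
    attr(empty, "nominal_interval_min") <- nominal_interval_min
    return(empty)
  }
  dx <- diff(vf$x); dy <- diff(vf$y)
  dur <- as.numeric(difftime(vf$timestamp[-1L], vf$timestamp[-n],
                             units = "mins"))
  len <- sqrt(dx^2 + dy^2)
  heading <- atan2(dy, dx)
  # a step reaching factor x nominal means at least one scheduled fix
  # is missing, so the 4-min step left by one dropped 2-min fix flags
  spans_gap <- dur >= gap_tolerance_factor * nominal_interval_min - 1e-9
  turn <- rep(NA_real_, n - 1L)
  if (n >= 3L) {
    dth <- heading[-1L] - heading[-(n - 1L)]
    dth <- ((dth + pi) %% (2 * pi)) - pi          # wrap to (-pi, pi]
    dth[dth == -pi] <- pi
    ok <- !spans_gap[-1L] & !spans_gap[-(n - 1L)] &
      len[-1L] > 0 & len[-(n - 1L)] > 0           # undefined for zero steps
    turn[-1L][ok] <- dth[ok]
  }
  out <- data.frame(t0 = vf$timestamp[-n], t1 = vf$timestamp[-1L],
                    duration_min = dur, length_m = len,
                    heading = heading, turn = turn, spans_gap = spans_gap)
  class(out) <- c("hm_steps", "data.frame")
  attr(out, "nominal_interval_min") <- nominal_interval_min
  out
}

#' Trajectory sinuosity: mean cosine of turning angles
#'
#' 1 represents straight-line movement, 0 Brownian-like motion and
#' negative values systematic back-tracking. Only turning angles
#' defined between consecutive non-gap steps enter the mean.
#'
#' @param steps an `hm_steps`.
#' @return mean cosine in `[-1, 1]`, or `NA` (with a warning) when no
#'   turning angle is defined.
#' @export
sinuosity <- function(steps) {
  tu <- steps$turn[!is.na(steps$turn)]
  if (!length(tu)) {
    warning("sinuosity undefined: no defined turning angle")
    return(NA_real_)
  }
  mean(cos(tu))
}

#' Maximum step speed in km/h
#'
#' Maximum over non-gap steps of length divided by the actual step
#' duration (so irregular fix spacing is handled correctly).
#'
#' @param steps an `hm_steps`.
#' @return speed in km/h, or `NA` (with a warning) for an empty
#'   series.
#' @export
max_speed <- function(steps) {
  s <- steps[!steps$spans_gap & steps$duration_min > 0, , drop = FALSE]
  if (!nrow(s)) {
    warning("max_speed undefined: no non-gap step")
    return(NA_real_)
  }
  max(s$length_m / s$duration_min) * 60 / 1000
}

#' Cumulative distance of a step series
#'
#' Sum of all step lengths, gap-spanning steps included (their count
#' is attached as attribute `n_gap_steps`). Empty series sum to 0.
#'
#' @param steps an `hm_steps`.
#' @return total distance in metres.
#' @export
cumulative_distance <- function(steps) {
  structure(sum(steps$length_m), n_gap_steps = sum(steps$spans_gap))
}

#' Net displacement from a reference point at requested times
#'
#' Euclidean distance from `reference` to the valid fix nearest each
#' requested timestamp, provided that fix lies within `tol_min`
#' minutes (default half the nominal interval); `NA` otherwise.
#'
#' @param traj an `hm_traj`.
#' @param reference numeric length-2 reference point (metres).
#' @param times POSIXct vector of requested timestamps.
#' @param nominal_interval_min nominal fix interval, minutes.
#' @param tol_min matching tolerance, minutes.
#' @return numeric vector of distances (metres), `NA` where no fix is
#'   close enough.
#' @export
net_displacement <- function(traj, reference, times,
                             nominal_interval_min = 60,
                             tol_min = nominal_interval_min / 2) {
  stopifnot(length(reference) == 2L, all(is.finite(reference)))
  vf <- valid_fixes(traj)
  if (!nrow(vf)) return(rep(NA_real_, length(times)))
  tv <- as.numeric(vf$timestamp)
  tq <- as.numeric(times)
  idx <- findInterval(tq, tv)
  lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, length(tv))
  pick <- ifelse(abs(tq - tv[lo]) <= abs(tq - tv[hi]), lo, hi)
  ok <- abs(tq - tv[pick]) <= tol_min * 60
  d <- sqrt((vf$x[pick] - reference[1L])^2 + (vf$y[pick] - reference[2L])^2)
  d[!ok] <- NA_real_
  d
}

# half-day periods tiling the 5-day window centred on the hunt day
profile_periods <- function(hunt_start, config) {
  lt <- as.POSIXlt(hunt_start, tz = config$tz)
  day0 <- as.POSIXct(sprintf("%04d-%02d-%02d %02d:00:00",
                             lt$year + 1900L, lt$mon + 1L, lt$mday,
                             config$day_start_hour), tz = config$tz)
  utc <- function(t) as.POSIXct(as.numeric(t), origin = "1970-01-01",
                                tz = "UTC")
  out <- list()
  for (off in -2:2) {
    d0 <- day0 + off * 86400
    day_len <- (config$day_end_hour - config$day_start_hour) * 3600
    out[[length(out) + 1L]] <- list(
      label = sprintf("day%+d day", off), offset = off, phase = "day",
      from = utc(d0), to = utc(d0 + day_len))
    out[[length(out) + 1L]] <- list(
      label = sprintf("day%+d night", off), offset = off, phase = "night",
      from = utc(d0 + day_len), to = utc(d0 + 86400))
  }
  out
}

#' Net-displacement profile over the 5-day window around hunts
#'
#' For each hunting event, net displacement from the encounter point
#' (the animal's position at hunt start) is evaluated at every valid
#' fix within each half-day period (day = 08:00-18:00 local, night =
#' 18:00-08:00) of the 5-day window centred on the hunt day; the
#' per-event median is then summarized across events (median and
#' quartiles) separately for the fleeing and staying groups. Periods
#' that end before the hunt starts are labelled baseline.
#'
#' @param events classified event table (see [build_event_table()]).
#' @param trajectories named list of `hm_traj`.
#' @param config an [analysis_config()].
#' @return data frame with one row per group x period: `group`,
#'   `period`, `offset_days`, `phase`, `baseline`, `median_m`, `q1_m`,
#'   `q3_m`, `n_events`. Groups without events are omitted with a
#'   warning.
#' @export
displacement_profile <- function(events, trajectories,
                                 config = analysis_config()) {
  trajectories <- name_by_id(trajectories)
  ev <- events[!is.na(events$classification), , drop = FALSE]
  out <- list()
  for (grp in c("fleeing", "staying")) {
    eg <- ev[ev$classification == grp, , drop = FALSE]
    if (!nrow(eg)) {
      warning("displacement_profile: no events in group '", grp, "'")
      next
    }
    percell <- list()
    for (i in seq_len(nrow(eg))) {
      tr <- trajectories[[eg$individual_id[i]]]
      pers <- profile_periods(eg$t_start[i], config)
      for (p in pers) {
        vf <- valid_fixes(tr, p$from, p$to)
        if (!nrow(vf)) next
        d <- sqrt((vf$x - eg$x0[i])^2 + (vf$y - eg$y0[i])^2)
        key <- p$label
        percell[[key]] <- c(percell[[key]], stats::median(d))
      }
    }
    pers <- profile_periods(eg$t_start[1L], config)
    for (p in pers) {
      v <- percell[[p$label]]
      if (is.null(v)) next
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        group = grp, period = p$label, offset_days = p$offset,
        phase = p$phase, baseline = p$offset < 0,
        median_m = q[2L], q1_m = q[1L], q3_m = q[3L], n_events = length(v))
    }
  }
  if (!length(out)) return(data.frame())
  do.call(rbind, out)
}
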