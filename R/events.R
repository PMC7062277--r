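# Hunting-event detection, flee/stay classification and the
# immediate/delayed distance responses.

#' Detect hunting events
#'
#' A hunting event is the presence of a monitored individual within
#' the limits of the hunted area during a drive hunt. Membership is
#' decided at hunt start: the individual's valid fix nearest the hunt
#' start (within half the immediate fix interval) must lie inside the
#' hunted polygon (boundary counts as inside); that fix becomes the
#' encounter point. Individuals with no valid fix near the start are
#' skipped for that hunt.
#'
#' @param trajectories named list of `hm_traj`.
#' @param hunts hunt data frame (see [read_hunts()]).
#' @param areas named list of `hm_area`.
#' @param config an [analysis_config()].
#' @return event data frame, one row per (individual, hunt) pair with
#'   the individual inside at hunt start: `event_id`,
#'   `individual_id`, `hunt_id`, `area_id`, `t_start`, `t_end`, `x0`,
#'   `y0`, effort/habitat covariates (`bush`, `dogs_per_ha`,
#'   `beaters_per_ha`, `gunshots`) and placeholder columns
#'   (`classification`, `fam`, distances) filled by later stages.
#' @export
detect_events <- function(trajectories, hunts, areas,
                          config = analysis_config()) {
  trajectories <- name_by_id(trajectories)
  rows <- list()
  tol_s <- config$immediate_interval_min * 60 / 2
  for (hi in seq_len(nrow(hunts))) {
    h <- hunts[hi, ]
    area <- areas[[h$area_id]]
    if (is.null(area)) stop("reference error: unknown area '", h$area_id, "'")
    for (id in names(trajectories)) {
      tr <- trajectories[[id]]
      vf <- valid_fixes(tr)
      if (!nrow(vf)) next
      dt <- abs(as.numeric(vf$timestamp) - as.numeric(h$start))
      k <- which.min(dt)
      if (dt[k] > tol_s) next                      # no fix near hunt start
      if (!point_in_polygon(vf$x[k], vf$y[k], area$polygon)) next
      rows[[length(rows) + 1L]] <- data.frame(
        event_id = paste0(h$hunt_id, ":", id),
        individual_id = id, hunt_id = h$hunt_id, area_id = h$area_id,
        t_start = h$start, t_end = h$end,
        x0 = vf$x[k], y0 = vf$y[k],
        bush = if ("bush_fraction" %in% names(h)) h$bush_fraction else NA_real_,
        dogs_per_ha = if ("dogs_per_ha" %in% names(h)) h$dogs_per_ha else NA_real_,
        beaters_per_ha = if ("beaters_per_ha" %in% names(h)) h$beaters_per_ha else NA_real_,
        gunshots = if ("n_gunshots" %in% names(h)) h$n_gunshots else NA_real_,
        fam = NA_real_, classification = NA_character_,
        dist_immediate = NA_real_, dist_delayed = NA_real_,
        speed_max_kmh = NA_real_, sinuosity = NA_real_,
        n_gap_steps = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(event_id = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify the immediate response of one hunting event
#'
#' Fleeing means crossing the shooting line, identified with the
#' hunted-area boundary: an event is `"fleeing"` iff any valid fix
#' strictly outside the polygon (beyond the configured boundary
#' buffer) occurs within the hunt window, `"staying"` otherwise. A fix
#' exactly on the boundary has not crossed the line and counts as
#' inside. Events whose window holds fewer than 2 valid fixes, or
#' fewer than `min_fix_fraction` of the expected fixes, are
#' unclassifiable (`NA` with a warning).
#'
#' @param event one event row (see [detect_events()]).
#' @param trajectory the individual's `hm_traj`.
#' @param area the event's `hm_area`.
#' @param config an [analysis_config()].
#' @return `"fleeing"`, `"staying"` or `NA_character_`.
#' @export
classify_event <- function(event, trajectory, area,
                           config = analysis_config()) {
  vf <- valid_fixes(trajectory, event$t_start, event$t_end)
  dur_min <- as.numeric(difftime(event$t_end, event$t_start, units = "mins"))
  expected <- floor(dur_min / config$immediate_interval_min) + 1
  if (nrow(vf) < 2L || nrow(vf) < config$min_fix_fraction * expected) {
    warning("event ", event$event_id, " unclassifiable: ",
            nrow(vf), " valid fixes in hunt window")
    return(NA_character_)
  }
  sd <- signed_distance(vf$x, vf$y, area$polygon)
  if (any(sd > config$boundary_buffer_m + 1e-9)) "fleeing" else "staying"
}

#' Immediate distance response (DistI)
#'
#' Total cumulative distance covered during the drive hunt: the sum
#' of 2-min step lengths between hunt start and end.
#'
#' @inheritParams classify_event
#' @param trajectory the individual's `hm_traj`.
#' @return distance in metres (attribute `n_gap_steps` counts steps
#'   spanning fix gaps).
#' @export
immediate_distance <- function(event, trajectory,
                               config = analysis_config()) {
  st <- build_steps(trajectory, event$t_start, event$t_end,
                    nominal_interval_min = config$immediate_interval_min,
                    gap_tolerance_factor = config$gap_tolerance_factor)
  cumulative_distance(st)
}

#' Delayed distance response (DistD)
#'
#' Total cumulative distance covered up to the first dawn (08:00
#' local) after the hunt, summing hourly step lengths from the
#' configured origin (hunt start by default, hunt end optionally).
#' The trajectory is resampled to the hourly grid (valid fix nearest
#' each hour mark, within half the hourly interval) before summation,
#' so the 2-min fixes recorded during the hunt itself contribute
#' hourly steps, not 2-min steps.
#'
#' @inheritParams immediate_distance
#' @return distance in metres; attribute `partial` is `TRUE` (with a
#'   warning) when the trajectory ends before the first dawn.
#' @export
delayed_distance <- function(event, trajectory,
                             config = analysis_config()) {
  origin <- if (config$delayed_from == "hunt_start") event$t_start else
    event$t_end
  dawn <- next_local_hour(event$t_end, config$dawn_hour, config)
  marks <- seq(as.numeric(origin), as.numeric(dawn), by = 3600)
  if (marks[length(marks)] < as.numeric(dawn))
    marks <- c(marks, as.numeric(dawn))
  vf <- valid_fixes(trajectory)
  partial <- !nrow(vf) || max(as.numeric(vf$timestamp)) < as.numeric(dawn)
  if (partial)
    warning("event ", event$event_id,
            ": trajectory ends before first dawn; delayed distance partial")
  if (!nrow(vf)) return(structure(NA_real_, partial = TRUE))
  tv <- as.numeric(vf$timestamp)
  idx <- findInterval(marks, tv)
  lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, length(tv))
  pick <- ifelse(abs(marks - tv[lo]) <= abs(marks - tv[hi]), lo, hi)
  ok <- abs(marks - tv[pick]) <= config$delayed_interval_min * 60 / 2
  pick <- unique(pick[ok])
  if (length(pick) < 2L) return(structure(NA_real_, partial = partial))
  d <- sum(sqrt(diff(vf$x[pick])^2 + diff(vf$y[pick])^2))
  structure(d, partial = partial)
}

#' Classify all events and fill in their movement responses
#'
#' Convenience wrapper applying [classify_event()],
#' [immediate_distance()], [delayed_distance()], [max_speed()] and
#' [sinuosity()] to every detected event, and joining the familiarity
#' index when isopleth sets are supplied.
#'
#' @param events event table from [detect_events()].
#' @param trajectories named list of `hm_traj`.
#' @param areas named list of `hm_area`.
#' @param config an [analysis_config()].
#' @param isopleths optional named list (by individual) of
#'   `hm_isopleths` used to fill the `fam` covariate.
#' @return the event table with `classification`, `dist_immediate`,
#'   `dist_delayed`, `speed_max_kmh`, `sinuosity`, `n_gap_steps` and
#'   (optionally) `fam` filled.
#' @export
build_event_table <- function(events, trajectories, areas,
                              config = analysis_config(),
                              isopleths = NULL) {
  if (!nrow(events)) return(events)
  trajectories <- name_by_id(trajectories)
  fam_cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    tr <- trajectories[[ev$individual_id]]
    area <- areas[[ev$area_id]]
    events$classification[i] <- tryCatch(
      classify_event(ev, tr, area, config),
      warning = function(w) NA_character_)
    di <- immediate_distance(ev, tr, config)
    events$dist_immediate[i] <- as.numeric(di)
    events$n_gap_steps[i] <- attr(di, "n_gap_steps")
    events$dist_delayed[i] <- suppressWarnings(
      as.numeric(delayed_distance(ev, tr, config)))
    st <- build_steps(tr, ev$t_start, ev$t_end,
                      nominal_interval_min = config$immediate_interval_min,
                      gap_tolerance_factor = config$gap_tolerance_factor)
    events$speed_max_kmh[i] <- suppressWarnings(max_speed(st))
    events$sinuosity[i] <- suppressWarnings(sinuosity(st))
    if (!is.null(isopleths)) {
      key <- paste0(ev$individual_id, "|", ev$area_id)
      if (is.null(fam_cache[[key]])) {
        iso <- isopleths[[ev$individual_id]]
        fam_cache[[key]] <- if (is.null(iso)) NA_real_ else
          as.numeric(familiarity_index(iso, area))
      }
      events$fam[i] <- fam_cache[[key]]
    }
  }
  events
}
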