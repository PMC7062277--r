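# Censored return-time construction (post-hunt and reversed-time
# control), Kaplan-Meier estimation and the 72-h short-return
# dichotomy.

return_record <- function(event_id, individual_id, condition, duration_h,
                          censored, threshold_h = 72) {
  data.frame(event_id = event_id, individual_id = individual_id,
             condition = condition, duration = duration_h,
             censored = censored,
             short_return = short_return_indicator(duration_h, censored,
                                                   threshold_h),
             stringsAsFactors = FALSE)
}

#' Post-hunt return time of one hunting event
#'
#' The clock starts at the animal's first valid fix outside the
#' hunted polygon at or after hunt start (for stayers this is the
#' first exit after the hunt ends) and stops at the first subsequent
#' valid fix back inside. If no inside fix occurs within the
#' censoring horizon (144 h by default) the record is censored at the
#' horizon.
#'
#' @param event one classified event row.
#' @param trajectory the individual's `hm_traj`.
#' @param area the event's `hm_area`.
#' @param config an [analysis_config()].
#' @return one-row `ReturnRecord` data frame (`event_id`,
#'   `individual_id`, `condition = "post_hunt"`, `duration` in hours,
#'   `censored`, `short_return`), or `NULL` (with a warning) when the
#'   animal never exits within the horizon.
#' @export
forward_return_time <- function(event, trajectory, area,
                                config = analysis_config()) {
  vf <- valid_fixes(trajectory, from = event$t_start)
  if (!nrow(vf)) {
    warning("event ", event$event_id, ": no post-hunt fixes")
    return(NULL)
  }
  inside <- point_in_polygon(vf$x, vf$y, area$polygon)
  horizon_s <- config$censor_horizon_h * 3600
  exit_k <- which(!inside)[1L]
  if (is.na(exit_k) ||
      as.numeric(vf$timestamp[exit_k]) - as.numeric(event$t_start) > horizon_s) {
    warning("event ", event$event_id,
            ": animal never exited the hunted area within the horizon")
    return(NULL)
  }
  t0 <- as.numeric(vf$timestamp[exit_k])
  back <- which(inside & as.numeric(vf$timestamp) > t0)
  back <- back[as.numeric(vf$timestamp[back]) - t0 <= horizon_s]
  if (length(back)) {
    dur <- (as.numeric(vf$timestamp[back[1L]]) - t0) / 3600
    return_record(event$event_id, event$individual_id, "post_hunt",
                  dur, FALSE, config$short_return_h)
  } else {
    return_record(event$event_id, event$individual_id, "post_hunt",
                  config$censor_horizon_h, TRUE, config$short_return_h)
  }
}

#' Control (pre-hunt) return time of one hunting event
#'
#' The undisturbed counterpart of [forward_return_time()], computed
#' on a reversed time scale starting at hunt start (when the animal
#' is inside the area): the entry fix of the presence spell
#' containing hunt start is located (first inside fix after the last
#' outside fix before the hunt), then the exit fix: the last inside
#' fix before the preceding absence spell (the animal left the area
#' between that fix and the first outside one); the duration is the
#' gap between exit and entry fixes. If
#' the animal was continuously inside over the whole horizon, or the
#' exit lies beyond the horizon, the record is censored at the
#' horizon.
#'
#' @inheritParams forward_return_time
#' @return one-row `ReturnRecord` data frame with
#'   `condition = "control"`, or `NULL` (with a warning) when the
#'   pre-hunt history is shorter than the censoring horizon.
#' @export
control_return_time <- function(event, trajectory, area,
                                config = analysis_config()) {
  horizon_s <- config$censor_horizon_h * 3600
  t_start <- as.numeric(event$t_start)
  vf <- valid_fixes(trajectory, to = event$t_start)
  if (!nrow(vf) ||
      t_start - min(as.numeric(vf$timestamp)) < horizon_s) {
    warning("event ", event$event_id,
            ": pre-hunt history shorter than the censoring horizon")
    return(NULL)
  }
  inside <- point_in_polygon(vf$x, vf$y, area$polygon)
  tv <- as.numeric(vf$timestamp)
  out_ix <- which(!inside)
  if (!length(out_ix)) {
    # continuously present over the whole record
    return(return_record(event$event_id, event$individual_id, "control",
                         config$censor_horizon_h, TRUE,
                         config$short_return_h))
  }
  last_out <- max(out_ix)
  entry_candidates <- which(inside & seq_along(inside) > last_out)
  if (!length(entry_candidates)) {
    warning("event ", event$event_id,
            ": animal outside the area just before hunt start")
    return(NULL)
  }
  entry_k <- min(entry_candidates)
  # walk back to the start of the absence spell preceding this entry;
  # the exit fix is the last inside fix before it (the animal left the
  # area between that fix and the first outside one)
  spell_out <- out_ix[out_ix < entry_k]
  spell_start <- spell_out[length(spell_out)]
  while (length(spell_out) > 1L &&
         spell_out[length(spell_out) - 1L] == spell_start - 1L) {
    spell_out <- spell_out[-length(spell_out)]
    spell_start <- spell_out[length(spell_out)]
  }
  exit_k <- max(spell_start - 1L, 1L)
  dur <- (tv[entry_k] - tv[exit_k]) / 3600
  if (t_start - tv[exit_k] > horizon_s || dur > config$censor_horizon_h) {
    return_record(event$event_id, event$individual_id, "control",
                  config$censor_horizon_h, TRUE, config$short_return_h)
  } else {
    return_record(event$event_id, event$individual_id, "control",
                  dur, FALSE, config$short_return_h)
  }
}

#' Kaplan-Meier estimate of the return-time curve
#'
#' Product-limit estimator over the (possibly censored) return
#' durations, with a Greenwood-variance 95% band (log transform),
#' computed with the survival package.
#'
#' @param records `ReturnRecord` data frame.
#' @param condition optional condition filter (`"post_hunt"` or
#'   `"control"`).
#' @return object of class `hm_km`: data frame with `time` (hours),
#'   `surv`, `lower`, `upper`, `n_risk`, `n_event`, plus attributes
#'   `n` and `median_h` (smallest time with S(t) <= 0.5, `NA` when
#'   the curve never reaches 0.5).
#' @export
km_estimate <- function(records, condition = NULL) {
  if (!is.null(condition))
    records <- records[records$condition == condition, , drop = FALSE]
  if (!nrow(records)) stop("no records to estimate from")
  fit <- survival::survfit(
    survival::Surv(records$duration, !records$censored) ~ 1,
    conf.type = "log")
  out <- data.frame(time = fit$time, surv = fit$surv,
                    lower = fit$lower, upper = fit$upper,
                    n_risk = fit$n.risk, n_event = fit$n.event)
  med <- out$time[out$surv <= 0.5][1L]
  structure(out, class = c("hm_km", "data.frame"),
            n = nrow(records), median_h = if (is.na(med)) NA_real_ else med)
}

#' Kaplan-Meier median
#' @param km an `hm_km` from [km_estimate()].
#' @return median return time in hours (`NA` if the curve never
#'   crosses 0.5).
#' @export
km_median <- function(km) attr(km, "median_h")

#' Short-return indicator
#'
#' Binary coding of return times around the 72-h threshold: an
#' uncensored duration shorter than the threshold codes as 0, a
#' duration of at least the threshold (uncensored, or censored at or
#' beyond it) codes as 1, and a record censored before the threshold
#' is unresolvable (`NA`).
#'
#' @param duration_h return duration in hours (vectorized).
#' @param censored logical.
#' @param threshold_h dichotomy threshold, hours.
#' @return integer 0/1/`NA`.
#' @export
short_return_indicator <- function(duration_h, censored, threshold_h = 72) {
  ifelse(duration_h >= threshold_h, 1L,
         ifelse(!censored, 0L, NA_integer_))
}

#' Build the return-record table for all events
#'
#' Applies [forward_return_time()] and [control_return_time()] to
#' every classified event and stacks the results, carrying the `fam`
#' covariate over for the short-return model.
#'
#' @param events classified event table.
#' @param trajectories named list of `hm_traj`.
#' @param areas named list of `hm_area`.
#' @param config an [analysis_config()].
#' @return `ReturnRecord` data frame with a `fam` column.
#' @export
build_return_table <- function(events, trajectories, areas,
                               config = analysis_config()) {
  trajectories <- name_by_id(trajectories)
  rows <- list()
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    if (is.na(ev$classification)) next
    tr <- trajectories[[ev$individual_id]]
    area <- areas[[ev$area_id]]
    for (f in list(forward_return_time, control_return_time)) {
      r <- suppressWarnings(f(ev, tr, area, config))
      if (!is.null(r)) {
        r$fam <- ev$fam
        rows[[length(rows) + 1L]] <- r
      }
    }
  }
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
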