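# Synthetic herd-and-hunt generator.
#
# Generates GPS trajectories, hunted areas and hunt logs with the
# statistical structure the analysis assumes, together with
# ground-truth labels, so that every stage of the pipeline can be
# validated without field data. Behaviour branches (flee vs stay),
# kinematic scales and return-lag distributions are calibrated to the
# field-reported drive-hunt monitoring values; see generator_config().

#' Generator configuration
#'
#' Defaults emulate the drive-hunt monitoring design: 14 collared
#' individuals with ~561 ha annual ranges, 23 weekly hunt days of 4-6
#' one-hour drives over areas averaging 101 ha, a 0.68 flee
#' probability, post-hunt vs control return-lag medians of 34 h vs
#' 17 h with 38% vs 12% non-return mass beyond 144 h, GPS error of
#' 5.8 m (median radial) and fix success 82% (2-min regime) / 86%
#' (hourly).
#'
#' @param n_individuals number of collared individuals.
#' @param hr_mean_ha,hr_sd_ha annual home-range size distribution
#'   (truncated normal), hectares.
#' @param n_hunt_days number of weekly hunt days in the season.
#' @param hunts_per_day integer range of drives per hunt day.
#' @param hunt_duration_min drive duration, minutes.
#' @param area_mean_ha,area_sd_ha,area_range_ha hunted-area size
#'   distribution (truncated normal on the range), hectares.
#' @param flee_probability probability that an exposed individual
#'   flees during the drive.
#' @param flee_speed_kmh,speed_sdlog flight-phase step-speed scale
#'   (log-normal median) and log-sd; calibrated so the median maximum
#'   2-min speed of fleeing events is near 18 km/h.
#' @param flee_heading_sd flight-phase heading noise, radians.
#' @param flee_exit_clearance_m flight continues until this far beyond
#'   the boundary.
#' @param postexit_speed_kmh,postexit_sdlog,postexit_heading_sd
#'   post-exit wandering kinematics of fleers.
#' @param stay_slow_kmh,stay_slow_sdlog,stay_burst_prob,
#'   stay_burst_kmh,stay_burst_sdlog staying-branch kinematics: slow
#'   tortuous movement with occasional flushes, calibrated so the
#'   median maximum speed is near 10 km/h and the median cumulative
#'   hunt-hour distance near 1 km.
#' @param stay_turn_sd heading-reversal noise (radians) of the
#'   staying branch; gives a mean turning-angle cosine near -0.29.
#' @param interior_margin_m staying paths keep this distance from the
#'   boundary so GPS noise cannot carry a fix across it.
#' @param dawn_displacement_m net displacement from the encounter site
#'   reached by the first dawn (both branches).
#' @param distd_flee_m,distd_stay_m target cumulative hourly distances
#'   by first dawn per branch.
#' @param post_return_median_h,post_nonreturn_mass overall median of
#'   the post-hunt return lag and probability of no return within
#'   144 h. Lags are a mixture: a non-return branch with the given
#'   mass, plus a log-normal returner branch whose meanlog is solved
#'   so the overall median equals `post_return_median_h` (the
#'   quantity the Kaplan-Meier stage recovers).
#' @param post_lag_sdlog log-sd of the returner branch; kept tight so
#'   that recovering the configured median at a few hundred events is
#'   a sharp test, and reproducing the clearly bimodal split between
#'   returns within days and non-returns.
#' @param control_median_h,control_nonreturn_mass,control_lag_sdlog
#'   same for the undisturbed control spells.
#' @param bush_range,gunshot_range understorey fraction and gunshot
#'   count ranges (uniform draws).
#' @param beater_range,dog_range,shooter_range crew-size ranges per
#'   drive (uniform integer draws; per-hectare densities derive from
#'   counts and area).
#' @param gps_noise_m median radial GPS error, metres.
#' @param fix_success_2min,fix_success_hourly fix success per regime.
#' @param season_start,season_end,capture_date study calendar (local
#'   dates).
#' @param landscape_m side of the square study landscape, metres.
#' @param ou_tau_h home-range attraction time scale of the
#'   Ornstein-Uhlenbeck walk, hours.
#' @return object of class `hm_genconfig` (named list).
#' @export
generator_config <- function(n_individuals = 14L,
                             hr_mean_ha = 561.1, hr_sd_ha = 282.5,
                             n_hunt_days = 23L,
                             hunts_per_day = c(4L, 6L),
                             hunt_duration_min = 60,
                             area_mean_ha = 101, area_sd_ha = 30,
                             area_range_ha = c(47, 201),
                             flee_probability = 0.68,
                             flee_speed_kmh = 16, speed_sdlog = 0.25,
                             flee_heading_sd = 0.25,
                             flee_exit_clearance_m = 120,
                             postexit_speed_kmh = 3,
                             postexit_sdlog = 0.5,
                             postexit_heading_sd = 0.8,
                             stay_slow_kmh = 0.5, stay_slow_sdlog = 0.6,
                             stay_burst_prob = 0.06,
                             stay_burst_kmh = 7, stay_burst_sdlog = 0.35,
                             stay_turn_sd = 1.57,
                             interior_margin_m = 20,
                             dawn_displacement_m = 2158,
                             distd_flee_m = 6721, distd_stay_m = 5027,
                             post_return_median_h = 34,
                             post_nonreturn_mass = 0.38,
                             post_lag_sdlog = 0.2,
                             control_median_h = 17,
                             control_nonreturn_mass = 0.12,
                             control_lag_sdlog = 0.35,
                             bush_range = c(0.036, 0.459),
                             gunshot_range = c(10, 85),
                             beater_range = c(30, 45),
                             dog_range = c(30, 50),
                             shooter_range = c(36, 43),
                             gps_noise_m = 5.8,
                             fix_success_2min = 0.82,
                             fix_success_hourly = 0.86,
                             season_start = "2017-11-15",
                             season_end = "2018-02-28",
                             capture_date = "2017-02-01",
                             landscape_m = 7400,
                             ou_tau_h = 6) {
  stopifnot(flee_probability >= 0, flee_probability <= 1,
            post_nonreturn_mass > 0, post_nonreturn_mass < 1,
            control_nonreturn_mass > 0, control_nonreturn_mass < 1,
            area_range_ha[1L] < area_range_ha[2L],
            gps_noise_m >= 0,
            fix_success_2min > 0, fix_success_2min <= 1,
            fix_success_hourly > 0, fix_success_hourly <= 1)
  cfg <- as.list(environment())
  class(cfg) <- "hm_genconfig"
  cfg
}

# Return lags are a two-branch mixture: with probability `mass` the
# animal does not return within the horizon; otherwise its lag is
# log-normal with spread `sdlog` and meanlog solved so that the
# *overall* median of the mixture equals the configured median (the
# quantity the Kaplan-Meier stage recovers):
#   (1 - mass) * F_lognormal(median_cfg) = 0.5
returner_meanlog <- function(median_h, mass, sdlog) {
  stopifnot(mass < 0.5)
  log(median_h) - sdlog * stats::qnorm(0.5 / (1 - mass))
}

draw_return_lag <- function(n, median_h, mass, sdlog, horizon_h = 144) {
  ml <- returner_meanlog(median_h, mass, sdlog)
  lag <- stats::rlnorm(n, ml, sdlog)
  nonret <- stats::runif(n) < mass
  lag[nonret] <- horizon_h + 50
  # sub-hour lags sit below the resolution of the hourly schedule
  pmax(lag, 1)
}

# truncated normal by rejection
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

# uniform interior point(s) at least `margin` inside the polygon
sample_interior <- function(n, poly, margin = 0) {
  out <- matrix(NA_real_, 0L, 2L)
  while (nrow(out) < n) {
    cand <- runif_in_polygon(2L * (n - nrow(out)) + 10L, poly)
    if (margin > 0) {
      keep <- signed_distance(cand[, 1L], cand[, 2L], poly) <= -margin
      cand <- cand[keep, , drop = FALSE]
    }
    out <- rbind(out, cand)
  }
  out[seq_len(n), , drop = FALSE]
}

# point a fixed clearance outside the polygon, in a random direction
# from its centroid
sample_exterior <- function(n, poly, min_m = 200, max_m = 1500) {
  cen <- poly_centroid(poly)
  rmax <- max(sqrt((poly[, 1L] - cen[1L])^2 + (poly[, 2L] - cen[2L])^2))
  th <- stats::runif(n, 0, 2 * pi)
  r <- rmax + stats::runif(n, min_m, max_m)
  cbind(cen[1L] + r * cos(th), cen[2L] + r * sin(th))
}

#' Simulate the true path of one hunting event
#'
#' Generates the noise-free movement of one individual from hunt
#' start to the first dawn after the hunt, at 2-min resolution during
#' the drive and hourly afterwards. The flee branch is a fast,
#' near-straight flight crossing the boundary during the drive
#' followed by slower wandering; the stay branch is slow, tortuous,
#' confined movement (with occasional flushes) that never exits the
#' polygon during the drive, followed by a delayed departure. Both
#' branches drift away from the encounter site after the hunt so that
#' net displacement at first dawn is near the configured scale.
#'
#' @param start numeric length-2 position inside the polygon at hunt
#'   start.
#' @param poly hunted-area polygon matrix.
#' @param t_start,t_end hunt window (POSIXct, UTC).
#' @param branch `"flee"` or `"stay"`.
#' @param config a [generator_config()].
#' @param acfg an [analysis_config()] (for the dawn clock time).
#' @return data frame `time`, `x`, `y`, `regime` (`"2min"` or
#'   `"hourly"`), with attribute `exit_time` (first true crossing of
#'   the boundary, POSIXct).
#' @export
simulate_hunt_response <- function(start, poly, t_start, t_end,
                                   branch = c("flee", "stay"),
                                   config = generator_config(),
                                   acfg = analysis_config()) {
  branch <- match.arg(branch)
  step_h <- 2 / 60
  times <- seq(as.numeric(t_start), as.numeric(t_end), by = 120)
  n <- length(times)
  xy <- matrix(NA_real_, n, 2L)
  xy[1L, ] <- start
  cen <- poly_centroid(poly)
  out_dir <- atan2(start[2L] - cen[2L], start[1L] - cen[1L])
  if (!is.finite(out_dir)) out_dir <- stats::runif(1, 0, 2 * pi)
  heading <- out_dir
  exited <- FALSE
  exit_time <- NA_real_
  for (k in 2L:n) {
    if (branch == "flee") {
      sd_prev <- signed_distance(xy[k - 1L, 1L], xy[k - 1L, 2L], poly)
      if (!exited && sd_prev < config$flee_exit_clearance_m) {
        v <- config$flee_speed_kmh *
          exp(stats::rnorm(1, 0, config$speed_sdlog))
        heading <- out_dir + stats::rnorm(1, 0, config$flee_heading_sd)
      } else {
        exited <- TRUE
        v <- config$postexit_speed_kmh *
          exp(stats::rnorm(1, 0, config$postexit_sdlog))
        heading <- heading + stats::rnorm(1, 0, config$postexit_heading_sd)
      }
      len <- v * 1000 * step_h
      cand <- xy[k - 1L, ] + len * c(cos(heading), sin(heading))
      if (exited) {
        # once across the shooting line, fleers do not wander back in
        tries <- 0L
        while (signed_distance(cand[1L], cand[2L], poly) < 30 &&
               tries < 20L) {
          heading <- out_dir + stats::rnorm(1, 0, 0.5)
          cand <- xy[k - 1L, ] + len * c(cos(heading), sin(heading))
          tries <- tries + 1L
        }
      }
      xy[k, ] <- cand
    } else {
      burst <- stats::runif(1) < config$stay_burst_prob
      v <- if (burst)
        config$stay_burst_kmh * exp(stats::rnorm(1, 0, config$stay_burst_sdlog))
      else
        config$stay_slow_kmh * exp(stats::rnorm(1, 0, config$stay_slow_sdlog))
      heading <- heading + pi + stats::rnorm(1, 0, config$stay_turn_sd)
      len <- v * 1000 * step_h
      cand <- xy[k - 1L, ] + len * c(cos(heading), sin(heading))
      tries <- 0L
      while (signed_distance(cand[1L], cand[2L], poly) >
             -config$interior_margin_m && tries < 20L) {
        heading <- atan2(cen[2L] - xy[k - 1L, 2L],
                         cen[1L] - xy[k - 1L, 1L]) +
          stats::rnorm(1, 0, 0.5)
        cand <- xy[k - 1L, ] + len * c(cos(heading), sin(heading))
        tries <- tries + 1L
      }
      if (signed_distance(cand[1L], cand[2L], poly) >
          -config$interior_margin_m) {
        # guaranteed inward fallback
        d <- cen - xy[k - 1L, ]
        cand <- xy[k - 1L, ] + d * min(1, len / sqrt(sum(d^2)))
      }
      xy[k, ] <- cand
    }
    if (is.na(exit_time) &&
        signed_distance(xy[k, 1L], xy[k, 2L], poly) > 0)
      exit_time <- times[k]
  }
  # delayed phase: hourly drift away from the encounter site, scaled
  # so the first-dawn net displacement and cumulative hourly distance
  # land near the configured branch targets
  dawn <- as.numeric(next_local_hour(t_end, acfg$dawn_hour, acfg))
  htimes <- seq(times[n] + 3600, dawn, by = 3600)
  if (length(htimes) && htimes[length(htimes)] < dawn)
    htimes <- c(htimes, dawn)
  last <- xy[n, ]
  r0vec <- last - start
  r0 <- sqrt(sum(r0vec^2))
  u <- if (r0 > 1) r0vec / r0 else
    c(cos(out_dir), sin(out_dir))
  nh <- length(htimes)
  hxy <- matrix(NA_real_, nh, 2L)
  if (nh) {
    r_target <- config$dawn_displacement_m * exp(stats::rnorm(1, 0, 0.15))
    t_target <- (if (branch == "flee") config$distd_flee_m else
      config$distd_stay_m) * exp(stats::rnorm(1, 0, 0.2))
    len_budget <- max(t_target - r0, nh * 50)
    s <- len_budget / nh
    dr <- (max(r_target, r0 + 100) - r0) / nh
    lat <- sqrt(max(s^2 - dr^2, 100))
    perp <- c(-u[2L], u[1L])
    pos <- last
    for (k in seq_len(nh)) {
      pos <- pos + dr * u + sample(c(-1, 1), 1L) * lat * perp
      if (is.na(exit_time)) {
        if (signed_distance(pos[1L], pos[2L], poly) > 0)
          exit_time <- htimes[k]
      } else {
        # no re-entry once departed: push stray points back outside
        while (signed_distance(pos[1L], pos[2L], poly) < 30)
          pos <- cen + (pos - cen) * 1.15
      }
      hxy[k, ] <- pos
    }
  }
  out <- data.frame(
    time = as.POSIXct(c(times, htimes), origin = "1970-01-01", tz = "UTC"),
    x = c(xy[, 1L], hxy[, 1L]), y = c(xy[, 2L], hxy[, 2L]),
    regime = c(rep("2min", n), rep("hourly", nh)))
  attr(out, "exit_time") <- if (is.na(exit_time)) NULL else
    as.POSIXct(exit_time, origin = "1970-01-01", tz = "UTC")
  out
}

#' Apply the GPS observation model to a true path
#'
#' Adds isotropic Gaussian position noise (per-axis sd chosen so the
#' median radial error equals `gps_noise_m`) and independent fix
#' dropout at one minus the per-regime fix success.
#'
#' @param path data frame `time`, `x`, `y` and `regime` (`"2min"` or
#'   `"hourly"`), as produced by [simulate_hunt_response()].
#' @param individual_id id for the emitted relocations.
#' @param config a [generator_config()].
#' @param noise,dropout logical switches, both on by default.
#' @return an `hm_traj` of the observed fixes (`fix_ok = TRUE`).
#' @export
apply_observation_model <- function(path, individual_id,
                                    config = generator_config(),
                                    noise = TRUE, dropout = TRUE) {
  keep <- rep(TRUE, nrow(path))
  if (dropout) {
    p <- ifelse(path$regime == "2min", config$fix_success_2min,
                config$fix_success_hourly)
    keep <- stats::runif(nrow(path)) < p
  }
  df <- path[keep, , drop = FALSE]
  if (noise && config$gps_noise_m > 0) {
    sdax <- config$gps_noise_m / sqrt(2 * log(2))
    df$x <- df$x + stats::rnorm(nrow(df), 0, sdax)
    df$y <- df$y + stats::rnorm(nrow(df), 0, sdax)
  }
  as_trajectory(data.frame(individual_id = individual_id,
                           timestamp = df$time, x = df$x, y = df$y,
                           fix_ok = TRUE))
}

# draw per-drive effort/habitat covariates
draw_hunt_covariates <- function(config) {
  list(n_beaters = round(stats::runif(1, config$beater_range[1L],
                                      config$beater_range[2L])),
       n_dogs = round(stats::runif(1, config$dog_range[1L],
                                   config$dog_range[2L])),
       n_shooters = round(stats::runif(1, config$shooter_range[1L],
                                       config$shooter_range[2L])),
       n_gunshots = round(stats::runif(1, config$gunshot_range[1L],
                                       config$gunshot_range[2L])),
       bush = stats::runif(1, config$bush_range[1L], config$bush_range[2L]))
}

#' Simulate standalone hunting events
#'
#' Generates `n_events` independent hunting events (one individual,
#' one hunted area and one drive each) with known ground-truth
#' behaviour labels, optionally extended with post-hunt return paths
#' and pre-hunt control presence spells so that the survival stage
#' can be exercised on the same trajectories.
#'
#' @param n_events number of events.
#' @param config a [generator_config()].
#' @param acfg an [analysis_config()].
#' @param with_returns `"none"` (hunt window and dawn drift only),
#'   `"post"` (adds the post-hunt absence spell and return) or
#'   `"both"` (also adds a 150-h pre-hunt history encoding the
#'   control spell).
#' @param noise,dropout observation-model switches.
#' @return list with `trajectories` (named list of `hm_traj`),
#'   `hunts` (drive-hunt log data frame), `areas` (named list of
#'   `hm_area`) and `truth` (data frame: `event_id`,
#'   `individual_id`, `hunt_id`, `true_branch`, `true_exit_time`,
#'   `true_post_lag_h`, `true_control_lag_h`).
#' @export
simulate_events <- function(n_events, config = generator_config(),
                            acfg = analysis_config(),
                            with_returns = c("none", "post", "both"),
                            noise = TRUE, dropout = TRUE) {
  with_returns <- match.arg(with_returns)
  trajs <- list(); areas <- list(); hunts <- list(); truth <- list()
  t0 <- as.POSIXct("2017-12-01 10:00:00", tz = acfg$tz)
  for (i in seq_len(n_events)) {
    id <- sprintf("deer%04d", i)
    aid <- sprintf("area%04d", i)
    hid <- sprintf("hunt%04d", i)
    area_ha <- rtnorm(1, config$area_mean_ha, config$area_sd_ha,
                      config$area_range_ha[1L], config$area_range_ha[2L])
    # each event gets its own day and its own 10-km landscape tile so
    # that independent events cannot interact in time or space
    cen <- c(((i - 1L) %% 100L) * 1e4 +
               stats::runif(1, 0, config$landscape_m),
             ((i - 1L) %/% 100L) * 1e4 +
               stats::runif(1, 0, config$landscape_m))
    poly <- random_convex_polygon(cen, area_ha)
    cv <- draw_hunt_covariates(config)
    t_start <- as.POSIXct(t0, tz = "UTC") + (i - 1L) * 86400
    t_end <- t_start + config$hunt_duration_min * 60
    branch <- if (stats::runif(1) < config$flee_probability) "flee" else
      "stay"
    start <- sample_interior(1L, poly, config$interior_margin_m)[1L, ]
    path <- simulate_hunt_response(start, poly, t_start, t_end, branch,
                                   config, acfg)
    exit_time <- attr(path, "exit_time")
    # short pre-hunt presence so the encounter fix exists
    pre_t <- seq(as.numeric(t_start) - 600, as.numeric(t_start) - 120,
                 by = 120)
    pre <- data.frame(
      time = as.POSIXct(pre_t, origin = "1970-01-01", tz = "UTC"),
      x = start[1L] + cumsum(stats::rnorm(length(pre_t), 0, 3)),
      y = start[2L] + cumsum(stats::rnorm(length(pre_t), 0, 3)),
      regime = "2min")
    post_lag <- draw_return_lag(1L, config$post_return_median_h,
                                config$post_nonreturn_mass,
                                config$post_lag_sdlog,
                                acfg$censor_horizon_h)
    ctl_lag <- draw_return_lag(1L, config$control_median_h,
                               config$control_nonreturn_mass,
                               config$control_lag_sdlog,
                               acfg$censor_horizon_h)
    segs <- list(pre, path)
    if (with_returns != "none" && !is.null(exit_time)) {
      ret_t <- as.numeric(exit_time) + post_lag * 3600
      last_t <- as.numeric(path$time[nrow(path)])
      horizon_t <- as.numeric(exit_time) +
        (acfg$censor_horizon_h + 6) * 3600
      returns <- ret_t <= horizon_t
      # the return fix cannot precede the first hourly tick after the
      # hunt; the dawn drift is truncated at the return
      back_start <- if (returns)
        max(round(ret_t / 3600), ceiling(as.numeric(t_end) / 3600) + 1) *
        3600 else Inf
      segs[[2L]] <- path[as.numeric(path$time) < back_start, , drop = FALSE]
      stop_t <- min(back_start - 3600, horizon_t)
      if (stop_t > last_t + 3600) {
        away_t <- seq(last_t + 3600, stop_t, by = 3600)
        away <- sample_exterior(length(away_t), poly, 300, 2500)
        segs <- c(segs, list(data.frame(
          time = as.POSIXct(away_t, origin = "1970-01-01", tz = "UTC"),
          x = away[, 1L], y = away[, 2L], regime = "hourly")))
      }
      if (returns) {
        back_t <- seq(back_start, by = 3600, length.out = 3L)
        back <- sample_interior(3L, poly, config$interior_margin_m)
        segs <- c(segs, list(data.frame(
          time = as.POSIXct(back_t, origin = "1970-01-01", tz = "UTC"),
          x = back[, 1L], y = back[, 2L], regime = "hourly")))
      }
    }
    if (with_returns == "both") {
      # pre-hunt history encoding the control spell: inside up to and
      # including the exit fix, outside for ctl_lag hours, inside
      # again from the entry fix until hunt start. Spell endpoints sit
      # on the hourly grid so the observed exit-to-entry gap equals
      # the drawn lag (rounded to the schedule resolution).
      pre_arrive_h <- sample(2:12, 1L)
      entry_t <- as.numeric(t_start) - pre_arrive_h * 3600
      gap_h <- max(round(ctl_lag), 1)
      if (dropout) {
        # fix dropout can only lengthen the observed exit-to-entry gap
        # (each dropped boundary fix pushes it out one tick, geometric
        # with rate 1 - fix success per side); shrink the constructed
        # gap by the expected lengthening so the observed spell is an
        # unbiased reading of the drawn lag
        p_mis <- 1 - config$fix_success_hourly
        extra <- 2 * p_mis / (1 - p_mis)
        gap_h <- max(gap_h - stats::rbinom(1L, 1L, min(extra, 1)), 1)
      }
      exit_t <- entry_t - gap_h * 3600
      hist_t <- seq(as.numeric(t_start) - 150 * 3600,
                    as.numeric(t_start) - 3600, by = 3600)
      hist_t <- hist_t[hist_t < pre_t[1L]]
      inside <- hist_t <= exit_t | hist_t >= entry_t
      hxy <- matrix(NA_real_, length(hist_t), 2L)
      n_in <- sum(inside)
      if (n_in)
        hxy[inside, ] <- sample_interior(n_in, poly,
                                         config$interior_margin_m)
      if (any(!inside))
        hxy[!inside, ] <- sample_exterior(sum(!inside), poly, 300, 2500)
      segs <- c(list(data.frame(
        time = as.POSIXct(hist_t, origin = "1970-01-01", tz = "UTC"),
        x = hxy[, 1L], y = hxy[, 2L], regime = "hourly")), segs)
    }
    full <- do.call(rbind, segs)
    full <- full[order(full$time), , drop = FALSE]
    full <- full[!duplicated(full$time), , drop = FALSE]
    trajs[[id]] <- apply_observation_model(full, id, config,
                                           noise = noise,
                                           dropout = dropout)
    areas[[aid]] <- hunted_area(aid, poly, bush_fraction = cv$bush)
    hunts[[length(hunts) + 1L]] <- data.frame(
      hunt_id = hid, area_id = aid, start = t_start, end = t_end,
      n_beaters = cv$n_beaters, n_dogs = cv$n_dogs,
      n_shooters = cv$n_shooters, n_gunshots = cv$n_gunshots,
      bush_fraction = cv$bush, area_ha = area_ha,
      dogs_per_ha = cv$n_dogs / area_ha,
      beaters_per_ha = cv$n_beaters / area_ha,
      stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      event_id = paste0(hid, ":", id), individual_id = id, hunt_id = hid,
      true_branch = branch,
      true_exit_time = if (is.null(exit_time)) NA_real_ else
        as.numeric(exit_time),
      true_post_lag_h = post_lag, true_control_lag_h = ctl_lag,
      stringsAsFactors = FALSE)
  }
  list(trajectories = trajs, hunts = do.call(rbind, hunts),
       areas = areas, truth = do.call(rbind, truth), config = config)
}

# exact Ornstein-Uhlenbeck transition over a variable time step
ou_step <- function(pos, centre, dt_h, tau_h, sigma_m) {
  a <- exp(-dt_h / tau_h)
  s <- sigma_m * sqrt(1 - a * a)
  centre + a * (pos - centre) + stats::rnorm(2L, 0, s)
}

# fix schedule of one individual over the study year: 12-h fixes
# outside the hunting season, hourly within it, 2-min fixes in the
# 08:00-20:00 local window of hunt days
population_schedule <- function(config, acfg, hunt_days) {
  cap <- as.POSIXct(paste(config$capture_date, "00:00:00"), tz = acfg$tz)
  s0 <- as.POSIXct(paste(config$season_start, "00:00:00"), tz = acfg$tz)
  s1 <- as.POSIXct(paste(config$season_end, "23:59:59"), tz = acfg$tz)
  yr_end <- cap + 365 * 86400
  t12 <- seq(as.numeric(cap), as.numeric(yr_end), by = 12 * 3600)
  t12 <- t12[t12 < as.numeric(s0) | t12 > as.numeric(s1)]
  th <- seq(as.numeric(s0), min(as.numeric(s1), as.numeric(yr_end)),
            by = 3600)
  t2 <- unlist(lapply(hunt_days, function(d) {
    w0 <- as.numeric(as.POSIXct(paste(d, "08:00:00"), tz = acfg$tz))
    seq(w0, w0 + 12 * 3600, by = 120)
  }))
  regime <- c(rep("hourly", length(t12)), rep("hourly", length(th)),
              rep("2min", length(t2)))
  tt <- c(t12, th, t2)
  o <- order(tt)
  tt <- tt[o]; regime <- regime[o]
  keep <- !duplicated(tt)
  data.frame(time = tt[keep], regime = regime[keep])
}

#' Simulate a full monitored population and its hunting season
#'
#' The end-to-end generator: home-range-attracted
#' Ornstein-Uhlenbeck walks for each collared individual over the
#' study year (sampled on the dual fix schedule), weekly hunt days of
#' 4-6 one-hour drives over convex hunted-area polygons placed to
#' overlap home ranges, flee/stay behaviour branches drawn with the
#' configured flee probability spliced into the walk, and post-hunt
#' absence spells honouring the configured return-lag distribution.
#' The walk's stationary sd is calibrated so the 95% Gaussian range
#' equals the drawn home-range size.
#'
#' @param config a [generator_config()].
#' @param acfg an [analysis_config()].
#' @param out_dir optional directory; when given, writes
#'   `relocations.csv`, `hunts.csv`, `areas.geojson` and
#'   `truth.json` in the formats the readers consume.
#' @param noise,dropout observation-model switches.
#' @return list with `trajectories`, `hunts`, `areas`, `truth`
#'   (events with true branch labels and lags, plus per-individual
#'   home-range centres and dispersions) and `config`. Fully
#'   reproducible given the RNG state (use `set.seed()` before
#'   calling).
#' @export
simulate_population <- function(config = generator_config(),
                                acfg = analysis_config(),
                                out_dir = NULL,
                                noise = TRUE, dropout = TRUE) {
  L <- config$landscape_m
  n <- config$n_individuals
  centres <- cbind(stats::runif(n, 0.25 * L, 0.75 * L),
                   stats::runif(n, 0.25 * L, 0.75 * L))
  hr_ha <- rtnorm(n, config$hr_mean_ha, config$hr_sd_ha,
                  lower = 100, upper = 1600)
  sigma <- sqrt(hr_ha * 1e4 / (2 * pi * (-log(0.05))))
  s0 <- as.POSIXct(paste(config$season_start, "00:00:00"), tz = acfg$tz)
  first_friday <- s0 + ((5 - as.POSIXlt(s0)$wday) %% 7) * 86400
  hunt_days <- format(first_friday + (seq_len(config$n_hunt_days) - 1L) *
                        7 * 86400, "%Y-%m-%d", tz = acfg$tz)
  sched <- population_schedule(config, acfg, hunt_days)
  # base walks
  paths <- vector("list", n)
  for (i in seq_len(n)) {
    m <- nrow(sched)
    xy <- matrix(NA_real_, m, 2L)
    xy[1L, ] <- centres[i, ] + stats::rnorm(2L, 0, sigma[i])
    dt <- diff(sched$time) / 3600
    for (k in 2L:m)
      xy[k, ] <- ou_step(xy[k - 1L, ], centres[i, ], dt[k - 1L],
                         config$ou_tau_h, sigma[i])
    paths[[i]] <- xy
  }
  base_paths <- paths
  ids <- sprintf("deer%02d", seq_len(n))
  # hunts: per hunt day, 4-6 sequential drives; each area is centred
  # near the hunt-start position of a randomly chosen individual so
  # that exposure actually occurs
  hunts <- list(); areas <- list(); truth_ev <- list()
  # individuals inside an active response/absence window are not
  # re-exposed: a second splice would corrupt the first spell
  avoid_until <- rep(-Inf, n)
  aseq <- 0L
  for (d in seq_along(hunt_days)) {
    nh <- sample(seq(config$hunts_per_day[1L], config$hunts_per_day[2L]),
                 1L)
    for (j in seq_len(nh)) {
      aseq <- aseq + 1L
      t_start <- as.POSIXct(paste(hunt_days[d], "09:00:00"),
                            tz = acfg$tz) + (j - 1L) * 5400
      t_start <- as.POSIXct(as.numeric(t_start), origin = "1970-01-01",
                            tz = "UTC")
      t_end <- t_start + config$hunt_duration_min * 60
      k0 <- findInterval(as.numeric(t_start), sched$time)
      tgt <- sample.int(n, 1L)
      cen <- paths[[tgt]][k0, ] + stats::rnorm(2L, 0, 300)
      area_ha <- rtnorm(1, config$area_mean_ha, config$area_sd_ha,
                        config$area_range_ha[1L], config$area_range_ha[2L])
      poly <- random_convex_polygon(cen, area_ha)
      cv <- draw_hunt_covariates(config)
      aid <- sprintf("area%03d", aseq)
      hid <- sprintf("hunt%03d", aseq)
      areas[[aid]] <- hunted_area(aid, poly, bush_fraction = cv$bush)
      hunts[[aseq]] <- data.frame(
        hunt_id = hid, area_id = aid, start = t_start, end = t_end,
        n_beaters = cv$n_beaters, n_dogs = cv$n_dogs,
        n_shooters = cv$n_shooters, n_gunshots = cv$n_gunshots,
        bush_fraction = cv$bush, area_ha = area_ha,
        dogs_per_ha = cv$n_dogs / area_ha,
        beaters_per_ha = cv$n_beaters / area_ha,
        stringsAsFactors = FALSE)
      # splice behaviour responses for exposed individuals
      for (i in seq_len(n)) {
        if (as.numeric(t_start) < avoid_until[i]) next
        pos <- paths[[i]][k0, ]
        if (!point_in_polygon(pos[1L], pos[2L], poly)) next
        branch <- if (stats::runif(1) < config$flee_probability) "flee"
        else "stay"
        if (branch == "stay" &&
            signed_distance(pos[1L], pos[2L], poly) >
            -config$interior_margin_m)
          pos <- sample_interior(1L, poly, config$interior_margin_m)[1L, ]
        resp <- simulate_hunt_response(pos, poly, t_start, t_end, branch,
                                       config, acfg)
        lag <- draw_return_lag(1L, config$post_return_median_h,
                               config$post_nonreturn_mass,
                               config$post_lag_sdlog,
                               acfg$censor_horizon_h)
        exit_time <- attr(resp, "exit_time")
        rt <- as.numeric(resp$time)
        # impose the response on every schedule tick it spans; the
        # hourly delayed-phase points are linearly interpolated onto
        # the finer 2-min hunt-day grid
        win <- which(sched$time >= rt[1L] &
                       sched$time <= rt[length(rt)])
        if (length(win)) {
          paths[[i]][win, 1L] <- stats::approx(rt, resp$x,
                                               xout = sched$time[win])$y
          paths[[i]][win, 2L] <- stats::approx(rt, resp$y,
                                               xout = sched$time[win])$y
        }
        matched_until <- if (length(win)) max(sched$time[win]) else
          as.numeric(t_end)
        # condition the walk on the absence spell: from the end of the
        # spliced response until exit + lag, continue the OU walk kept
        # outside the hunted polygon; afterwards ease back onto the
        # precomputed base walk so the home range is preserved
        avoid_end <- if (is.null(exit_time)) matched_until else
          as.numeric(exit_time) + lag * 3600
        avoid_until[i] <- max(avoid_until[i], avoid_end + 12 * 3600)
        ex_t <- if (is.null(exit_time)) Inf else as.numeric(exit_time)
        pcen <- poly_centroid(poly)
        push_out <- function(p) {
          tries <- 0L
          while (signed_distance(p[1L], p[2L], poly) < 30 && tries < 40L) {
            p <- pcen + (p - pcen) * 1.2
            tries <- tries + 1L
          }
          p
        }
        cond <- which(sched$time > matched_until & sched$time <= avoid_end)
        for (k in cond) {
          dt_h <- (sched$time[k] - sched$time[k - 1L]) / 3600
          nxt <- ou_step(paths[[i]][k - 1L, ], centres[i, ], dt_h,
                         config$ou_tau_h, sigma[i])
          if (sched$time[k] > ex_t &&
              signed_distance(nxt[1L], nxt[2L], poly) < 30) {
            tries <- 0L
            while (signed_distance(nxt[1L], nxt[2L], poly) < 30 &&
                   tries < 25L) {
              nxt <- ou_step(paths[[i]][k - 1L, ], centres[i, ], dt_h,
                             config$ou_tau_h, sigma[i])
              tries <- tries + 1L
            }
            if (signed_distance(nxt[1L], nxt[2L], poly) < 30)
              nxt <- push_out(nxt)
          }
          paths[[i]][k, ] <- nxt
        }
        k_last <- if (length(cond)) cond[length(cond)] else
          if (length(win)) win[length(win)] else NA_integer_
        # honour the spell end: the first fix after exit + lag is back
        # inside the hunted area (returners only)
        if (!is.na(k_last) && !is.null(exit_time) &&
            lag <= acfg$censor_horizon_h) {
          k_ret <- which(sched$time > avoid_end)[1L]
          if (!is.na(k_ret)) {
            paths[[i]][k_ret, ] <- sample_interior(
              1L, poly, config$interior_margin_m)[1L, ]
            k_last <- k_ret
          }
        }
        relax <- if (is.na(k_last)) integer(0) else
          which(sched$time > sched$time[k_last])
        if (length(relax)) {
          offset <- paths[[i]][k_last, ] - base_paths[[i]][k_last, ]
          w <- exp(-((sched$time[relax] - sched$time[k_last]) / 3600) / 12)
          paths[[i]][relax, ] <- base_paths[[i]][relax, , drop = FALSE] +
            cbind(offset[1L] * w, offset[2L] * w)
        }
        truth_ev[[length(truth_ev) + 1L]] <- data.frame(
          event_id = paste0(hid, ":", ids[i]), individual_id = ids[i],
          hunt_id = hid, true_branch = branch,
          true_exit_time = if (is.null(exit_time)) NA_real_ else
            as.numeric(exit_time),
          true_post_lag_h = lag, stringsAsFactors = FALSE)
      }
    }
  }
  trajs <- list()
  for (i in seq_len(n)) {
    path <- data.frame(time = as.POSIXct(sched$time,
                                         origin = "1970-01-01",
                                         tz = "UTC"),
                       x = paths[[i]][, 1L], y = paths[[i]][, 2L],
                       regime = sched$regime)
    trajs[[ids[i]]] <- apply_observation_model(path, ids[i], config,
                                               noise = noise,
                                               dropout = dropout)
  }
  truth <- list(
    events = if (length(truth_ev)) do.call(rbind, truth_ev) else
      data.frame(),
    individuals = data.frame(individual_id = ids,
                             centre_x = centres[, 1L],
                             centre_y = centres[, 2L],
                             hr_ha = hr_ha, sigma_m = sigma))
  out <- list(trajectories = trajs,
              hunts = do.call(rbind, hunts), areas = areas,
              truth = truth, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_relocations(trajs, file.path(out_dir, "relocations.csv"))
    write_hunts(out$hunts, file.path(out_dir, "hunts.csv"))
    write_areas(areas, file.path(out_dir, "areas.geojson"))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, POSIXt = "ISO8601")
  }
  out
}
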