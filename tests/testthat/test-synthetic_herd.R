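# Synthetic herd-and-hunt generator: determinism, calibration targets
# and full-pipeline recovery.

test_that("the generator is deterministic given the seed", {
  set.seed(123)
  a <- simulate_events(5, with_returns = "both")
  set.seed(123)
  b <- simulate_events(5, with_returns = "both")
  expect_identical(a$truth, b$truth)
  expect_identical(lapply(a$trajectories, as.data.frame),
                   lapply(b$trajectories, as.data.frame))
  expect_identical(a$hunts, b$hunts)
})

test_that("behaviour branches follow the configured flee probability", {
  set.seed(9)
  all_flee <- simulate_events(15, generator_config(flee_probability = 1))
  expect_true(all(all_flee$truth$true_branch == "flee"))
  set.seed(9)
  none <- simulate_events(15, generator_config(flee_probability = 0))
  expect_true(all(none$truth$true_branch == "stay"))
})

test_that("hunted-area sizes match the emulated size distribution", {
  set.seed(13)
  sim <- simulate_events(50)
  ha <- sim$hunts$area_ha
  expect_true(all(ha >= 47 & ha <= 201))
  expect_lt(abs(mean(ha) - 101) / 101, 0.15)
})

test_that("the observation model reproduces schedule, dropout and error", {
  sq <- square_poly(0, 0, 5000)
  n <- 5000
  path <- data.frame(time = t_utc("2017-12-01 08:00:00") +
                       seq(0, by = 120, length.out = n),
                     x = 0, y = 0, regime = "2min")
  # noise and dropout off: observed equals true at schedule times
  tr0 <- apply_observation_model(path, "a", noise = FALSE,
                                 dropout = FALSE)
  expect_equal(nrow(tr0), n)
  expect_true(all(tr0$x == 0 & tr0$y == 0))
  # dropout at 18%: binomial count near 0.82 n
  set.seed(41)
  tr1 <- apply_observation_model(path, "a", noise = FALSE)
  phat <- nrow(tr1) / n
  expect_lt(abs(phat - 0.82), 3 * sqrt(0.82 * 0.18 / n))
  # median radial error near the configured 5.8 m
  set.seed(42)
  tr2 <- apply_observation_model(path, "a", dropout = FALSE)
  r <- sqrt(tr2$x^2 + tr2$y^2)
  expect_equal(median(r), 5.8, tolerance = 0.05)
  # and the Rayleigh-mean closed form for the per-axis sd
  sdax <- 5.8 / sqrt(2 * log(2))
  expect_equal(mean(r), sdax * sqrt(pi / 2), tolerance = 0.05)
})

test_that("flee kinematics land near the calibrated maximum speed", {
  set.seed(14)
  sq <- square_poly(500, 505, 505)
  sp <- replicate(100, {
    st <- runif_in_polygon(1, sq)[1, ]
    p <- simulate_hunt_response(st, sq, t_utc("2017-12-01 09:00:00"),
                                t_utc("2017-12-01 10:00:00"), "flee")
    tr <- as_trajectory(data.frame(individual_id = "f", timestamp = p$time,
                                   x = p$x, y = p$y, fix_ok = TRUE))
    max_speed(build_steps(tr, p$time[1], p$time[31]))
  })
  expect_lt(abs(median(sp) - 18) / 18, 0.25)
})

test_that("stay paths never exit during the hunt; both branches disperse", {
  set.seed(15)
  sq <- square_poly(0, 0, 600)
  for (r in 1:10) {
    st <- c(runif(1, -400, 400), runif(1, -400, 400))
    p <- simulate_hunt_response(st, sq, t_utc("2017-12-01 09:00:00"),
                                t_utc("2017-12-01 10:00:00"), "stay")
    hunt <- p[p$regime == "2min", ]
    expect_true(all(signed_distance(hunt$x, hunt$y, sq) <= 0))
    # by first dawn the animal is far from the encounter site
    last <- p[nrow(p), ]
    expect_gt(sqrt((last$x - st[1])^2 + (last$y - st[2])^2), 1000)
  }
})

test_that("generated lags flow through the survival stage unbiased", {
  set.seed(16)
  sim <- simulate_events(120, with_returns = "both")
  cfg <- analysis_config()
  ev <- detect_events(sim$trajectories, sim$hunts, sim$areas, cfg)
  ev <- build_event_table(ev, sim$trajectories, sim$areas, cfg)
  rec <- build_return_table(ev, sim$trajectories, sim$areas, cfg)
  m <- merge(rec[rec$condition == "post_hunt", ], sim$truth,
             by = "event_id")
  ok <- !m$censored & m$true_post_lag_h <= 144
  # observed durations track the generated lags to within the hourly
  # grid plus scheduling slack
  expect_lt(median(abs(m$duration[ok] - m$true_post_lag_h[ok])), 1.5)
  # censoring happens exactly for the non-return branch
  expect_equal(m$censored, m$true_post_lag_h > 144)
})

test_that("the full population generator round-trips through the files", {
  set.seed(77)
  gcfg <- generator_config(n_individuals = 4L, n_hunt_days = 4L,
                           season_start = "2017-11-15",
                           season_end = "2017-12-20",
                           capture_date = "2017-11-01")
  d <- withr::local_tempdir()
  sim <- simulate_population(gcfg, out_dir = d)
  expect_true(all(file.exists(file.path(d, c("relocations.csv",
                                             "hunts.csv",
                                             "areas.geojson",
                                             "truth.json")))))
  trajs <- read_relocations(file.path(d, "relocations.csv"))
  hh <- read_hunts(file.path(d, "hunts.csv"), file.path(d, "areas.geojson"))
  expect_equal(length(trajs), 4)
  expect_equal(nrow(hh$hunts), nrow(sim$hunts))
  expect_equal(hh$hunts$hunt_id, sim$hunts$hunt_id)  # order preserved
  # coordinates survive to 1e-6 m
  expect_equal(trajs[[1]]$x, sim$trajectories[[1]]$x, tolerance = 1e-6)
  # events detected from the files agree with the ground truth
  cfg <- analysis_config()
  ev <- detect_events(trajs, hh$hunts, hh$areas, cfg)
  ev <- build_event_table(ev, trajs, hh$areas, cfg)
  m <- merge(ev, sim$truth$events, by = "event_id")
  expect_gt(nrow(m), 3)
  agree <- mean(m$classification ==
                  ifelse(m$true_branch == "flee", "fleeing", "staying"),
                na.rm = TRUE)
  expect_gte(agree, 0.95)
  # fix success per regime near the configured 82% / 86%, pooled over
  # the whole herd
  rrs <- lapply(trajs, regime_report, hunts = hh$hunts, config = cfg)
  pool <- function(reg) {
    obs <- sum(vapply(rrs, function(r) r$n_observed[r$regime == reg], 0))
    exp_ <- sum(vapply(rrs, function(r) r$n_expected[r$regime == reg], 0))
    obs / exp_
  }
  expect_lt(abs(pool("2min") - 0.82), 0.03)
  expect_lt(abs(pool("hourly") - 0.86), 0.03)
})

test_that("first-dawn displacement exceeds baseline roaming across events", {
  set.seed(78)
  gcfg <- generator_config(n_individuals = 8L, n_hunt_days = 8L,
                           season_start = "2017-11-15",
                           season_end = "2018-01-20",
                           capture_date = "2017-11-01")
  sim <- simulate_population(gcfg)
  cfg <- analysis_config()
  ev <- detect_events(sim$trajectories, sim$hunts, sim$areas, cfg)
  ev <- build_event_table(ev, sim$trajectories, sim$areas, cfg)
  ev <- ev[!is.na(ev$classification), ]
  expect_gt(nrow(ev), 30)
  nd <- function(offset_s) vapply(seq_len(nrow(ev)), function(i) {
    tr <- sim$trajectories[[ev$individual_id[i]]]
    dawn <- huntmove:::next_local_hour(ev$t_end[i], cfg$dawn_hour, cfg)
    net_displacement(tr, c(ev$x0[i], ev$y0[i]), dawn + offset_s,
                     nominal_interval_min = 60)
  }, numeric(1L))
  post_dawn <- nd(0)              # first dawn after the hunt
  baseline <- nd(-2 * 86400)      # same clock time, two days before
  expect_gt(median(post_dawn, na.rm = TRUE),
            median(baseline, na.rm = TRUE))
  # the displacement profile itself tiles and reports both groups
  pr <- suppressWarnings(displacement_profile(ev, sim$trajectories, cfg))
  expect_true(all(table(pr$group, pr$offset_days) <= 2))
  expect_gt(sum(pr$n_events[pr$offset_days == 0 & pr$phase == "day"]),
            20)
})
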