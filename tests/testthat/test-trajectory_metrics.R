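# Step construction and window-level movement metrics.

test_that("steps, gaps and turning angles follow the fix record", {
  tr <- make_traj(c(0, 120, 240), c(0, 100, 200), c(0, 0, 0))
  st <- build_steps(tr, nominal_interval_min = 2)
  expect_equal(st$length_m, c(100, 100))
  expect_equal(st$turn[2], 0)
  expect_false(any(st$spans_gap))
  # missing middle fix: one 4-min step flagged, no turning angle
  tr2 <- make_traj(c(0, 240, 360), c(0, 200, 300), c(0, 0, 0))
  st2 <- build_steps(tr2, nominal_interval_min = 2,
                     gap_tolerance_factor = 2)
  expect_equal(st2$spans_gap, c(TRUE, FALSE))
  expect_true(all(is.na(st2$turn)))
  # single fix in window -> empty series, not an error
  st3 <- build_steps(make_traj(0, 0, 0), nominal_interval_min = 2)
  expect_s3_class(st3, "hm_steps")
  expect_equal(nrow(st3), 0)
  expect_equal(as.numeric(cumulative_distance(st3)), 0)
})

test_that("sinuosity hits its definitional values", {
  straight <- make_traj(seq(0, 120 * 9, 120), seq(0, 900, 100), rep(0, 10))
  expect_equal(sinuosity(build_steps(straight)), 1)
  # every turn 180 degrees
  zig <- make_traj(seq(0, 120 * 5, 120), rep(c(0, 100), 3), rep(0, 6))
  expect_equal(sinuosity(build_steps(zig)), -1)
  # square path, all 90-degree turns
  sqp <- make_traj(seq(0, 120 * 4, 120), c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0))
  expect_equal(sinuosity(build_steps(sqp)), 0, tolerance = 1e-12)
  # uniform-random-heading walk: Brownian-like, mean cosine near 0
  set.seed(99)
  n <- 10000
  ang <- cumsum(stats::runif(n, -pi, pi))
  walk <- make_traj(seq(0, by = 120, length.out = n + 1),
                    c(0, cumsum(cos(ang))) * 10,
                    c(0, cumsum(sin(ang))) * 10)
  expect_lt(abs(sinuosity(build_steps(walk))), 0.02)
  expect_warning(sinuosity(build_steps(make_traj(c(0, 120), c(0, 1), c(0, 0)))),
                 "undefined")
})

test_that("max_speed uses true step durations and converts to km/h", {
  one <- make_traj(c(0, 120), c(0, 600), c(0, 0))
  expect_equal(max_speed(build_steps(one)), 18)
  two <- make_traj(c(0, 120, 240), c(0, 100, 150), c(0, 0, 0))
  expect_equal(max_speed(build_steps(two)), 3)
  expect_warning(v <- max_speed(build_steps(make_traj(0, 0, 0))),
                 "undefined")
  expect_true(is.na(v))
  # irregular spacing: 300 m in 5 min is 3.6 km/h, not a 2-min speed
  irr <- make_traj(c(0, 300), c(0, 300), c(0, 0))
  st <- build_steps(irr, nominal_interval_min = 5,
                    gap_tolerance_factor = 2)
  expect_equal(max_speed(st), 3.6)
})

test_that("cumulative distance matches a brute-force re-summation oracle", {
  tr <- make_traj(seq(0, 360, 120), c(0, 100, 300, 600), rep(0, 4))
  expect_equal(as.numeric(cumulative_distance(build_steps(tr))), 600)
  # generator fleeing path, fixed seed: oracle to 1e-9 relative
  set.seed(7)
  sq <- square_poly(500, 500, 500)
  p <- simulate_hunt_response(c(500, 500), sq,
                              t_utc("2017-12-01 09:00:00"),
                              t_utc("2017-12-01 10:00:00"), "flee")
  tr2 <- as_trajectory(data.frame(individual_id = "f", timestamp = p$time,
                                  x = p$x, y = p$y, fix_ok = TRUE))
  got <- as.numeric(cumulative_distance(
    build_steps(tr2, p$time[1], p$time[31], nominal_interval_min = 2)))
  want <- brute_resum(tr2, p$time[1], p$time[31])
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("metrics are invariant under rigid motions and bound each other", {
  set.seed(3)
  n <- 60
  tr <- make_traj(seq(0, by = 120, length.out = n),
                  cumsum(rnorm(n, 0, 50)), cumsum(rnorm(n, 0, 50)))
  st <- build_steps(tr)
  th <- 0.83
  rot <- function(x, y) list(x = cos(th) * x - sin(th) * y + 1234,
                             y = sin(th) * x + cos(th) * y - 987)
  r <- rot(tr$x, tr$y)
  tr2 <- make_traj(seq(0, by = 120, length.out = n), r$x, r$y)
  st2 <- build_steps(tr2)
  expect_equal(max_speed(st), max_speed(st2), tolerance = 1e-9)
  expect_equal(as.numeric(cumulative_distance(st)),
               as.numeric(cumulative_distance(st2)), tolerance = 1e-9)
  expect_equal(sinuosity(st), sinuosity(st2), tolerance = 1e-9)
  # triangle inequality: path length >= net displacement of endpoints
  net <- sqrt((tr$x[n] - tr$x[1])^2 + (tr$y[n] - tr$y[1])^2)
  expect_gte(as.numeric(cumulative_distance(st)), net)
  expect_true(sinuosity(st) >= -1 && sinuosity(st) <= 1)
})

test_that("net displacement matches nearest fixes within tolerance", {
  tr <- make_traj(c(0, 3600), c(300, 0), c(400, 0))
  expect_equal(net_displacement(tr, c(0, 0), tr$timestamp[1]), 500)
  expect_equal(net_displacement(tr, c(0, 0), tr$timestamp[2]), 0)
  # requested time with no fix within half the nominal interval
  far <- tr$timestamp[2] + 7200
  expect_true(is.na(net_displacement(tr, c(0, 0), far)))
})

test_that("displacement profile tiles the 5-day window per group", {
  cfg <- analysis_config()
  h0 <- as.POSIXct("2017-12-01 09:00:00", tz = cfg$tz)
  # one fleeing animal: at the encounter until the hunt, 1000 m away after
  off <- seq(-2 * 86400, 2 * 86400, 3600)
  xs <- ifelse(off < 3600, 0, 1000)
  tr <- make_traj(off, xs, 0 * off, id = "a", origin = h0)
  ev <- data.frame(event_id = "e1", individual_id = "a",
                   t_start = h0, t_end = h0 + 3600, x0 = 0, y0 = 0,
                   classification = "fleeing")
  expect_warning(pr <- displacement_profile(ev, list(a = tr), cfg),
                 "staying")
  expect_true(all(pr$group == "fleeing"))
  expect_equal(sort(unique(pr$offset_days)), -2:2)
  base <- pr[pr$baseline, ]
  post <- pr[pr$offset_days > 0, ]
  expect_true(all(base$median_m == 0))
  expect_true(all(post$median_m == 1000))
  # two events with displacements 100 and 300 in one period -> median 200
  tr1 <- make_traj(c(1800), c(100), c(0), id = "a", origin = h0)
  tr2 <- make_traj(c(1800), c(300), c(0), id = "b", origin = h0)
  ev2 <- data.frame(event_id = c("e1", "e2"), individual_id = c("a", "b"),
                    t_start = h0, t_end = h0 + 3600, x0 = 0, y0 = 0,
                    classification = "fleeing")
  pr2 <- suppressWarnings(displacement_profile(ev2, list(a = tr1, b = tr2),
                                               cfg))
  cell <- pr2[pr2$offset_days == 0 & pr2$phase == "day", ]
  expect_equal(cell$median_m, 200)
  expect_equal(cell$n_events, 2)
})
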