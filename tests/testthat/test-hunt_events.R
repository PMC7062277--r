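# Event detection, flee/stay classification and distance responses.

mk_hunt <- function(start = t_utc("2017-12-01 09:00:00"), dur_min = 60,
                    area_id = "A") {
  data.frame(hunt_id = "h1", area_id = area_id, start = start,
             end = start + dur_min * 60, n_beaters = 36, n_dogs = 32,
             n_shooters = 40, n_gunshots = 40, bush_fraction = 0.064,
             dogs_per_ha = 0.32, beaters_per_ha = 0.36)
}

test_that("event membership is decided at hunt start", {
  cfg <- analysis_config()
  sq <- square_poly(500, 500, 500)
  areas <- list(A = hunted_area("A", sq))
  h <- mk_hunt()
  inside <- make_traj(seq(0, 3600, 120), rep(500, 31), rep(500, 31),
                      id = "in")
  # 50 m outside at start, enters later: not an event
  late <- make_traj(seq(0, 3600, 120),
                    c(-50, rep(500, 30)), rep(500, 31), id = "late")
  outside <- make_traj(seq(0, 3600, 120), rep(3000, 31), rep(3000, 31),
                       id = "out")
  ev <- detect_events(list(inside = inside, late = late,
                           outside = outside), h, areas, cfg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$individual_id, "in")
  expect_equal(c(ev$x0, ev$y0), c(500, 500))
  expect_equal(ev$gunshots, 40)
  # two collared animals inside, one outside -> 2 events
  ev2 <- detect_events(list(a = inside, late = late,
                            b = make_traj(seq(0, 3600, 120), rep(10, 31),
                                          rep(10, 31), id = "b")),
                       h, areas, cfg)
  expect_equal(nrow(ev2), 2)
  # detection is order-independent over individuals
  ev3 <- detect_events(list(b = make_traj(seq(0, 3600, 120), rep(10, 31),
                                          rep(10, 31), id = "b"),
                            a = inside), h, areas, cfg)
  expect_setequal(ev3$individual_id, ev2$individual_id)
})

test_that("classification is a pure function of boundary crossings", {
  cfg <- analysis_config()
  sq <- square_poly(500, 500, 500)
  area <- hunted_area("A", sq)
  h <- mk_hunt()
  ev <- function(tr) {
    e <- detect_events(list(x = tr), h, list(A = area), cfg)
    expect_equal(nrow(e), 1)
    e
  }
  # path exiting mid-hunt (then re-entering): fleeing
  xs <- rep(500, 31); xs[15:18] <- c(900, 1100, 1100, 800)
  fl <- make_traj(seq(0, 3600, 120), xs, rep(500, 31), id = "x")
  expect_equal(classify_event(ev(fl), fl, area, cfg), "fleeing")
  # tortuous path entirely inside: staying
  set.seed(4)
  st <- make_traj(seq(0, 3600, 120), 500 + cumsum(rnorm(31, 0, 20)) %% 300,
                  500 + cumsum(rnorm(31, 0, 20)) %% 300, id = "x")
  expect_equal(classify_event(ev(st), st, area, cfg), "staying")
  # a fix exactly on the boundary has not crossed the line
  xs2 <- rep(500, 31); xs2[10] <- 1000
  bd <- make_traj(seq(0, 3600, 120), xs2, rep(500, 31), id = "x")
  expect_equal(classify_event(ev(bd), bd, area, cfg), "staying")
  # beyond the buffer it has
  xs3 <- rep(500, 31); xs3[10] <- 1000.01
  bd2 <- make_traj(seq(0, 3600, 120), xs3, rep(500, 31), id = "x")
  expect_equal(classify_event(ev(bd2), bd2, area, cfg), "fleeing")
  # with a GPS-error buffer the same fix counts as inside
  cfg_buf <- analysis_config(boundary_buffer_m = 5.8)
  expect_equal(classify_event(ev(bd2), bd2, area, cfg_buf), "staying")
  # too few fixes in the window: unclassifiable, not guessed
  thin <- make_traj(c(0, 1800), c(500, 500), c(500, 500), id = "x")
  e_thin <- data.frame(event_id = "e", t_start = h$start, t_end = h$end)
  expect_warning(cl <- classify_event(e_thin, thin, area, cfg),
                 "unclassifiable")
  expect_true(is.na(cl))
})

test_that("immediate distance sums 2-min steps over the hunt window", {
  cfg <- analysis_config()
  h <- mk_hunt(dur_min = 60)
  tr <- make_traj(seq(0, 3600, 120), seq(0, 3000, 100), rep(0, 31),
                  id = "x")
  e <- data.frame(event_id = "e", t_start = h$start, t_end = h$end)
  d <- immediate_distance(e, tr, cfg)
  expect_equal(as.numeric(d), 3000)
  expect_equal(attr(d, "n_gap_steps"), 0)
  # stationary animal: fix jitter only, bounded by noise scale
  set.seed(5)
  jit <- make_traj(seq(0, 3600, 120), rnorm(31, 0, 5), rnorm(31, 0, 5),
                   id = "x")
  expect_lt(as.numeric(immediate_distance(e, jit, cfg)), 3 * 5 * 31)
})

test_that("delayed distance runs from the configured origin to first dawn", {
  cfg_end <- analysis_config(delayed_from = "hunt_end")
  cfg_start <- analysis_config()
  tz <- cfg_end$tz
  start <- as.POSIXct("2017-12-01 16:00:00", tz = tz)
  h <- data.frame(event_id = "e", t_start = start, t_end = start + 3600)
  # hourly 500-m steps from hunt end (17:00) to 08:00 next day: 15 steps
  off <- seq(0, 16 * 3600, 3600)
  tr <- make_traj(off, seq(0, by = 500, length.out = length(off)),
                  rep(0, length(off)), id = "x", origin = start)
  expect_equal(as.numeric(delayed_distance(h, tr, cfg_end)), 15 * 500)
  # from hunt start the intra-hunt hourly step is included too
  expect_equal(as.numeric(delayed_distance(h, tr, cfg_start)), 16 * 500)
  # trajectory ending early: flagged partial
  short <- make_traj(off[1:5], seq(0, by = 500, length.out = 5),
                     rep(0, 5), id = "x", origin = start)
  expect_warning(d <- delayed_distance(h, short, cfg_start), "partial")
  expect_true(attr(d, "partial"))
})

test_that("classifier recovers generated labels exactly without noise", {
  set.seed(21)
  sim <- simulate_events(40, noise = FALSE, dropout = FALSE)
  cfg <- analysis_config()
  ev <- detect_events(sim$trajectories, sim$hunts, sim$areas, cfg)
  ev <- build_event_table(ev, sim$trajectories, sim$areas, cfg)
  expect_equal(nrow(ev), 40)               # no dropout: all detected
  m <- merge(ev, sim$truth, by = "event_id")
  expect_equal(m$classification,
               ifelse(m$true_branch == "flee", "fleeing", "staying"))
  # flee events have an outside fix in-window; stay events none
  for (i in seq_len(nrow(m))) {
    tr <- sim$trajectories[[m$individual_id.x[i]]]
    vf <- tr[tr$timestamp >= m$t_start[i] & tr$timestamp <= m$t_end[i], ]
    outside <- signed_distance(vf$x, vf$y,
                               sim$areas[[m$area_id[i]]]$polygon) > 1e-9
    expect_equal(any(outside), m$classification[i] == "fleeing")
  }
})
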