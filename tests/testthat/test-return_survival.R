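# Censored return-time construction and Kaplan-Meier estimation.

ret_area <- hunted_area("A", square_poly(500, 500, 500))

# trajectory visiting/leaving the area on an hourly grid: `state` is
# TRUE (inside) / FALSE (outside) per hour offset
state_traj <- function(offsets_h, state, origin, id = "x") {
  make_traj(offsets_h * 3600,
            ifelse(state, 500, 5000), ifelse(state, 500, 5000),
            id = id, origin = origin)
}

test_that("forward return time runs exit fix to first inside fix", {
  cfg <- analysis_config()
  start <- t_utc("2017-12-01 10:00:00")
  e <- data.frame(event_id = "e", individual_id = "x",
                  t_start = start, t_end = start + 3600)
  # exit at 10:00 day 0, first fix back inside 20:00 day 1: 34 h
  st <- c(FALSE, rep(FALSE, 33), rep(TRUE, 3))
  tr <- state_traj(c(0:33, 34:36), c(rep(FALSE, 34), rep(TRUE, 3)),
                   origin = start)
  r <- forward_return_time(e, tr, ret_area, cfg)
  expect_equal(r$duration, 34)
  expect_false(r$censored)
  expect_equal(r$condition, "post_hunt")
  expect_equal(r$short_return, 0L)
  # return after 2 h
  r2 <- forward_return_time(e, state_traj(0:5, c(FALSE, FALSE, TRUE,
                                                 TRUE, TRUE, TRUE),
                                          origin = start),
                            ret_area, cfg)
  expect_equal(r2$duration, 2)
  # no inside fix within 144 h: censored at the horizon
  tr3 <- state_traj(0:160, rep(FALSE, 161), origin = start)
  r3 <- forward_return_time(e, tr3, ret_area, cfg)
  expect_true(r3$censored)
  expect_equal(r3$duration, 144)
  expect_equal(r3$short_return, 1L)
  # never exits: no-exit signal
  tr4 <- state_traj(0:150, rep(TRUE, 151), origin = start)
  expect_warning(r4 <- forward_return_time(e, tr4, ret_area, cfg),
                 "never exited")
  expect_null(r4)
})

test_that("control return time scans the reversed pre-hunt scale", {
  cfg <- analysis_config()
  start <- t_utc("2017-12-08 10:00:00")
  e <- data.frame(event_id = "e", individual_id = "x",
                  t_start = start, t_end = start + 3600)
  # exited 48 h before the hunt, re-entered 31 h before: 17 h spell
  off <- -150:0
  inside <- off <= -48 | off >= -31
  r <- control_return_time(e, state_traj(off, inside, origin = start),
                           ret_area, cfg)
  expect_equal(r$duration, 17)
  expect_false(r$censored)
  expect_equal(r$condition, "control")
  # continuously inside for the prior 6 days: censored
  r2 <- control_return_time(e, state_traj(off, rep(TRUE, length(off)),
                                          origin = start),
                            ret_area, cfg)
  expect_true(r2$censored)
  expect_equal(r2$duration, 144)
  # exited 150 h before, re-entered 10 h before: censored at 144
  inside3 <- off <= -150 | off >= -10
  r3 <- control_return_time(e, state_traj(off, inside3, origin = start),
                            ret_area, cfg)
  expect_true(r3$censored)
  expect_equal(r3$duration, 144)
  # insufficient history: dropped
  expect_warning(r4 <- control_return_time(
    e, state_traj(-10:0, rep(TRUE, 11), origin = start), ret_area, cfg),
    "shorter than")
  expect_null(r4)
})

test_that("product-limit estimate matches the hand oracle", {
  rec <- data.frame(event_id = letters[1:4], individual_id = "x",
                    condition = "post_hunt",
                    duration = c(2, 4, 4, 6), censored = c(F, F, F, T),
                    short_return = 0L)
  km <- km_estimate(rec)
  expect_equal(km$surv[km$time == 2], 0.75)
  expect_equal(km$surv[km$time == 4], 0.25)
  expect_equal(km_median(km), 4)
  expect_true(all(diff(km$surv) <= 0))
  # agrees with the independent hand product-limit computation
  hand <- km_hand(rec$duration, !rec$censored)
  expect_equal(km$surv[match(hand$time, km$time)], hand$surv)
  # all censored: S stays at 1
  rec_c <- transform(rec, censored = TRUE)
  km_c <- km_estimate(rec_c)
  expect_true(all(km_c$surv == 1))
  expect_true(is.na(km_median(km_c)))
  # a single uncensored duration drops S from 1 to 0 at that time
  km_1 <- km_estimate(rec[1, ])
  expect_equal(km_1$surv, 0)
  expect_equal(km_median(km_1), 2)
})

test_that("KM equals one minus the empirical CDF without censoring", {
  set.seed(17)
  dur <- round(rlnorm(80, log(20), 0.7), 3)
  rec <- data.frame(event_id = as.character(1:80), individual_id = "x",
                    condition = "control", duration = dur,
                    censored = FALSE, short_return = 0L)
  km <- km_estimate(rec)
  for (t in sample(dur, 10))
    expect_equal(km$surv[km$time == t], mean(dur > t), tolerance = 1e-12)
})

test_that("KM median recovers a known log-normal median at n = 200", {
  set.seed(23)
  dur <- rlnorm(200, log(30), 0.5)
  cens <- dur > 144
  rec <- data.frame(event_id = as.character(1:200), individual_id = "x",
                    condition = "post_hunt",
                    duration = pmin(dur, 144), censored = cens,
                    short_return = NA)
  expect_equal(km_median(km_estimate(rec)), 30, tolerance = 0.1)
})

test_that("the estimator has no condition-dependent logic", {
  set.seed(29)
  rec <- data.frame(event_id = as.character(1:50), individual_id = "x",
                    condition = rep(c("post_hunt", "control"), 25),
                    duration = rlnorm(50, 3, 0.6),
                    censored = runif(50) < 0.2, short_return = NA)
  swapped <- transform(rec, condition = ifelse(condition == "post_hunt",
                                               "control", "post_hunt"))
  expect_equal(as.data.frame(km_estimate(rec, "post_hunt")),
               as.data.frame(km_estimate(swapped, "control")))
})

test_that("short-return coding follows the 72-h dichotomy", {
  expect_equal(short_return_indicator(34, FALSE), 0L)
  expect_equal(short_return_indicator(100, FALSE), 1L)
  expect_equal(short_return_indicator(72, FALSE), 1L)   # boundary
  expect_equal(short_return_indicator(144, TRUE), 1L)
  expect_true(is.na(short_return_indicator(50, TRUE)))
})
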