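# Fixture builders and independent oracles used across test files.

t_utc <- function(s) as.POSIXct(s, tz = "UTC")

# trajectory from second-offsets relative to an origin
make_traj <- function(offsets_s, x, y, id = "a",
                      origin = t_utc("2017-12-01 09:00:00"),
                      fix_ok = TRUE) {
  as_trajectory(data.frame(individual_id = id,
                           timestamp = origin + offsets_s,
                           x = x, y = y, fix_ok = fix_ok))
}

square_poly <- function(cx, cy, half) {
  cbind(cx + c(-1, 1, 1, -1) * half, cy + c(-1, -1, 1, 1) * half)
}

# independent brute-force re-summation of pairwise distances between
# consecutive valid fixes in a window (oracle for cumulative_distance)
brute_resum <- function(traj, from, to) {
  d <- traj[traj$fix_ok & traj$timestamp >= from & traj$timestamp <= to, ]
  d <- d[order(d$timestamp), ]
  tot <- 0
  for (k in seq_len(nrow(d) - 1))
    tot <- tot + sqrt((d$x[k + 1] - d$x[k])^2 + (d$y[k + 1] - d$y[k])^2)
  tot
}

# hand product-limit estimator (oracle for km_estimate)
km_hand <- function(dur, event) {
  ts <- sort(unique(dur[event]))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n_i <- sum(dur >= ts[i])
    d_i <- sum(dur == ts[i] & event)
    s <- s * (1 - d_i / n_i)
    out[i] <- s
  }
  data.frame(time = ts, surv = out)
}

# Monte-Carlo oracle for the familiarity index: uniform points in the
# hunted polygon, band weight looked up per point
fam_mc <- function(iso, poly, n) {
  pts <- runif_in_polygon(n, poly)
  b <- band_at(iso, pts[, 1], pts[, 2])
  w <- ifelse(is.na(b), 0, iso$weights[ifelse(is.na(b), 1L, b)])
  mean(w)
}

# standard isotropic-Gaussian UD fixture shared by familiarity tests
gaussian_iso <- function(n = 800, sd = 500, cell = 25, seed = 42) {
  set.seed(seed)
  p <- cbind(rnorm(n, 0, sd), rnorm(n, 0, sd))
  ud <- estimate_ud(p, cell_m = cell)
  list(ud = ud, iso = isopleth_regions(ud), sd = sd)
}
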