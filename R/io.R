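# Data model and file readers/writers.
#
# Tabular dialect: comma-separated, header required, UTF-8, '.'
# decimal separator. Timestamps are ISO 8601 UTC. Coordinates are
# projected metres; geographic (lon/lat) input is rejected rather than
# auto-projected so that distance semantics stay unambiguous.

TS_FMT <- "%Y-%m-%dT%H:%M:%SZ"

parse_utc <- function(s) {
  t <- as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  alt <- is.na(t)
  if (any(alt))
    t[alt] <- as.POSIXct(s[alt], format = "%Y-%m-%d %H:%M:%OS", tz = "UTC")
  t
}

#' Build a trajectory from a relocation data frame
#'
#' A trajectory is the time-ordered GPS record of one individual:
#' columns `individual_id`, `timestamp` (POSIXct, UTC), `x`, `y`
#' (projected metres) and `fix_ok`. Rows are sorted by time;
#' duplicate timestamps and mixed individuals are rejected. Fixes
#' flagged `fix_ok = FALSE` are retained (they matter for fix-success
#' reporting) but are excluded from all metric computations.
#'
#' @param df data frame with the columns above.
#' @return an object of class `hm_traj` (a data frame).
#' @export
as_trajectory <- function(df) {
  need <- c("individual_id", "timestamp", "x", "y", "fix_ok")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("format error: missing column(s) ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  if (length(unique(df$individual_id)) > 1L)
    stop("a trajectory holds a single individual; got ",
         paste(unique(df$individual_id), collapse = ", "))
  if (!inherits(df$timestamp, "POSIXct"))
    df$timestamp <- parse_utc(as.character(df$timestamp))
  attr(df$timestamp, "tzone") <- "UTC"
  df$fix_ok <- as.logical(df$fix_ok)
  if (anyNA(df$timestamp)) stop("unparseable timestamps in trajectory")
  df <- df[order(df$timestamp), , drop = FALSE]
  dup <- duplicated(df$timestamp)
  if (any(dup))
    stop("validation error: duplicate timestamps for individual '",
         df$individual_id[1L], "': ",
         paste(format(unique(df$timestamp[dup]), TS_FMT, tz = "UTC"),
               collapse = ", "))
  bad <- df$fix_ok & !(is.finite(df$x) & is.finite(df$y))
  if (any(bad))
    stop("validation error: non-finite coordinates on fix_ok rows")
  rownames(df) <- NULL
  class(df) <- c("hm_traj", "data.frame")
  df
}

# index a trajectory list by each trajectory's own individual id
name_by_id <- function(trajectories) {
  if (inherits(trajectories, "hm_traj")) trajectories <- list(trajectories)
  names(trajectories) <- vapply(trajectories,
                                function(t) as.character(t$individual_id[1L]),
                                character(1L))
  trajectories
}

# valid fixes of a trajectory, optionally restricted to a time window
valid_fixes <- function(traj, from = NULL, to = NULL) {
  keep <- traj$fix_ok & is.finite(traj$x) & is.finite(traj$y)
  if (!is.null(from)) keep <- keep & traj$timestamp >= from
  if (!is.null(to)) keep <- keep & traj$timestamp <= to
  traj[keep, , drop = FALSE]
}

reject_geographic <- function(x, y) {
  fin <- is.finite(x) & is.finite(y)
  if (!any(fin)) return(invisible())
  # degree-like magnitudes together with a sub-2-unit spread means
  # lon/lat almost surely; a metric dataset confined to 2 m is absurd
  degreeish <- all(abs(x[fin]) <= 180 & abs(y[fin]) <= 90)
  tiny <- diff(range(x[fin])) < 2 && diff(range(y[fin])) < 2
  if (degreeish && tiny)
    stop("coordinates look geographic (lon/lat); a projected metric CRS ",
         "is required and input is not auto-projected")
  invisible()
}

#' Read GPS relocations into per-individual trajectories
#'
#' @param path CSV with columns `individual_id` (or `id`), `timestamp`
#'   (ISO 8601), `x`, `y`, `fix_ok`.
#' @param config optional [analysis_config()] (unused by the reader
#'   itself; accepted for pipeline symmetry).
#' @return named list of `hm_traj`, one per individual. The number of
#'   malformed rows dropped is reported via `message()`.
#' @export
read_relocations <- function(path, config = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("id" %in% names(df) && !"individual_id" %in% names(df))
    names(df)[names(df) == "id"] <- "individual_id"
  need <- c("individual_id", "timestamp", "x", "y", "fix_ok")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("format error: missing column(s) ", paste(miss, collapse = ", "))
  df$timestamp <- parse_utc(as.character(df$timestamp))
  df$x <- as.numeric(df$x); df$y <- as.numeric(df$y)
  df$fix_ok <- as.logical(df$fix_ok)
  malformed <- is.na(df$timestamp) | is.na(df$fix_ok) |
    (df$fix_ok & !(is.finite(df$x) & is.finite(df$y)))
  if (any(malformed)) {
    message("read_relocations: dropped ", sum(malformed), " malformed row(s)")
    df <- df[!malformed, , drop = FALSE]
  }
  reject_geographic(df$x, df$y)
  out <- lapply(split(df, df$individual_id), as_trajectory)
  out[order(names(out))]
}

#' Write trajectories to a relocation CSV
#'
#' Round-trips through [read_relocations()] exactly (timestamps to the
#' second, coordinates to 1e-6 m).
#'
#' @param trajs list of `hm_traj` (or a single one).
#' @param path output CSV path.
#' @export
write_relocations <- function(trajs, path) {
  if (inherits(trajs, "hm_traj")) trajs <- list(trajs)
  df <- do.call(rbind, lapply(trajs, as.data.frame))
  df$timestamp <- format(df$timestamp, TS_FMT, tz = "UTC")
  df$x <- sprintf("%.6f", df$x)
  df$y <- sprintf("%.6f", df$y)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a hunted area
#'
#' @param area_id identifier.
#' @param polygon polygon matrix in projected metres.
#' @param bush_fraction proportion of the area covered by dense
#'   understorey, in `[0, 1]` (`NA` if unknown).
#' @param area_ha optional declared area; must agree with the polygon
#'   area within 0.1%.
#' @return object of class `hm_area`: list with `area_id`, `polygon`,
#'   `area_ha` (computed from geometry) and `bush_fraction`.
#' @export
hunted_area <- function(area_id, polygon, bush_fraction = NA_real_,
                        area_ha = NULL) {
  poly <- poly_ring(polygon)
  ha <- poly_area_m2(poly) / 1e4
  if (ha <= 0) stop("geometry error: zero-area polygon for area '",
                    area_id, "'")
  if (!is.null(area_ha) && is.finite(area_ha) &&
      abs(area_ha - ha) > 1e-3 * ha)
    stop("geometry error: declared area_ha (", area_ha,
         ") disagrees with polygon area (", signif(ha, 6),
         ") for area '", area_id, "'")
  bush_fraction <- suppressWarnings(as.numeric(bush_fraction)[1L])
  if (length(bush_fraction) != 1L || is.null(bush_fraction))
    bush_fraction <- NA_real_
  if (!is.na(bush_fraction) && (bush_fraction < 0 || bush_fraction > 1))
    stop("bush_fraction must lie in [0, 1]")
  structure(list(area_id = as.character(area_id), polygon = poly,
                 area_ha = ha, bush_fraction = bush_fraction),
            class = "hm_area")
}

#' Read hunted-area polygons from GeoJSON
#'
#' Expects a FeatureCollection with one Polygon feature per hunted
#' area, property `area_id` and optionally `bush_fraction` and
#' `area_ha`. Coordinates must be in a projected metric CRS (declared
#' via the analysis config, not reprojected here).
#'
#' @param path GeoJSON file.
#' @return named list of `hm_area`.
#' @export
read_areas <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(g$features)) stop("format error: not a GeoJSON FeatureCollection")
  out <- list()
  for (f in g$features) {
    aid <- f$properties$area_id
    if (is.null(aid)) stop("format error: feature without 'area_id' property")
    if (!identical(f$geometry$type, "Polygon"))
      stop("geometry error: feature '", aid, "' is not a Polygon")
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1L]],
                                  function(v) unlist(v)[1:2]))
    reject_geographic(ring[, 1L], ring[, 2L])
    bf <- f$properties$bush_fraction
    ah <- f$properties$area_ha
    if (is.null(bf) || !length(bf) || !is.numeric(bf)) bf <- NA_real_
    if (is.null(ah) || !length(ah) || !is.numeric(ah)) ah <- NULL
    out[[aid]] <- hunted_area(aid, ring, bush_fraction = bf, area_ha = ah)
  }
  out
}

#' Write hunted areas to GeoJSON
#' @param areas named list of `hm_area`.
#' @param path output path.
#' @export
write_areas <- function(areas, path) {
  feats <- lapply(areas, function(a) {
    ring <- rbind(a$polygon, a$polygon[1L, ])
    list(type = "Feature",
         properties = list(area_id = a$area_id, area_ha = a$area_ha,
                           bush_fraction = a$bush_fraction),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) as.numeric(ring[i, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection",
                            features = unname(feats)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a drive-hunt log and its hunted-area polygons
#'
#' @param hunt_log_path CSV with columns `hunt_id`, `area_id`, `date`,
#'   `start`, `end` (ISO 8601 UTC timestamps), `n_beaters`, `n_dogs`,
#'   `n_shooters`, `n_gunshots` and optionally `bush_fraction`.
#' @param areas_path GeoJSON of hunted-area polygons (see
#'   [read_areas()]).
#' @return list with `hunts` (a data frame, in file order, with
#'   per-hectare `dogs_per_ha` and `beaters_per_ha` densities added)
#'   and `areas` (named list of `hm_area`).
#' @export
read_hunts <- function(hunt_log_path, areas_path) {
  areas <- read_areas(areas_path)
  h <- utils::read.csv(hunt_log_path, stringsAsFactors = FALSE)
  need <- c("hunt_id", "area_id", "date", "start", "end",
            "n_beaters", "n_dogs", "n_shooters", "n_gunshots")
  miss <- setdiff(need, names(h))
  if (length(miss))
    stop("format error: missing column(s) ", paste(miss, collapse = ", "))
  dangling <- setdiff(unique(h$area_id), names(areas))
  if (length(dangling))
    stop("reference error: hunt log references unknown area(s) ",
         paste(dangling, collapse = ", "))
  h$start <- parse_utc(as.character(h$start))
  h$end <- parse_utc(as.character(h$end))
  if (anyNA(h$start) || anyNA(h$end)) stop("unparseable hunt start/end times")
  if (any(h$end <= h$start)) stop("validation error: hunt end <= start")
  cnt <- c("n_beaters", "n_dogs", "n_shooters", "n_gunshots")
  if (any(unlist(h[cnt]) < 0)) stop("validation error: negative counts")
  ah <- vapply(areas[h$area_id], `[[`, numeric(1L), "area_ha")
  h$area_ha <- ah
  h$dogs_per_ha <- h$n_dogs / ah
  h$beaters_per_ha <- h$n_beaters / ah
  if (!"bush_fraction" %in% names(h))
    h$bush_fraction <- vapply(areas[h$area_id], `[[`, numeric(1L),
                              "bush_fraction")
  # hunt-log bush supersedes the GeoJSON property where both exist
  for (i in seq_len(nrow(h))) {
    a <- h$area_id[i]
    if (is.na(areas[[a]]$bush_fraction) && is.finite(h$bush_fraction[i]))
      areas[[a]]$bush_fraction <- h$bush_fraction[i]
  }
  list(hunts = h, areas = areas)
}

#' Write a hunt log to CSV
#' @param hunts hunt data frame as returned by [read_hunts()].
#' @param path output path.
#' @export
write_hunts <- function(hunts, path) {
  h <- hunts
  h$date <- format(h$start, "%Y-%m-%d", tz = "UTC")
  h$start <- format(h$start, TS_FMT, tz = "UTC")
  h$end <- format(h$end, TS_FMT, tz = "UTC")
  cols <- c("hunt_id", "area_id", "date", "start", "end", "n_beaters",
            "n_dogs", "n_shooters", "n_gunshots", "bush_fraction")
  utils::write.csv(h[intersect(cols, names(h))], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fix-interval and fix-success report per GPS regime
#'
#' Compares the achieved fix record of one trajectory against the
#' dual collar schedule: 2-min fixes within the 08:00-20:00 local
#' window of hunt days, hourly fixes elsewhere in the trajectory span.
#' A scheduled tick counts as observed when a valid fix lies within
#' half the nominal interval of it.
#'
#' @param traj an `hm_traj`.
#' @param hunts hunt data frame (used for the hunt-day dates); may
#'   have zero rows.
#' @param config an [analysis_config()].
#' @param floor trajectories with success below this fraction in any
#'   non-empty regime are flagged.
#' @return data frame with one row per regime: `regime`, `n_expected`,
#'   `n_observed`, `success`, `flagged`.
#' @export
regime_report <- function(traj, hunts, config = analysis_config(),
                          floor = 0.5) {
  vf <- valid_fixes(traj)
  span <- range(as.numeric(traj$timestamp))
  # the hourly programme only runs during the hunting season; proxy
  # the season by the span of logged hunt days (plus a margin) when
  # hunts are available
  if (nrow(hunts)) {
    season <- range(as.numeric(hunts$start)) + c(0, 1) * 86400
    clamped <- c(max(span[1L], season[1L]), min(span[2L], season[2L]))
    if (clamped[2L] > clamped[1L]) span <- clamped
  }
  hunt_dates <- unique(format(hunts$start, "%Y-%m-%d", tz = config$tz))
  win2 <- lapply(hunt_dates, function(d) {
    s <- as.POSIXct(paste(d, "08:00:00"), tz = config$tz)
    c(max(as.numeric(s), as.numeric(span[1L])),
      min(as.numeric(s) + 12 * 3600, as.numeric(span[2L])))
  })
  win2 <- Filter(function(w) w[2L] > w[1L], win2)
  tick2 <- unlist(lapply(win2, function(w) seq(w[1L], w[2L], by = 120)))
  tickh <- seq(as.numeric(span[1L]), as.numeric(span[2L]), by = 3600)
  if (length(tick2)) {
    in2 <- vapply(tickh, function(t)
      any(vapply(win2, function(w) t >= w[1L] && t <= w[2L], logical(1L))),
      logical(1L))
    tickh <- tickh[!in2]
  }
  tv <- as.numeric(vf$timestamp)
  hit <- function(ticks, tol) {
    if (!length(ticks) || !length(tv)) return(0L)
    idx <- findInterval(ticks, tv)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, length(tv))
    sum(pmin(abs(ticks - tv[lo]), abs(ticks - tv[hi])) <= tol)
  }
  n2 <- length(tick2); o2 <- hit(tick2, 60)
  nh <- length(tickh); oh <- hit(tickh, 1800)
  out <- data.frame(
    regime = c("2min", "hourly"),
    n_expected = c(n2, nh),
    n_observed = c(o2, oh),
    success = c(if (n2) o2 / n2 else NA_real_,
                if (nh) oh / nh else NA_real_))
  out$flagged <- !is.na(out$success) & out$success < floor
  out
}
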