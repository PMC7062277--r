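# Fixed-kernel utilization distribution, isopleth regions and the
# site-familiarity index of a hunted area.

#' Subsample a trajectory to one fix per 12-hour bin
#'
#' Annual home ranges are estimated from one location every 12 hours;
#' within each 12-h bin (aligned to the epoch) the valid fix nearest
#' the bin centre is retained. Deterministic given the input; empty
#' bins are simply skipped.
#'
#' @param traj an `hm_traj`.
#' @param interval_h bin width in hours.
#' @return an `hm_traj` of the retained fixes. Fewer than 30 retained
#'   fixes trigger a warning (kernel range unreliable).
#' @export
annual_relocation_subsample <- function(traj, interval_h = 12) {
  vf <- valid_fixes(traj)
  if (!nrow(vf)) stop("no valid fixes to subsample")
  w <- interval_h * 3600
  tv <- as.numeric(vf$timestamp)
  bin <- floor(tv / w)
  centre <- (bin + 0.5) * w
  off <- abs(tv - centre)
  keep <- unlist(lapply(split(seq_along(bin), bin), function(ix)
    ix[which.min(off[ix])]), use.names = FALSE)
  out <- vf[sort(keep), , drop = FALSE]
  if (nrow(out) < 30L)
    warning("fewer than 30 retained fixes; utilization distribution ",
            "will be unreliable")
  rownames(out) <- NULL
  class(out) <- c("hm_traj", "data.frame")
  out
}

#' Fixed-kernel utilization distribution on a regular grid
#'
#' Bivariate Gaussian kernel density of relocation points, evaluated
#' on a regular grid padded at least `pad_bandwidths` bandwidths
#' beyond the data extent and renormalized to total mass 1. The
#' default bandwidth is the ad hoc bivariate normal reference rule
#' `h = sigma * n^(-1/6)` with `sigma` the mean of the coordinate
#' standard deviations, the convention of the home-range literature.
#'
#' @param points two-column matrix or data frame of (x, y) in metres,
#'   or an `hm_traj`.
#' @param cell_m grid cell size in metres.
#' @param bandwidth `"reference"` or `"fixed_value"`.
#' @param bandwidth_value kernel sd in metres when
#'   `bandwidth = "fixed_value"`.
#' @param pad_bandwidths grid padding beyond the data extent, in
#'   bandwidths.
#' @return object of class `hm_ud`: list with grid coordinates `x`,
#'   `y` (cell centres), density matrix `z` (probability per square
#'   metre, rows indexing `x`), `cell_m` and `h` (the bandwidth used).
#' @export
estimate_ud <- function(points, cell_m = 10,
                        bandwidth = c("reference", "fixed_value"),
                        bandwidth_value = NULL, pad_bandwidths = 3) {
  bandwidth <- match.arg(bandwidth)
  if (inherits(points, "hm_traj")) {
    vf <- valid_fixes(points)
    points <- cbind(vf$x, vf$y)
  }
  p <- as.matrix(points)
  if (nrow(p) < 5L) stop("at least 5 points are required")
  if (any(!is.finite(p))) stop("non-finite coordinates")
  sx <- stats::sd(p[, 1L]); sy <- stats::sd(p[, 2L])
  if (bandwidth == "reference") {
    if (sx == 0 || sy == 0)
      stop("bandwidth error: degenerate point set (zero spread)")
    h <- 0.5 * (sx + sy) * nrow(p)^(-1 / 6)
  } else {
    if (is.null(bandwidth_value) || bandwidth_value <= 0)
      stop("bandwidth_value must be a positive sd in metres")
    h <- bandwidth_value
  }
  pad <- pad_bandwidths * h
  xr <- range(p[, 1L]) + c(-pad, pad)
  yr <- range(p[, 2L]) + c(-pad, pad)
  nx <- max(8L, ceiling(diff(xr) / cell_m))
  ny <- max(8L, ceiling(diff(yr) / cell_m))
  # MASS::kde2d's h argument is 4x the Gaussian kernel sd
  k <- MASS::kde2d(p[, 1L], p[, 2L], h = 4 * h, n = c(nx, ny),
                   lims = c(xr, yr))
  dx <- k$x[2L] - k$x[1L]
  dy <- k$y[2L] - k$y[1L]
  z <- k$z / (sum(k$z) * dx * dy)
  structure(list(x = k$x, y = k$y, z = z, cell_m = c(dx, dy), h = h,
                 n_points = nrow(p)),
            class = "hm_ud")
}

#' @exportS3Method base::print
print.hm_ud <- function(x, ...) {
  cat(sprintf("<hm_ud> %d x %d grid, cell %.1f x %.1f m, h = %.1f m, %d points\n",
              length(x$x), length(x$y), x$cell_m[1L], x$cell_m[2L], x$h,
              x$n_points))
  invisible(x)
}

# default band weights: the printed coefficients 1, .9 and .15 anchor
# a linear descent 1.0, 0.9, ..., 0.2 over the nine full-width bands,
# then 0.15 for the half-width (90-95) band
iso_band_weights <- function() c(seq(1, 0.2, by = -0.1), 0.15)

#' Isopleth regions of a utilization distribution
#'
#' The L% isopleth set is the minimal-area set of grid cells holding
#' probability mass L/100 (cells thresholded on density, sorted
#' descending). Bands are the set differences of successive levels:
#' iso(0-10), iso(10-20), ..., iso(90-95), with decreasing familiarity
#' weights 1.0, 0.9, ..., 0.2, 0.15.
#'
#' @param ud an `hm_ud`.
#' @param levels isopleth levels in percent, increasing.
#' @param weights band weights, one per band (length of `levels`).
#' @return object of class `hm_isopleths`: the grid plus `levels`,
#'   `thresholds` (density thresholds per level), `band` (integer
#'   matrix; band index per cell, `NA` outside the outermost level),
#'   `weights`, `band_area_ha`, `band_mass` and `area_within_ha`
#'   (cumulative area within each level).
#' @export
isopleth_regions <- function(ud, levels = c(seq(10, 90, 10), 95),
                             weights = iso_band_weights()) {
  stopifnot(inherits(ud, "hm_ud"), !is.unsorted(levels),
            length(weights) == length(levels))
  cell_area <- prod(ud$cell_m)
  dens <- as.vector(ud$z)
  ord <- order(dens, decreasing = TRUE)
  cum <- cumsum(dens[ord]) * cell_area
  thr <- numeric(length(levels))
  for (i in seq_along(levels)) {
    k <- which(cum >= levels[i] / 100)[1L]
    if (is.na(k))
      stop("resolution error: level ", levels[i],
           "% mass unreachable on this grid")
    thr[i] <- dens[ord[k]]
  }
  band <- matrix(NA_integer_, nrow(ud$z), ncol(ud$z))
  for (i in rev(seq_along(levels))) band[ud$z >= thr[i]] <- i
  band_mass <- vapply(seq_along(levels), function(i)
    sum(dens[as.vector(band) == i], na.rm = TRUE) * cell_area, numeric(1L))
  band_area <- vapply(seq_along(levels), function(i)
    sum(band == i, na.rm = TRUE) * cell_area / 1e4, numeric(1L))
  structure(list(x = ud$x, y = ud$y, cell_m = ud$cell_m,
                 levels = levels, thresholds = thr, band = band,
                 weights = weights, band_area_ha = band_area,
                 band_mass = band_mass,
                 area_within_ha = cumsum(band_area)),
            class = "hm_isopleths")
}

#' @exportS3Method base::print
print.hm_isopleths <- function(x, ...) {
  cat("<hm_isopleths>\n")
  lab <- paste0("iso(", c(0, x$levels[-length(x$levels)]), "-", x$levels, ")")
  print(data.frame(band = lab, weight = x$weights,
                   area_ha = round(x$band_area_ha, 2),
                   mass = round(x$band_mass, 4)))
  invisible(x)
}

#' Band index at point locations
#'
#' Piecewise-constant lookup of the isopleth band containing each
#' point (the band of the enclosing grid cell); `NA` outside the
#' outermost isopleth or off the grid.
#'
#' @param iso an `hm_isopleths`.
#' @param x,y point coordinates (metres).
#' @return integer vector of band indices.
#' @export
band_at <- function(iso, x, y) {
  dx <- iso$cell_m[1L]; dy <- iso$cell_m[2L]
  ix <- round((x - iso$x[1L]) / dx) + 1L
  iy <- round((y - iso$y[1L]) / dy) + 1L
  out <- rep(NA_integer_, length(x))
  ok <- ix >= 1L & ix <= length(iso$x) & iy >= 1L & iy <= length(iso$y)
  out[ok] <- iso$band[cbind(ix[ok], iy[ok])]
  out
}

#' Site-familiarity index of a hunted area
#'
#' Weighted sum over isopleth bands of the fraction of the hunted
#' area each band overlaps:
#' `Fam = sum_b w_b * area(band_b intersect area) / area(area)`,
#' with weights decreasing from 1 (core, 0-10 band) to 0.15 (90-95
#' band); the portion of the hunted area outside the outermost
#' isopleth contributes 0. Overlaps are computed cell-exactly by
#' clipping the hunted polygon against every grid cell straddling its
#' boundary.
#'
#' @param iso an `hm_isopleths`.
#' @param area an `hm_area`, or a polygon matrix.
#' @return familiarity index in `[0, 1]`, with attribute
#'   `band_fraction` (fraction of the hunted area in each band).
#' @export
familiarity_index <- function(iso, area) {
  poly <- if (inherits(area, "hm_area")) area$polygon else poly_ring(area)
  a_tot <- poly_area_m2(poly)
  if (a_tot <= 0) stop("domain error: zero-area hunted polygon")
  dx <- iso$cell_m[1L]; dy <- iso$cell_m[2L]
  cell_area <- dx * dy
  bb <- apply(poly, 2L, range)
  ix <- which(iso$x + dx / 2 > bb[1L, 1L] & iso$x - dx / 2 < bb[2L, 1L])
  iy <- which(iso$y + dy / 2 > bb[1L, 2L] & iso$y - dy / 2 < bb[2L, 2L])
  nb <- length(iso$weights)
  band_overlap <- numeric(nb)
  if (length(ix) && length(iy)) {
    # corner-based classification: cells with all/no corners inside are
    # full/empty (convex polygons); mixed cells are clipped exactly
    cx <- iso$x[ix]; cy <- iso$y[iy]
    gx <- rep(cx, times = length(cy)); gy <- rep(cy, each = length(cx))
    cnt <- integer(length(gx))
    for (sx in c(-0.5, 0.5)) for (sy in c(-0.5, 0.5))
      cnt <- cnt + point_in_polygon(gx + sx * dx, gy + sy * dy, poly,
                                    boundary = FALSE)
    convex <- is_convex(poly)
    verts_in_cell <- function(x0, x1, y0, y1)
      any(poly[, 1L] >= x0 & poly[, 1L] <= x1 &
            poly[, 2L] >= y0 & poly[, 2L] <= y1)
    for (k in seq_along(gx)) {
      x0 <- gx[k] - dx / 2; x1 <- gx[k] + dx / 2
      y0 <- gy[k] - dy / 2; y1 <- gy[k] + dy / 2
      a <- if (cnt[k] == 4L && convex) cell_area
      else if (cnt[k] == 0L && !verts_in_cell(x0, x1, y0, y1)) 0
      else poly_rect_intersection_area(poly, x0, x1, y0, y1)
      if (a > 0) {
        b <- iso$band[ix[(k - 1L) %% length(ix) + 1L],
                      iy[(k - 1L) %/% length(ix) + 1L]]
        if (!is.na(b)) band_overlap[b] <- band_overlap[b] + a
      }
    }
  }
  frac <- band_overlap / a_tot
  structure(min(1, sum(iso$weights * frac)), band_fraction = frac)
}

#' Construct a square polygon wholly inside one isopleth band
#'
#' Searches the grid for a position where a square of half-width
#' `half_m` fits entirely within the cells of the requested band
#' (shrinking the square if necessary), and verifies the fit. Band
#' index 0 requests a square wholly outside the outermost isopleth.
#' Intended for constructing definitional test cases of the
#' familiarity index (a polygon wholly inside band b has familiarity
#' exactly the band weight).
#'
#' @param iso an `hm_isopleths`.
#' @param band_index integer band (1 = innermost), or 0 for outside.
#' @param half_m requested half-width of the square, metres.
#' @return polygon matrix (4 vertices).
#' @export
band_probe_polygon <- function(iso, band_index, half_m = NULL) {
  dx <- iso$cell_m[1L]; dy <- iso$cell_m[2L]
  if (is.null(half_m)) half_m <- 3 * max(dx, dy)
  square <- function(cx, cy, h)
    cbind(cx + c(-1, 1, 1, -1) * h, cy + c(-1, -1, 1, 1) * h)
  if (band_index == 0L) {
    # beyond the grid is by construction outside every isopleth
    return(square(iso$x[length(iso$x)] + 10 * half_m,
                  iso$y[length(iso$y)] + 10 * half_m, half_m))
  }
  target <- !is.na(iso$band) & iso$band == band_index
  fits <- function(icx, icy, h) {
    rx <- which(abs(iso$x - iso$x[icx]) <= h + dx / 2)
    ry <- which(abs(iso$y - iso$y[icy]) <= h + dy / 2)
    length(rx) > 0 && length(ry) > 0 && all(target[rx, ry])
  }
  cand <- which(target, arr.ind = TRUE)
  if (!nrow(cand)) stop("band ", band_index, " holds no grid cell")
  for (h in half_m * c(1, 0.5, 0.25)) {
    step <- max(1L, floor(h / dx))
    ok <- cand[, 1L] > step & cand[, 1L] <= nrow(target) - step &
      cand[, 2L] > step & cand[, 2L] <= ncol(target) - step
    for (k in which(ok)) {
      if (fits(cand[k, 1L], cand[k, 2L], h))
        return(square(iso$x[cand[k, 1L]], iso$y[cand[k, 2L]], h))
    }
  }
  stop("no square of the requested size fits inside band ", band_index,
       "; refine the grid or shrink half_m")
}

# convexity of a simple polygon: consistent cross-product sign
is_convex <- function(poly) {
  p <- poly_ring(poly)
  n <- nrow(p)
  i1 <- seq_len(n); i2 <- c(i1[-1L], 1L); i3 <- c(i2[-1L], 1L)
  cr <- (p[i2, 1L] - p[i1, 1L]) * (p[i3, 2L] - p[i2, 2L]) -
    (p[i2, 2L] - p[i1, 2L]) * (p[i3, 1L] - p[i2, 1L])
  all(cr >= -1e-9) || all(cr <= 1e-9)
}
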