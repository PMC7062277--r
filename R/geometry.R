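# Planar geometry for projected (metric) coordinates.
#
# All polygons are two-column numeric matrices (x, y) of vertices in
# metres, given in ring order, *not* closed (first vertex is not
# repeated at the end). Simple (non-self-intersecting) rings are
# assumed; orientation is irrelevant.

#' Normalize a polygon matrix
#'
#' Accepts a two-column matrix or data frame, closed or open, and
#' returns an open two-column numeric matrix. Used by all geometry
#' helpers so that rings read from GeoJSON (closed) and rings built in
#' code (open) are interchangeable.
#'
#' @param poly two-column matrix or data frame of vertex coordinates.
#' @return open two-column numeric matrix.
#' @keywords internal
poly_ring <- function(poly) {
  p <- as.matrix(poly)
  if (!is.numeric(p) || ncol(p) != 2L)
    stop("polygon must be a two-column numeric matrix of (x, y) vertices")
  n <- nrow(p)
  if (n >= 2L && all(p[1L, ] == p[n, ])) p <- p[-n, , drop = FALSE]
  if (nrow(p) < 3L) stop("polygon needs at least 3 distinct vertices")
  if (any(!is.finite(p))) stop("polygon vertices must be finite")
  dimnames(p) <- list(NULL, c("x", "y"))
  p
}

#' Polygon area (shoelace formula)
#'
#' @param poly polygon matrix (see [poly_ring()]).
#' @return area in square metres (non-negative).
#' @examples
#' poly_area_m2(cbind(c(0, 1000, 1000, 0), c(0, 0, 1010, 1010))) # 1.01e6
#' @export
poly_area_m2 <- function(poly) {
  p <- poly_ring(poly)
  x <- p[, 1L]; y <- p[, 2L]
  j <- c(seq_len(nrow(p))[-1L], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Polygon centroid
#' @param poly polygon matrix.
#' @return numeric length-2 (x, y) centroid of the polygon interior.
#' @export
poly_centroid <- function(poly) {
  p <- poly_ring(poly)
  x <- p[, 1L]; y <- p[, 2L]
  j <- c(seq_len(nrow(p))[-1L], 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(p))
  c(sum((x + x[j]) * cr) / (6 * a), sum((y + y[j]) * cr) / (6 * a))
}

#' Point-in-polygon test with explicit boundary handling
#'
#' Even-odd (ray crossing) rule, vectorized over points. Points within
#' `tol` metres of an edge are treated as on the boundary; by default
#' boundary points count as inside, matching the convention that an
#' animal standing exactly on the shooting line has not crossed it.
#'
#' @param x,y point coordinates (metres), equal length.
#' @param poly polygon matrix.
#' @param boundary logical; should boundary points count as inside?
#' @param tol boundary snap tolerance in metres.
#' @return logical vector.
#' @export
point_in_polygon <- function(x, y, poly, boundary = TRUE, tol = 1e-9) {
  p <- poly_ring(poly)
  n <- nrow(p)
  stopifnot(length(x) == length(y))
  inside <- logical(length(x))
  onb <- logical(length(x))
  xs <- p[, 1L]; ys <- p[, 2L]
  jprev <- c(n, seq_len(n - 1L))
  for (k in seq_len(n)) {
    x1 <- xs[jprev[k]]; y1 <- ys[jprev[k]]
    x2 <- xs[k];        y2 <- ys[k]
    dx <- x2 - x1; dy <- y2 - y1
    l2 <- dx * dx + dy * dy
    tt <- if (l2 > 0) pmin(1, pmax(0, ((x - x1) * dx + (y - y1) * dy) / l2)) else 0
    d2 <- (x1 + tt * dx - x)^2 + (y1 + tt * dy - y)^2
    onb <- onb | d2 <= tol * tol
    crosses <- ((y1 > y) != (y2 > y))
    if (any(crosses)) {
      xint <- x1 + (y - y1) / (y2 - y1) * dx
      inside <- xor(inside, crosses & x < xint)
    }
  }
  if (boundary) inside | onb else inside & !onb
}

#' Signed distance from points to a polygon boundary
#'
#' Negative inside the polygon, positive outside, zero on the
#' boundary. Used for boundary-buffered flee/stay classification and
#' for conditioning simulated walks.
#'
#' @inheritParams point_in_polygon
#' @return numeric vector of signed distances in metres.
#' @export
signed_distance <- function(x, y, poly) {
  p <- poly_ring(poly)
  n <- nrow(p)
  d2min <- rep(Inf, length(x))
  jprev <- c(n, seq_len(n - 1L))
  for (k in seq_len(n)) {
    x1 <- p[jprev[k], 1L]; y1 <- p[jprev[k], 2L]
    x2 <- p[k, 1L];        y2 <- p[k, 2L]
    dx <- x2 - x1; dy <- y2 - y1
    l2 <- dx * dx + dy * dy
    tt <- if (l2 > 0) pmin(1, pmax(0, ((x - x1) * dx + (y - y1) * dy) / l2)) else 0
    d2 <- (x1 + tt * dx - x)^2 + (y1 + tt * dy - y)^2
    d2min <- pmin(d2min, d2)
  }
  d <- sqrt(d2min)
  ifelse(point_in_polygon(x, y, p, boundary = TRUE), -d, d)
}

# Clip a polygon by the half-plane {a*x + b*y <= c} (Sutherland-Hodgman
# step). Returns an open matrix, possibly with 0 rows.
clip_halfplane <- function(p, a, b, c) {
  n <- nrow(p)
  if (n == 0L) return(p)
  val <- a * p[, 1L] + b * p[, 2L] - c
  keep <- val <= 0
  out <- matrix(numeric(0), ncol = 2L)
  for (k in seq_len(n)) {
    kprev <- if (k == 1L) n else k - 1L
    if (keep[kprev] != keep[k]) {
      # edge crosses the clip line: add intersection point
      t <- val[kprev] / (val[kprev] - val[k])
      out <- rbind(out, p[kprev, ] + t * (p[k, ] - p[kprev, ]))
    }
    if (keep[k]) out <- rbind(out, p[k, ])
  }
  out
}

#' Area of intersection between a polygon and an axis-aligned rectangle
#'
#' Sutherland-Hodgman clipping of the polygon against the four
#' rectangle half-planes; exact for simple polygons. This is the
#' primitive behind cellwise isopleth-band / hunted-area overlaps.
#'
#' @param poly polygon matrix.
#' @param x0,x1,y0,y1 rectangle bounds (metres), `x0 < x1`, `y0 < y1`.
#' @return intersection area in square metres.
#' @export
poly_rect_intersection_area <- function(poly, x0, x1, y0, y1) {
  p <- poly_ring(poly)
  p <- clip_halfplane(p, -1, 0, -x0)   # x >= x0
  if (nrow(p) < 3L) return(0)
  p <- clip_halfplane(p, 1, 0, x1)     # x <= x1
  if (nrow(p) < 3L) return(0)
  p <- clip_halfplane(p, 0, -1, -y0)   # y >= y0
  if (nrow(p) < 3L) return(0)
  p <- clip_halfplane(p, 0, 1, y1)     # y <= y1
  if (nrow(p) < 3L) return(0)
  x <- p[, 1L]; y <- p[, 2L]
  j <- c(seq_len(nrow(p))[-1L], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Random convex polygon of a given area
#'
#' Draws vertices at sorted random angles with jittered radii around a
#' centre, takes the convex hull, and rescales about the centroid so
#' the area matches `area_ha` exactly. Used by the synthetic generator
#' to emulate hunted-area polygons.
#'
#' @param centre numeric length-2 centre (metres).
#' @param area_ha target area in hectares.
#' @param n_vertices number of candidate vertices.
#' @return polygon matrix with exact area `area_ha`.
#' @export
random_convex_polygon <- function(centre, area_ha, n_vertices = 12L) {
  stopifnot(area_ha > 0)
  ang <- sort(stats::runif(n_vertices, 0, 2 * pi))
  rad <- stats::runif(n_vertices, 0.7, 1.3)
  p <- cbind(centre[1L] + rad * cos(ang), centre[2L] + rad * sin(ang))
  p <- p[grDevices::chull(p), , drop = FALSE]
  cen <- poly_centroid(p)
  s <- sqrt(area_ha * 1e4 / poly_area_m2(p))
  cbind(cen[1L] + s * (p[, 1L] - cen[1L]), cen[2L] + s * (p[, 2L] - cen[2L]))
}

#' Uniform random points inside a polygon
#'
#' Rejection sampling from the bounding box.
#'
#' @param n number of points.
#' @param poly polygon matrix.
#' @return n-by-2 matrix of points.
#' @export
runif_in_polygon <- function(n, poly) {
  p <- poly_ring(poly)
  bb <- apply(p, 2L, range)
  out <- matrix(NA_real_, 0L, 2L)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 100L)
    cand <- cbind(stats::runif(m, bb[1L, 1L], bb[2L, 1L]),
                  stats::runif(m, bb[1L, 2L], bb[2L, 2L]))
    keep <- point_in_polygon(cand[, 1L], cand[, 2L], p)
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}
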