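# Planar geometry primitives used by snapping and buffer-feature extraction.
# All routines work in a projected metric CRS (coordinates in meters).

#' Project WGS84 coordinates to a local metric plane
#'
#' Equirectangular projection about a reference point: x = R cos(lat0) dlon,
#' y = R dlat (radians). Adequate at the city scale (tens of km) where the
#' distortion is well below GPS error; inter-city distances use great-circle
#' arithmetic instead.
#'
#' @param lon,lat Numeric vectors of WGS84 coordinates in degrees.
#' @param origin Numeric length-2 `c(lon0, lat0)` reference point in degrees.
#' @return A two-column matrix of x/y coordinates in meters.
#' @export
project_local <- function(lon, lat, origin) {
  stopifnot(length(origin) == 2, is.finite(origin))
  R <- 6371008.8
  rad <- pi / 180
  x <- R * cos(origin[2] * rad) * (lon - origin[1]) * rad
  y <- R * (lat - origin[2]) * rad
  cbind(x = x, y = y)
}

# Distance from points (px, py) to the segment (x1,y1)-(x2,y2).
.dist_point_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1
  dy <- y2 - y1
  L2 <- dx * dx + dy * dy
  if (L2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- ((px - x1) * dx + (py - y1) * dy) / L2
  t <- pmin(1, pmax(0, t))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

# Minimum distance from each point (n x 2 matrix) to a polyline (m x 2 matrix).
.dist_points_polyline <- function(pts, line) {
  d <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(line) - 1L)) {
    d <- pmin(d, .dist_point_segment(pts[, 1], pts[, 2],
                                     line[i, 1], line[i, 2],
                                     line[i + 1L, 1], line[i + 1L, 2]))
  }
  d
}

# Midpoint of a polyline by arc length.
.polyline_midpoint <- function(line) {
  seg <- sqrt(diff(line[, 1])^2 + diff(line[, 2])^2)
  total <- sum(seg)
  if (total == 0) return(line[1, ])
  half <- total / 2
  cum <- c(0, cumsum(seg))
  i <- max(which(cum <= half))
  if (i >= nrow(line)) return(line[nrow(line), ])
  t <- (half - cum[i]) / seg[i]
  line[i, ] + t * (line[i + 1L, ] - line[i, ])
}

.polyline_length <- function(line) {
  sum(sqrt(diff(line[, 1])^2 + diff(line[, 2])^2))
}

#' Area of the intersection of a polygon and a disk
#'
#' Exact (to floating point) via Green's theorem: each polygon edge is split
#' at its circle crossings; sub-segments inside the disk contribute triangle
#' terms, sub-segments outside contribute circular-sector terms. Handles
#' non-convex rings; holes are not supported.
#'
#' @param poly Two-column matrix of ring vertices (closed or open).
#' @param center Numeric length-2 disk center.
#' @param r Disk radius (same units as coordinates).
#' @return Intersection area (>= 0).
#' @export
disk_polygon_area <- function(poly, center, r) {
  stopifnot(is.matrix(poly), ncol(poly) == 2, r >= 0)
  if (r == 0 || nrow(poly) < 3) return(0)
  # drop explicit closure
  n <- nrow(poly)
  if (all(poly[1, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  n <- nrow(poly)
  if (n < 3) return(0)
  px <- poly[, 1] - center[1]
  py <- poly[, 2] - center[2]
  total <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    total <- total + .disk_edge_contrib(c(px[i], py[i]), c(px[j], py[j]), r)
  }
  abs(total)
}

# Green's-theorem contribution of one edge (coordinates relative to center).
.disk_edge_contrib <- function(u, v, r) {
  d <- v - u
  a <- sum(d * d)
  if (a == 0) return(0)
  b <- 2 * sum(u * d)
  cc <- sum(u * u) - r * r
  disc <- b * b - 4 * a * cc
  ts <- c(0, 1)
  if (disc > 0) {
    sq <- sqrt(disc)
    t1 <- (-b - sq) / (2 * a)
    t2 <- (-b + sq) / (2 * a)
    ts <- sort(unique(c(0, 1, pmin(1, pmax(0, c(t1, t2))))))
  }
  contrib <- 0
  for (k in seq_len(length(ts) - 1L)) {
    p <- u + ts[k] * d
    q <- u + ts[k + 1L] * d
    mid <- u + (ts[k] + ts[k + 1L]) / 2 * d
    if (sum(mid * mid) <= r * r * (1 + 1e-12)) {
      contrib <- contrib + 0.5 * (p[1] * q[2] - p[2] * q[1])
    } else {
      ang <- atan2(p[1] * q[2] - p[2] * q[1], sum(p * q))
      contrib <- contrib + 0.5 * r * r * ang
    }
  }
  contrib
}

#' Length of a polyline inside a disk
#'
#' Closed-form chord clipping per edge (quadratic in the line parameter).
#'
#' @param line Two-column matrix of polyline vertices.
#' @param center Numeric length-2 disk center.
#' @param r Disk radius.
#' @return Total clipped length (>= 0).
#' @export
disk_polyline_length <- function(line, center, r) {
  stopifnot(is.matrix(line), ncol(line) == 2, r >= 0)
  if (r == 0 || nrow(line) < 2) return(0)
  total <- 0
  for (i in seq_len(nrow(line) - 1L)) {
    u <- line[i, ] - center
    d <- line[i + 1L, ] - line[i, ]
    a <- sum(d * d)
    if (a == 0) next
    b <- 2 * sum(u * d)
    cc <- sum(u * u) - r * r
    disc <- b * b - 4 * a * cc
    if (disc <= 0) next
    sq <- sqrt(disc)
    t1 <- max(0, (-b - sq) / (2 * a))
    t2 <- min(1, (-b + sq) / (2 * a))
    if (t2 > t1) total <- total + (t2 - t1) * sqrt(a)
  }
  total
}

# Shoelace area of a ring (absolute value).
.polygon_area <- function(poly) {
  n <- nrow(poly)
  if (all(poly[1, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  n <- nrow(poly)
  if (n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}
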