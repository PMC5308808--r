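# Planar geometry primitives for street centerlines.
#
# All operations assume a projected CRS in meters. Polylines are n x 2
# matrices (columns x, y) with n >= 2. Azimuths are degrees clockwise from
# north in [0, 360).

polyline_length <- function(m) {
  d <- diff(m)
  sum(sqrt(rowSums(d^2)))
}

cum_chainage <- function(m) {
  d <- diff(m)
  c(0, cumsum(sqrt(rowSums(d^2))))
}

# Azimuth of the direction (dx, dy): clockwise from north.
azimuth_deg <- function(dx, dy) {
  (atan2(dx, dy) * 180 / pi) %% 360
}

# Distance from points (px, py) to the segment a-b; returns the distances.
point_segment_distance <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  len2 <- vx^2 + vy^2
  if (len2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / len2))
  sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
}

# Closest point on polyline `m` to point p = c(x, y); returns list(point, dist).
closest_point_on_polyline <- function(p, m) {
  best <- list(point = m[1, ], dist = Inf)
  for (i in seq_len(nrow(m) - 1L)) {
    a <- m[i, ]; b <- m[i + 1L, ]
    v <- b - a
    len2 <- sum(v^2)
    t <- if (len2 == 0) 0 else min(1, max(0, sum((p - a) * v) / len2))
    q <- a + t * v
    d <- sqrt(sum((p - q)^2))
    if (d < best$dist) best <- list(point = q, dist = d)
  }
  best
}

# Dominant direction of a polyline in degrees mod 180 (principal axis of the
# vertex scatter; falls back to the end-to-end chord for two-vertex lines).
polyline_direction <- function(m) {
  if (nrow(m) == 2L) {
    return(azimuth_deg(m[2, 1] - m[1, 1], m[2, 2] - m[1, 2]) %% 180)
  }
  c0 <- sweep(m, 2, colMeans(m))
  cv <- crossprod(c0) / nrow(m)
  e <- eigen(cv, symmetric = TRUE)
  v <- e$vectors[, 1]
  azimuth_deg(v[1], v[2]) %% 180
}

# Acute angle between two undirected directions given in degrees mod 180.
direction_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  min(d, 180 - d)
}

# Symmetric vertex-to-polyline Hausdorff distance (adequate for densely
# vertexed centerlines; documented approximation).
hausdorff_distance <- function(a, b) {
  da <- max(vapply(seq_len(nrow(a)), function(i)
    closest_point_on_polyline(a[i, ], b)$dist, numeric(1)))
  db <- max(vapply(seq_len(nrow(b)), function(i)
    closest_point_on_polyline(b[i, ], a)$dist, numeric(1)))
  max(da, db)
}

# Point at `chainage` meters along polyline `m`; returns list(point, edge)
# where edge is the index of the polyline edge containing the chainage
# (the following edge at an interior vertex, the last edge at the end).
interpolate_along <- function(m, chainage) {
  cc <- cum_chainage(m)
  L <- cc[length(cc)]
  ch <- min(max(chainage, 0), L)
  if (ch >= L) {
    edge <- nrow(m) - 1L
    return(list(point = m[nrow(m), ], edge = edge))
  }
  edge <- findInterval(ch, cc, rightmost.closed = FALSE)
  a <- m[edge, ]; b <- m[edge + 1L, ]
  seg_len <- cc[edge + 1L] - cc[edge]
  t <- if (seg_len == 0) 0 else (ch - cc[edge]) / seg_len
  list(point = a + t * (b - a), edge = edge)
}

# --- local azimuthal equidistant projection (spherical) -------------------

EARTH_RADIUS_M <- 6371008.8

#' Project geographic coordinates to local planar meters
#'
#' Forward spherical azimuthal-equidistant projection centered on the study
#' area, so that distances from the center are preserved exactly and metric
#' parameters (50 m sampling, 2-30 m buffers, 3 km study radius) are
#' meaningful. The inverse is [aeqd_inverse()].
#'
#' @param lon,lat Geographic coordinates (degrees).
#' @param center `c(lon, lat)` of the projection center.
#' @return A two-column matrix of x, y in meters.
#' @export
aeqd_project <- function(lon, lat, center) {
  lam <- lon * pi / 180; phi <- lat * pi / 180
  lam0 <- center[1] * pi / 180; phi0 <- center[2] * pi / 180
  cosc <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  cosc <- pmin(1, pmax(-1, cosc))
  c_ang <- acos(cosc)
  k <- ifelse(c_ang < 1e-12, 1, c_ang / sin(c_ang))
  x <- EARTH_RADIUS_M * k * cos(phi) * sin(lam - lam0)
  y <- EARTH_RADIUS_M * k *
    (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam - lam0))
  cbind(x = x, y = y)
}

#' @rdname aeqd_project
#' @param x,y Planar coordinates in meters.
#' @return For the inverse, a two-column matrix of lon, lat in degrees.
#' @export
aeqd_inverse <- function(x, y, center) {
  lam0 <- center[1] * pi / 180; phi0 <- center[2] * pi / 180
  rho <- sqrt(x^2 + y^2)
  c_ang <- rho / EARTH_RADIUS_M
  phi <- ifelse(rho < 1e-9, phi0,
                asin(cos(c_ang) * sin(phi0) + y * sin(c_ang) * cos(phi0) / rho))
  lam <- lam0 + ifelse(rho < 1e-9, 0,
                       atan2(x * sin(c_ang),
                             rho * cos(phi0) * cos(c_ang) -
                               y * sin(phi0) * sin(c_ang)))
  cbind(lon = lam * 180 / pi, lat = phi * 180 / pi)
}

# TRUE when coordinates look like raw lon/lat degrees rather than meters:
# they fit in the lon/lat domain AND span less than one unit (a downtown
# study area is ~0.06 degrees across but tens to thousands of meters).
looks_geographic <- function(m) {
  if (nrow(m) == 0) return(FALSE)
  all(abs(m[, 1]) <= 180) && all(abs(m[, 2]) <= 90) &&
    max(diff(range(m[, 1])), diff(range(m[, 2]))) < 1
}

# --- ring (simple closed polygon) helpers ---------------------------------

# Ray-casting point-in-polygon; ring is a closed or open n x 2 matrix.
point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  if (all(ring[1, ] == ring[n, ])) { ring <- ring[-n, , drop = FALSE]; n <- n - 1L }
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if (((yi > py) != (yj > py)) &&
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)) inside <- !inside
    j <- i
  }
  inside
}

ring_area <- function(ring) {
  n <- nrow(ring)
  if (all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  x <- ring[, 1]; y <- ring[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}
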