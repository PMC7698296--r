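# Planar geometry primitives on a projected metric coordinate system.
# All coordinates are metres; all functions are pure.

#' Create a point-set geometry
#'
#' @param xy two-column matrix (or data.frame) of x/y coordinates in metres.
#' @return An object of class `fv_points`.
#' @export
fv_points <- function(xy) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2) stop("points need exactly two columns (x, y)")
  storage.mode(xy) <- "double"
  colnames(xy) <- c("x", "y")
  structure(xy, class = c("fv_points", "matrix", "array"))
}

#' Create a polyline-set geometry
#'
#' @param coords list of two-column coordinate matrices, one per polyline.
#' @return An object of class `fv_lines`.
#' @export
fv_lines <- function(coords) {
  coords <- lapply(coords, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 2 || nrow(m) < 2) stop("each polyline needs >= 2 (x, y) rows")
    storage.mode(m) <- "double"
    m
  })
  structure(coords, class = "fv_lines")
}

#' Create a polygon-set geometry
#'
#' Each polygon is a single outer ring (two-column matrix, not necessarily
#' closed; closure is implied). Holes are not supported.
#'
#' @param rings list of two-column coordinate matrices, one outer ring each.
#' @return An object of class `fv_polygons`.
#' @export
fv_polygons <- function(rings) {
  rings <- lapply(rings, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 2 || nrow(m) < 3) stop("each ring needs >= 3 (x, y) rows")
    storage.mode(m) <- "double"
    # drop an explicitly closed last vertex
    if (isTRUE(all.equal(m[1, ], m[nrow(m), ], check.attributes = FALSE)))
      m <- m[-nrow(m), , drop = FALSE]
    m
  })
  structure(rings, class = "fv_polygons")
}

## -- distances -------------------------------------------------------------

# squared distances from many points to one point
.dist2_to_point <- function(px, py, qx, qy) (px - qx)^2 + (py - qy)^2

# distance from points (px, py) to a single segment a-b
.dist_points_segment <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  L2 <- vx * vx + vy * vy
  if (L2 == 0) return(sqrt(.dist2_to_point(px, py, ax, ay)))
  t <- ((px - ax) * vx + (py - ay) * vy) / L2
  t <- pmin(1, pmax(0, t))
  sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
}

# distance from points to a polyline (matrix of vertices)
.dist_points_polyline <- function(px, py, coords) {
  d <- rep(Inf, length(px))
  for (i in seq_len(nrow(coords) - 1L)) {
    d <- pmin(d, .dist_points_segment(px, py, coords[i, 1], coords[i, 2],
                                      coords[i + 1, 1], coords[i + 1, 2]))
  }
  d
}

# ray-casting point-in-ring test; points on the boundary count as inside
.points_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  xs <- ring[, 1]; ys <- ring[, 2]
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  # boundary: distance to closed ring == 0 (within tolerance)
  ring_closed <- rbind(ring, ring[1, ])
  on_edge <- .dist_points_polyline(px, py, ring_closed) < 1e-9
  inside | on_edge
}

#' Distance from points to the nearest feature of a geometry set
#'
#' For polygons the distance is zero when the point lies inside (or on the
#' boundary of) any polygon, otherwise the distance to the nearest boundary.
#'
#' @param pts two-column matrix of query points, or a length-2 vector.
#' @param features an `fv_points`, `fv_lines` or `fv_polygons` object.
#' @return numeric vector of distances in metres.
#' @export
nearest_distance <- function(pts, features) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  pts <- as.matrix(pts)
  px <- pts[, 1]; py <- pts[, 2]
  if (inherits(features, "fv_points")) {
    if (nrow(features) == 0) stop("empty point feature set")
    d <- rep(Inf, length(px))
    for (i in seq_len(nrow(features)))
      d <- pmin(d, sqrt(.dist2_to_point(px, py, features[i, 1], features[i, 2])))
    return(d)
  }
  if (inherits(features, "fv_lines")) {
    if (length(features) == 0) stop("empty polyline feature set")
    d <- rep(Inf, length(px))
    for (coords in features) d <- pmin(d, .dist_points_polyline(px, py, coords))
    return(d)
  }
  if (inherits(features, "fv_polygons")) {
    if (length(features) == 0) stop("empty polygon feature set")
    d <- rep(Inf, length(px))
    inside <- logical(length(px))
    for (ring in features) {
      inside <- inside | .points_in_ring(px, py, ring)
      d <- pmin(d, .dist_points_polyline(px, py, rbind(ring, ring[1, ])))
    }
    d[inside] <- 0
    return(d)
  }
  stop("unsupported feature type: ", paste(class(features), collapse = "/"))
}

## -- union of equal-radius disks -------------------------------------------

# Merge angular intervals (lo, hi), all within [0, 2*pi) after wrap-splitting.
# Returns a matrix of disjoint merged intervals sorted by lo, or NULL if the
# full circle is covered.
.merge_arcs <- function(lo, hi) {
  two_pi <- 2 * pi
  lo <- lo %% two_pi
  hi <- hi %% two_pi
  wrap <- hi < lo
  if (any(wrap)) {
    lo <- c(lo[!wrap], lo[wrap], rep(0, sum(wrap)))
    hi <- c(hi[!wrap], rep(two_pi, sum(wrap)), hi[wrap])
  }
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  mlo <- lo[1]; mhi <- hi[1]
  out <- NULL
  for (i in seq_along(lo)[-1]) {
    if (lo[i] <= mhi + 1e-12) mhi <- max(mhi, hi[i])
    else { out <- rbind(out, c(mlo, mhi)); mlo <- lo[i]; mhi <- hi[i] }
  }
  out <- rbind(out, c(mlo, mhi))
  if (nrow(out) == 1 && out[1, 1] <= 1e-12 && out[1, 2] >= two_pi - 1e-12)
    return(NULL)
  out
}

# Boundary of the union of equal-radius disks around `centers` (one connected
# component). Returns list of rings (two-column matrices, open, counter-
# clockwise around the filled region; holes come out clockwise), plus signed
# area (m^2) and area-weighted centroid.
.disk_union <- function(centers, r, n_seg = 64) {
  centers <- as.matrix(centers)
  # coincident centers give identical disks; keep one representative
  if (nrow(centers) > 1) {
    dd <- as.matrix(stats::dist(centers))
    keep <- !vapply(seq_len(nrow(centers)), function(i)
      any(dd[i, seq_len(i - 1)] < 1e-9), logical(1))
    centers <- centers[keep, , drop = FALSE]
  }
  m <- nrow(centers)
  two_pi <- 2 * pi
  step <- two_pi / n_seg
  circle_ring <- function(cx, cy, a0, da) {
    nseg <- max(2L, ceiling(da / step))
    th <- a0 + da * seq(0, 1, length.out = nseg + 1L)
    cbind(cx + r * cos(th), cy + r * sin(th))
  }
  if (m == 1) {
    ring <- circle_ring(centers[1, 1], centers[1, 2], 0, two_pi)
    ring <- ring[-nrow(ring), , drop = FALSE]
    g <- .ring_measures(ring)
    return(list(rings = list(ring), area = g$area, centroid = g$centroid))
  }
  # uncovered arcs of each circle
  arcs <- list()  # each: c(i, a0, da)
  for (i in seq_len(m)) {
    d <- sqrt((centers[, 1] - centers[i, 1])^2 + (centers[, 2] - centers[i, 2])^2)
    nb <- which(d < 2 * r & seq_len(m) != i)
    if (length(nb) == 0) stop("disconnected disk in a merged component")
    phi <- atan2(centers[nb, 2] - centers[i, 2], centers[nb, 1] - centers[i, 1])
    beta <- acos(pmin(1, d[nb] / (2 * r)))
    cov <- .merge_arcs(phi - beta, phi + beta)
    if (is.null(cov)) next  # circle fully interior
    k <- nrow(cov)
    for (j in seq_len(k)) {
      a0 <- cov[j, 2]
      a1 <- if (j < k) cov[j + 1, 1] else cov[1, 1] + two_pi
      da <- a1 - a0
      if (da > 1e-10) arcs[[length(arcs) + 1L]] <- c(i, a0, da)
    }
  }
  if (length(arcs) == 0) stop("disk union produced no boundary arcs")
  A <- do.call(rbind, arcs)
  sx <- centers[A[, 1], 1] + r * cos(A[, 2])
  sy <- centers[A[, 1], 2] + r * sin(A[, 2])
  ex <- centers[A[, 1], 1] + r * cos(A[, 2] + A[, 3])
  ey <- centers[A[, 1], 2] + r * sin(A[, 2] + A[, 3])
  used <- logical(nrow(A))
  tol <- 1e-6 * max(1, r)
  rings <- list()
  while (any(!used)) {
    cur <- which(!used)[1]
    ring_pts <- NULL
    start <- c(sx[cur], sy[cur])
    repeat {
      used[cur] <- TRUE
      seg <- circle_ring(centers[A[cur, 1], 1], centers[A[cur, 1], 2],
                         A[cur, 2], A[cur, 3])
      ring_pts <- rbind(ring_pts, seg[-nrow(seg), , drop = FALSE])
      endp <- c(ex[cur], ey[cur])
      if (sqrt(sum((endp - start)^2)) < tol) break
      cand <- which(!used)
      if (length(cand) == 0) stop("open disk-union boundary: no matching arc")
      dd <- sqrt((sx[cand] - endp[1])^2 + (sy[cand] - endp[2])^2)
      nxt <- cand[which.min(dd)]
      if (min(dd) > tol) stop("open disk-union boundary: nearest arc too far")
      cur <- nxt
    }
    rings[[length(rings) + 1L]] <- ring_pts
  }
  area <- 0; cx <- 0; cy <- 0
  for (ring in rings) {
    g <- .ring_measures(ring)
    area <- area + g$area
    cx <- cx + g$area * g$centroid[1]
    cy <- cy + g$area * g$centroid[2]
  }
  list(rings = rings, area = area, centroid = c(cx / area, cy / area))
}

# signed shoelace area and centroid of an open ring
.ring_measures <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  a <- sum(cross) / 2
  if (abs(a) < 1e-12) return(list(area = 0, centroid = colMeans(ring)))
  cx <- sum((x + xn) * cross) / (6 * a)
  cy <- sum((y + yn) * cross) / (6 * a)
  list(area = a, centroid = c(cx, cy))
}
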