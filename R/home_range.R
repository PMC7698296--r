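# Kernel utilization distributions and isopleth home ranges. The smoothing
# factor h is the standard deviation (metres) of a bivariate Gaussian kernel
# centred on each fix; the 95% isopleth defines the home range and the 50%
# isopleth the core area.

#' Kernel utilization distribution
#'
#' Bivariate Gaussian kernel density (one kernel of standard deviation `h`
#' per fix) evaluated on a square grid padded at least `4 * h` beyond the
#' bounding box of the fixes and normalized to unit volume.
#'
#' @param xy two-column matrix of fix coordinates (metres).
#' @param h kernel standard deviation in metres (default 750).
#' @param cell_size grid cell edge in metres (default 100).
#' @return An object of class `kernel_ud`: list with `density` (matrix,
#'   rows south to north), `xll`, `yll`, `cell_size`, `h`.
#' @export
kernel_ud <- function(xy, h = 750, cell_size = 100) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  xy <- as.matrix(xy)
  stopifnot(nrow(xy) >= 1, h > 0, cell_size > 0)
  pad <- 4 * h
  xr <- range(xy[, 1]); yr <- range(xy[, 2])
  xll <- xr[1] - pad; yll <- yr[1] - pad
  nx <- ceiling((xr[2] + pad - xll) / cell_size)
  ny <- ceiling((yr[2] + pad - yll) / cell_size)
  gx <- xll + (seq_len(nx) - 0.5) * cell_size
  gy <- yll + (seq_len(ny) - 0.5) * cell_size
  dens <- matrix(0, ny, nx)
  for (i in seq_len(nrow(xy))) {
    dens <- dens + outer(stats::dnorm(gy, xy[i, 2], h),
                         stats::dnorm(gx, xy[i, 1], h))
  }
  dens <- dens / nrow(xy)
  dens <- dens / (sum(dens) * cell_size^2)  # exact unit volume on the grid
  structure(list(density = dens, xll = xll, yll = yll,
                 cell_size = cell_size, h = h),
            class = "kernel_ud")
}

#' Isopleth (smallest region holding a given fraction of the UD)
#'
#' Cells are sorted by density (descending) and accumulated until the target
#' volume fraction is reached; the selected cell set is the isopleth region.
#'
#' @param ud a `kernel_ud`.
#' @param level volume fraction in (0, 1), e.g. 0.95 or 0.50.
#' @return An object of class `isopleth`: list with `mask` (logical matrix),
#'   `area_km2`, `level`, and the grid metadata of `ud`.
#' @export
isopleth <- function(ud, level) {
  stopifnot(inherits(ud, "kernel_ud"), level > 0, level < 1)
  d <- ud$density
  cell_area <- ud$cell_size^2
  o <- order(d, decreasing = TRUE)
  cum <- cumsum(d[o]) * cell_area
  ncell <- which(cum >= level)[1]
  if (is.na(ncell)) ncell <- length(o)
  mask <- matrix(FALSE, nrow(d), ncol(d))
  mask[o[seq_len(ncell)]] <- TRUE
  structure(list(mask = mask, area_km2 = ncell * cell_area / 1e6,
                 level = level, xll = ud$xll, yll = ud$yll,
                 cell_size = ud$cell_size),
            class = "isopleth")
}

#' Test whether points fall inside an isopleth region
#'
#' @param iso an `isopleth`.
#' @param pts two-column matrix of points.
#' @return logical vector.
#' @export
isopleth_contains <- function(iso, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  pts <- as.matrix(pts)
  ix <- floor((pts[, 1] - iso$xll) / iso$cell_size) + 1L
  iy <- floor((pts[, 2] - iso$yll) / iso$cell_size) + 1L
  ok <- ix >= 1 & ix <= ncol(iso$mask) & iy >= 1 & iy <= nrow(iso$mask)
  res <- logical(nrow(pts))
  res[ok] <- iso$mask[cbind(iy[ok], ix[ok])]
  res
}

#' Distance from points to an isopleth region
#'
#' Zero for points inside the region, otherwise the distance to the nearest
#' boundary cell centre (resolution-limited to about half a cell).
#'
#' @param iso an `isopleth`.
#' @param pts two-column matrix of points.
#' @return numeric vector of distances in metres.
#' @export
isopleth_distance <- function(iso, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  pts <- as.matrix(pts)
  inside <- isopleth_contains(iso, pts)
  bc <- .mask_boundary_cells(iso$mask)
  if (nrow(bc) == 0) stop("empty isopleth region")
  bx <- iso$xll + (bc[, 2] - 0.5) * iso$cell_size
  by <- iso$yll + (bc[, 1] - 0.5) * iso$cell_size
  d <- vapply(seq_len(nrow(pts)), function(i)
    sqrt(min((bx - pts[i, 1])^2 + (by - pts[i, 2])^2)), numeric(1))
  d[inside] <- 0
  d
}

# row/col indices of masked cells having at least one unmasked 4-neighbour
# (or lying on the grid edge)
.mask_boundary_cells <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  pad <- matrix(FALSE, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- mask
  core <- pad[2:(ny + 1), 2:(nx + 1)]
  nb_all <- pad[1:ny, 2:(nx + 1)] & pad[3:(ny + 2), 2:(nx + 1)] &
            pad[2:(ny + 1), 1:nx] & pad[2:(ny + 1), 3:(nx + 2)]
  which(core & !nb_all, arr.ind = TRUE)
}

#' Per-bird-semester home range
#'
#' Computes the kernel UD of the supplied fixes and its 95% (home range) and
#' 50% (core area) isopleths.
#'
#' @param xy two-column matrix of fix coordinates.
#' @param h kernel standard deviation (metres).
#' @param cell_size grid cell edge (metres).
#' @return An object of class `home_range`: list with `ud`, `k95`, `k50`,
#'   `area_k95_km2`, `area_k50_km2`.
#' @export
home_range <- function(xy, h = 750, cell_size = 100) {
  ud <- kernel_ud(xy, h = h, cell_size = cell_size)
  k95 <- isopleth(ud, 0.95)
  k50 <- isopleth(ud, 0.50)
  structure(list(ud = ud, k95 = k95, k50 = k50,
                 area_k95_km2 = k95$area_km2, area_k50_km2 = k50$area_km2),
            class = "home_range")
}

#' Candidate farms within a home range
#'
#' A farm area is a potential food source for a bird-semester iff its
#' centroid lies inside the bird's 95% isopleth.
#'
#' @param hr a `home_range`.
#' @param fa a `farm_areas` object.
#' @return character vector of candidate `area_id`s.
#' @export
candidate_farms <- function(hr, fa) {
  ctr <- as.matrix(fa$areas[, c("centroid_x", "centroid_y")])
  if (nrow(ctr) == 0) return(character(0))
  fa$areas$area_id[isopleth_contains(hr$k95, ctr)]
}

#' Trace an isopleth cell set into rectilinear boundary rings
#'
#' Used for GeoJSON output: the selected cells are traced into closed
#' rectilinear rings following cell edges (outer rings counter-clockwise).
#'
#' @param iso an `isopleth`.
#' @return list of two-column coordinate matrices (closed rings).
#' @export
isopleth_rings <- function(iso) {
  mask <- iso$mask
  ny <- nrow(mask); nx <- ncol(mask)
  cs <- iso$cell_size
  # directed boundary edges with the region on the left (integer vertex grid)
  from <- NULL; to <- NULL
  cells <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(cells))) {
    iy <- cells[k, 1]; ix <- cells[k, 2]
    v00 <- c(ix - 1L, iy - 1L); v10 <- c(ix, iy - 1L)
    v11 <- c(ix, iy); v01 <- c(ix - 1L, iy)
    if (iy == 1 || !mask[iy - 1, ix]) { from <- rbind(from, v00); to <- rbind(to, v10) }
    if (ix == nx || !mask[iy, ix + 1]) { from <- rbind(from, v10); to <- rbind(to, v11) }
    if (iy == ny || !mask[iy + 1, ix]) { from <- rbind(from, v11); to <- rbind(to, v01) }
    if (ix == 1 || !mask[iy, ix - 1]) { from <- rbind(from, v01); to <- rbind(to, v00) }
  }
  if (is.null(from)) return(list())
  key <- function(v) paste(v[, 1], v[, 2])
  fk <- key(from)
  used <- logical(nrow(from))
  lut <- split(seq_along(fk), fk)
  rings <- list()
  for (s in seq_along(fk)) {
    if (used[s]) next
    ring <- list(from[s, ]); cur <- s; used[s] <- TRUE
    prev_dir <- to[s, ] - from[s, ]
    repeat {
      v <- to[cur, ]
      ring[[length(ring) + 1L]] <- v
      cand <- lut[[paste(v[1], v[2])]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0) break
      if (length(cand) > 1) {
        # at a corner-touch pick the left-most turn to keep rings simple
        turns <- vapply(cand, function(e) {
          d <- to[e, ] - from[e, ]
          atan2(prev_dir[1] * d[2] - prev_dir[2] * d[1],
                prev_dir[1] * d[1] + prev_dir[2] * d[2])
        }, numeric(1))
        cur <- cand[which.max(turns)]
      } else cur <- cand
      used[cur] <- TRUE
      prev_dir <- to[cur, ] - from[cur, ]
    }
    m <- do.call(rbind, ring)
    rings[[length(rings) + 1L]] <-
      cbind(iso$xll + m[, 1] * cs, iso$yll + m[, 2] * cs)
  }
  rings
}
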