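# Merged farm areas: the spatial unit of analysis. Farms whose buffer disks
# overlap (centre distance strictly below twice the buffer radius) are grouped
# into one farm area whose polygon is the union of the member disks.

#' Build merged farm areas from point farms
#'
#' Farms are partitioned into the connected components of the "buffer disks
#' intersect" graph: two disks of radius `radius_m` intersect iff the distance
#' between the farm points is strictly less than `2 * radius_m`. Each
#' component becomes one farm area whose polygon is the union of the member
#' disks; the centroid is the area centroid of that union polygon.
#'
#' @param farms data.frame with at least `farm_id`, `x`, `y` columns
#'   (coordinates in metres); any other columns are carried through.
#' @param radius_m buffer radius in metres (default 180, the lower 95% CI
#'   bound of observed carcass-dumping distances from farm buildings).
#' @param n_seg number of segments used to polygonize a full circle.
#' @return An object of class `farm_areas`: list with `areas` (one row per
#'   area: `area_id`, `centroid_x`, `centroid_y`, `n_members`, `area_m2`),
#'   `farms` (input farms plus `area_id`), `polygons` (named list of boundary
#'   rings per area), and `radius_m`.
#' @export
build_farm_areas <- function(farms, radius_m = 180, n_seg = 64) {
  stopifnot(is.data.frame(farms), radius_m > 0)
  req <- c("farm_id", "x", "y")
  if (!all(req %in% names(farms)))
    stop("farms must have columns farm_id, x, y")
  if (anyDuplicated(farms$farm_id))
    stop("duplicate farm_id in farm registry")
  if (any(!is.finite(farms$x)) || any(!is.finite(farms$y)))
    stop("non-finite farm coordinates")
  n <- nrow(farms)
  if (n == 0) {
    return(structure(list(
      areas = data.frame(area_id = character(), centroid_x = numeric(),
                         centroid_y = numeric(), n_members = integer(),
                         area_m2 = numeric()),
      farms = cbind(farms, area_id = character(0)),
      polygons = list(), radius_m = radius_m), class = "farm_areas"))
  }
  # coincident farms merge trivially; warn because their buffers are identical
  if (n > 1) {
    dd <- as.matrix(stats::dist(farms[, c("x", "y")]))
    if (any(dd[upper.tri(dd)] < 1e-9))
      warning("coincident farm locations; merged into one farm area")
    adj <- dd < 2 * radius_m
  } else adj <- matrix(TRUE, 1, 1)
  comp <- .connected_components(adj)
  # deterministic, input-order-independent labels: sort components by their
  # smallest member farm_id
  key <- vapply(split(as.character(farms$farm_id), comp),
                function(ids) min(ids), character(1))
  ord <- order(key)
  relabel <- integer(length(ord)); relabel[ord] <- seq_along(ord)
  comp <- relabel[comp]
  k <- max(comp)
  area_ids <- sprintf("FA%04d", seq_len(k))
  polys <- vector("list", k); names(polys) <- area_ids
  cx <- cy <- am2 <- numeric(k); nm <- integer(k)
  for (i in seq_len(k)) {
    idx <- which(comp == i)
    u <- .disk_union(as.matrix(farms[idx, c("x", "y")]), radius_m, n_seg)
    polys[[i]] <- u$rings
    cx[i] <- u$centroid[1]; cy[i] <- u$centroid[2]
    am2[i] <- u$area; nm[i] <- length(idx)
  }
  farms$area_id <- area_ids[comp]
  structure(list(
    areas = data.frame(area_id = area_ids, centroid_x = cx, centroid_y = cy,
                       n_members = nm, area_m2 = am2,
                       stringsAsFactors = FALSE),
    farms = farms, polygons = polys, radius_m = radius_m),
    class = "farm_areas")
}

# union-find over an adjacency matrix
.connected_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n)) for (j in which(adj[i, ] & seq_len(n) > i)) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <- ri
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' @export
print.farm_areas <- function(x, ...) {
  cat("farm_areas:", nrow(x$areas), "areas from", nrow(x$farms),
      "farms (buffer radius", x$radius_m, "m)\n")
  invisible(x)
}

#' Locate points inside farm areas
#'
#' A point lies inside a farm area iff it is within the buffer radius of any
#' member farm point (the exact definition of the union-of-disks polygon;
#' boundary points count as inside).
#'
#' @param fa a `farm_areas` object.
#' @param pts two-column matrix of points.
#' @return character vector of `area_id` (NA where outside every area).
#' @export
locate_in_farm_areas <- function(fa, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  pts <- as.matrix(pts)
  n <- nrow(pts)
  best <- rep(Inf, n)
  best_area <- rep(NA_character_, n)
  fx <- fa$farms$x; fy <- fa$farms$y; fid <- fa$farms$area_id
  for (i in seq_along(fx)) {
    d <- sqrt((pts[, 1] - fx[i])^2 + (pts[, 2] - fy[i])^2)
    upd <- d < best
    best[upd] <- d[upd]
    best_area[upd] <- fid[i]
  }
  best_area[best > fa$radius_m] <- NA_character_
  best_area
}

#' Distance from points to the nearest farm point
#'
#' @param fa a `farm_areas` object (or a farms data.frame with x/y).
#' @param pts two-column matrix of points.
#' @return numeric vector of distances in metres.
#' @export
nearest_farm_distance <- function(fa, pts) {
  farms <- if (inherits(fa, "farm_areas")) fa$farms else fa
  nearest_distance(pts, fv_points(farms[, c("x", "y")]))
}

## -- covariates ------------------------------------------------------------

#' Farm-level covariates for one semester
#'
#' Computes, from each farm-area centroid, the distances to the nearest
#' highly predictable feeding place (garbage dump or supplementary feeding
#' station), urban area, road, the dump itself, and the nearest feeding
#' station, plus the semester herd size summed over member farms.
#' Bird-specific covariates (distance to nearest occupied territory excluding
#' the bird's own nest, distance to its core area, distance to its own nest)
#' are added when `bird_context` is supplied.
#'
#' @param fa a `farm_areas` object whose `farms` table has a herd column for
#'   the requested semester (named `herd_<semester>`).
#' @param landscape list with `roads` (`fv_lines`), `urban` (`fv_polygons`),
#'   `dump` (`fv_points`), `feeding_stations` (`fv_points`).
#' @param semester semester label, e.g. `"2014S1"`.
#' @param bird_context optional list with fields `nests` (two-column matrix
#'   of occupied nests), `own_nest` (length-2 vector or NULL), `territorial`
#'   (flag), `k50` (an `isopleth` object or NULL), `area_k95_km2`.
#' @return data.frame with one row per farm area.
#' @export
farm_covariates <- function(fa, landscape, semester, bird_context = NULL) {
  ctr <- as.matrix(fa$areas[, c("centroid_x", "centroid_y")])
  hpfp <- fv_points(rbind(unclass(landscape$dump),
                          unclass(landscape$feeding_stations)))
  out <- data.frame(
    area_id   = fa$areas$area_id,
    dist_hpfp = nearest_distance(ctr, hpfp),
    dist_urb  = nearest_distance(ctr, landscape$urban),
    dist_road = nearest_distance(ctr, landscape$roads),
    dist_dump = nearest_distance(ctr, landscape$dump),
    dist_afs  = nearest_distance(ctr, landscape$feeding_stations),
    stringsAsFactors = FALSE)
  herd_col <- paste0("herd_", semester)
  if (!herd_col %in% names(fa$farms))
    stop("farms table lacks herd column ", herd_col)
  herd <- tapply(fa$farms[[herd_col]], fa$farms$area_id, sum)
  out$goat_sheep <- as.numeric(herd[out$area_id])
  if (!is.null(bird_context)) {
    bc <- bird_context
    nests <- bc$nests
    if (isTRUE(bc$territorial)) {
      if (is.null(bc$own_nest)) stop("territorial bird context without a nest")
      keep <- sqrt((nests[, 1] - bc$own_nest[1])^2 +
                   (nests[, 2] - bc$own_nest[2])^2) > 1e-6
      nests_other <- nests[keep, , drop = FALSE]
      if (nrow(nests_other) == 0) stop("no occupied nest other than the bird's own")
      out$dist_terr <- nearest_distance(ctr, fv_points(nests_other))
      out$dist_nest <- nearest_distance(ctr, fv_points(matrix(bc$own_nest, ncol = 2)))
    } else {
      if (is.null(nests) || nrow(nests) == 0) stop("no occupied nests supplied")
      out$dist_terr <- nearest_distance(ctr, fv_points(nests))
    }
    if (!is.null(bc$k50)) out$dist_k50 <- isopleth_distance(bc$k50, ctr)
    if (!is.null(bc$area_k95_km2)) out$area_k95 <- bc$area_k95_km2
  }
  out
}
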