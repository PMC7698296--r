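# Plain-text interchange: GeoJSON for geometries (with a planar metric CRS
# understood), CSV for tables, ESRI ASCII for the DEM, JSON for ground truth
# and diagnostics.

.geojson_feature <- function(geom_type, coords, props) {
  list(type = "Feature", properties = props,
       geometry = list(type = geom_type, coordinates = coords))
}

.ring_coords <- function(ring) {
  ring <- rbind(ring, ring[1, ])  # close
  lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
}

.line_coords <- function(m)
  lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))

#' Write a landscape to GeoJSON
#'
#' Features carry a `kind` property: road (LineString), urban (Polygon),
#' dump and feeding_station (Point).
#'
#' @param landscape landscape list (`roads`, `urban`, `dump`,
#'   `feeding_stations`).
#' @param path output path.
#' @export
write_landscape_geojson <- function(landscape, path) {
  feats <- list()
  for (m in unclass(landscape$roads))
    feats[[length(feats) + 1L]] <-
      .geojson_feature("LineString", .line_coords(m), list(kind = "road"))
  for (ring in unclass(landscape$urban))
    feats[[length(feats) + 1L]] <-
      .geojson_feature("Polygon", list(.ring_coords(ring)), list(kind = "urban"))
  dmp <- unclass(landscape$dump)
  for (i in seq_len(nrow(dmp)))
    feats[[length(feats) + 1L]] <-
      .geojson_feature("Point", c(dmp[i, 1], dmp[i, 2]), list(kind = "dump"))
  st <- unclass(landscape$feeding_stations)
  for (i in seq_len(nrow(st)))
    feats[[length(feats) + 1L]] <-
      .geojson_feature("Point", c(st[i, 1], st[i, 2]),
                       list(kind = "feeding_station"))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a landscape from GeoJSON
#'
#' @param path GeoJSON path with `kind`-typed features.
#' @return landscape list.
#' @export
read_landscape_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  roads <- list(); urban <- list(); dump <- NULL; stations <- NULL
  tomat <- function(cc) do.call(rbind, lapply(cc, function(p)
    c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
  for (f in gj$features) {
    kind <- f$properties$kind
    g <- f$geometry
    if (kind == "road") roads[[length(roads) + 1L]] <- tomat(g$coordinates)
    else if (kind == "urban") urban[[length(urban) + 1L]] <- tomat(g$coordinates[[1]])
    else if (kind == "dump")
      dump <- rbind(dump, c(as.numeric(g$coordinates[[1]]),
                            as.numeric(g$coordinates[[2]])))
    else if (kind == "feeding_station")
      stations <- rbind(stations, c(as.numeric(g$coordinates[[1]]),
                                    as.numeric(g$coordinates[[2]])))
  }
  list(roads = fv_lines(roads), urban = fv_polygons(urban),
       dump = fv_points(dump), feeding_stations = fv_points(stations))
}

#' Write farm areas to GeoJSON
#'
#' One Polygon feature per farm area (the union-of-disks boundary), with
#' `area_id`, `n_members`, centroid coordinates and optional extra
#' properties (e.g. the imputed carcass value).
#'
#' @param fa a `farm_areas` object.
#' @param path output path.
#' @param extra named list of per-area property vectors (aligned with
#'   `fa$areas` rows), e.g. `list(carcass = ...)`.
#' @export
write_farm_areas_geojson <- function(fa, path, extra = list()) {
  feats <- lapply(seq_len(nrow(fa$areas)), function(i) {
    props <- list(area_id = fa$areas$area_id[i],
                  n_members = fa$areas$n_members[i],
                  centroid_x = fa$areas$centroid_x[i],
                  centroid_y = fa$areas$centroid_y[i])
    for (nm in names(extra)) props[[nm]] <- extra[[nm]][i]
    rings <- fa$polygons[[fa$areas$area_id[i]]]
    .geojson_feature("Polygon", lapply(rings, .ring_coords), props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write per-bird-semester home ranges to GeoJSON
#'
#' @param ranges named list (`bird|semester`) of `home_range` objects.
#' @param path output path.
#' @export
write_home_ranges_geojson <- function(ranges, path) {
  feats <- list()
  for (nm in names(ranges)) {
    parts <- strsplit(nm, "|", fixed = TRUE)[[1]]
    for (lev in c("k95", "k50")) {
      rings <- isopleth_rings(ranges[[nm]][[lev]])
      for (ring in rings)
        feats[[length(feats) + 1L]] <- .geojson_feature(
          "Polygon", list(.ring_coords(ring)),
          list(bird_id = parts[1], semester = parts[2], isopleth = lev))
    }
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a simulated study to a directory
#'
#' Emits `farms.csv`, `fixes.csv`, `birds.csv`, `bird_semesters.csv`,
#' `landscape.geojson`, `dem.asc` and `truth.json`.
#'
#' @param sim a `farm_sim`.
#' @param dir output directory (created if needed).
#' @return character vector of written paths.
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  utils::write.csv(sim$farms, p("farms.csv"), row.names = FALSE)
  utils::write.csv(sim$fixes, p("fixes.csv"), row.names = FALSE)
  utils::write.csv(sim$birds, p("birds.csv"), row.names = FALSE)
  utils::write.csv(sim$bird_semesters, p("bird_semesters.csv"), row.names = FALSE)
  write_landscape_geojson(sim$landscape, p("landscape.geojson"))
  write_dem_asc(sim$dem, p("dem.asc"))
  tv <- sim$truth$visit_days
  jsonlite::write_json(list(
    visit_days = data.frame(bird_id = tv$bird_id, area_id = tv$area_id,
                            date = as.character(tv$date)),
    disposal = sim$truth$disposal,
    visit_coefficients = as.list(sim$truth$visit_coefficients),
    random_effects = sim$truth$random_effects),
    p("truth.json"), auto_unbox = TRUE, digits = NA)
  files <- c("farms.csv", "fixes.csv", "birds.csv", "bird_semesters.csv",
             "landscape.geojson", "dem.asc", "truth.json")
  vapply(files, p, character(1))
}

#' Read a fixes table
#' @param path CSV with bird_id, timestamp, x, y, altitude_m, speed_ms.
#' @return data.frame.
#' @export
read_fixes_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a farm registry table
#' @param path CSV with farm_id, x, y, per-semester herd/active columns and
#'   an optional disposal_answer column.
#' @return data.frame.
#' @export
read_farms_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
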