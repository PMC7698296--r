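# Visit detection: a GPS fix is a visit to a farm area iff it lies inside
# the area polygon, its altitude above ground (GPS altitude minus DEM ground
# elevation) is strictly below 25 m, and its instantaneous speed is strictly
# below 2 m/s. Visits aggregate to bird x farm-area x calendar-day records.

#' Classify GPS fixes against farm areas
#'
#' @param fixes data.frame with `bird_id`, `timestamp` (POSIXct or ISO-8601
#'   character, UTC), `x`, `y` (metres), `altitude_m` (same vertical datum as
#'   the DEM), `speed_ms`.
#' @param fa a `farm_areas` object.
#' @param dem a `dem_grid`.
#' @param altitude_threshold visit ceiling for altitude above ground (m).
#' @param speed_threshold visit ceiling for instantaneous speed (m/s).
#' @return the input data.frame with added columns `area_id` (containing
#'   farm area or NA), `agl` (altitude above ground), `is_visit`. Fixes
#'   outside the DEM extent are excluded; their count is reported via the
#'   `n_outside_dem` attribute and a message.
#' @export
classify_fixes <- function(fixes, fa, dem,
                           altitude_threshold = 25, speed_threshold = 2) {
  stopifnot(is.data.frame(fixes))
  req <- c("bird_id", "timestamp", "x", "y", "altitude_m", "speed_ms")
  if (!all(req %in% names(fixes)))
    stop("fixes must have columns ", paste(req, collapse = ", "))
  ground <- dem_elevation(dem, fixes$x, fixes$y)
  outside <- is.na(ground)
  if (any(outside)) {
    message(sum(outside), " fixes outside the DEM extent excluded")
    fixes <- fixes[!outside, , drop = FALSE]
    ground <- ground[!outside]
  }
  fixes$area_id <- locate_in_farm_areas(fa, cbind(fixes$x, fixes$y))
  fixes$agl <- fixes$altitude_m - ground
  fixes$is_visit <- !is.na(fixes$area_id) &
    fixes$agl < altitude_threshold & fixes$speed_ms < speed_threshold
  attr(fixes, "n_outside_dem") <- sum(outside)
  fixes
}

#' Aggregate qualifying fixes to visit days
#'
#' One record per (bird, farm area, calendar date in UTC) with at least one
#' qualifying fix; multiple qualifying fixes on one day collapse to one.
#'
#' @inheritParams classify_fixes
#' @return data.frame with `bird_id`, `area_id`, `date` (Date), sorted.
#' @export
aggregate_visit_days <- function(fixes, fa, dem,
                                 altitude_threshold = 25, speed_threshold = 2) {
  cl <- classify_fixes(fixes, fa, dem, altitude_threshold, speed_threshold)
  v <- cl[cl$is_visit, c("bird_id", "area_id", "timestamp")]
  if (nrow(v) == 0)
    return(data.frame(bird_id = character(), area_id = character(),
                      date = as.Date(character())))
  v$date <- as.Date(substr(as.character(v$timestamp), 1, 10))
  out <- unique(v[, c("bird_id", "area_id", "date")])
  out <- out[order(out$bird_id, out$area_id, out$date), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tracking coverage and bird-semester eligibility
#'
#' A calendar day counts as a day "with data" for a bird if at least one fix
#' exists that date. A bird-semester is eligible iff every month of the
#' semester has at least `min_days_per_month` days with data; the binomial
#' denominator for that bird-semester is the total number of days with data
#' in the semester.
#'
#' @param fixes data.frame with `bird_id` and `timestamp`.
#' @param semesters character vector of semester labels to evaluate.
#' @param min_days_per_month eligibility threshold (default 15).
#' @return data.frame with `bird_id`, `semester`, `eligible`, `n_days`.
#' @export
coverage_and_eligibility <- function(fixes, semesters, min_days_per_month = 15) {
  birds <- sort(unique(as.character(fixes$bird_id)))
  dates <- unique(data.frame(bird_id = as.character(fixes$bird_id),
                             date = as.Date(substr(as.character(fixes$timestamp), 1, 10))))
  dates$month <- format(dates$date, "%Y-%m")
  dates$semester <- semester_of(dates$date)
  out <- expand.grid(bird_id = birds, semester = semesters,
                     stringsAsFactors = FALSE)
  out$eligible <- FALSE
  out$n_days <- 0L
  for (i in seq_len(nrow(out))) {
    months <- semester_months(out$semester[i])
    dsub <- dates[dates$bird_id == out$bird_id[i] &
                  dates$semester == out$semester[i], , drop = FALSE]
    per_month <- table(factor(dsub$month, levels = months))
    out$eligible[i] <- all(per_month >= min_days_per_month)
    out$n_days[i] <- nrow(dsub)
  }
  out
}

#' Distance summary of qualifying fixes to the nearest farm point
#'
#' Descriptive statistic: mean and SD of the distance from each qualifying
#' (visit) fix to the nearest original farm point.
#'
#' @param fixes data.frame of classified fixes (`classify_fixes` output) or
#'   raw fixes (then `fa`/`dem` must be supplied to classify them first).
#' @param fa a `farm_areas` object.
#' @param dem a `dem_grid` (only needed when `fixes` are unclassified).
#' @return list with `mean_m`, `sd_m`, `n`.
#' @export
visit_distance_summary <- function(fixes, fa, dem = NULL) {
  if (!"is_visit" %in% names(fixes)) {
    if (is.null(dem)) stop("supply a DEM to classify raw fixes")
    fixes <- classify_fixes(fixes, fa, dem)
  }
  v <- fixes[fixes$is_visit, , drop = FALSE]
  if (nrow(v) == 0) stop("no qualifying visit fixes")
  d <- nearest_farm_distance(fa, cbind(v$x, v$y))
  list(mean_m = mean(d), sd_m = if (nrow(v) > 1) stats::sd(d) else 0, n = nrow(v))
}
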