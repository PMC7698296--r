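# Synthetic study generator. Produces landscapes, farm registries, bird
# rosters and GPS trajectories with fully known ground truth (true visit
# days, true disposal answers, true model coefficients and realized random
# effects) so that every downstream stage of the pipeline can be validated
# without any field data.

#' Simulation configuration
#'
#' Defaults encode the study conditions the pipeline targets: ~300 m-scale
#' clustered farms with lognormal herd sizes, a disposal model in which
#' abandonment becomes more likely further from urban areas and from the
#' garbage dump, farm-use coefficients of the magnitudes reported for
#' farm-level analyses, random-intercept SDs of 0.5 / 0.3 / 0.4 (farm /
#' semester / bird) on the logit scale, and a 20-minute GPS duty cycle.
#'
#' @param seed integer RNG seed.
#' @param extent numeric c(xmin, ymin, xmax, ymax) in metres.
#' @param n_farms,n_birds,n_semesters counts.
#' @param first_semester label of the first simulated semester.
#' @param herd_lognormal c(mu, sigma) of log herd size.
#' @param disposal_coefficients named vector: intercept plus any of
#'   dist_dump, dist_afs, dist_road, goat_sheep, dist_urb (applied to
#'   z-scored predictors).
#' @param visit_coefficients named vector: intercept plus farm-use terms
#'   (goat_sheep, carcass, dist_road, dist_hpfp, breeding,
#'   `breeding:dist_hpfp`), applied to z-scored covariates.
#' @param random_effect_sds named c(farm, semester, bird) SDs (logit scale).
#' @param fix_interval_s background sampling interval, 1-1200 s.
#' @param days_per_month tracked days per month per bird (>= 15 keeps every
#'   bird-semester eligible).
#' @param decoy_rates named per-tracked-day rates of fixes over farms that
#'   violate exactly one visit criterion: c(high_altitude, high_speed,
#'   near_miss).
#' @param known_disposal_fraction fraction of farms with an interviewed
#'   (observed) disposal answer.
#' @param prop_territorial fraction of birds holding a territory.
#' @param buffer_radius_m farm-area buffer radius.
#' @param forage_radius_m radius around a bird's activity centre within
#'   which farms can be programmed as visited.
#' @param inactive_fraction fraction of farms inactive in one semester.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       extent = c(0, 0, 40000, 30000),
                       n_farms = 60, n_birds = 10, n_semesters = 4,
                       first_semester = "2014S1",
                       herd_lognormal = c(mu = 4.5, sigma = 0.8),
                       disposal_coefficients = c(intercept = 0.3,
                                                 dist_urb = 0.9,
                                                 dist_dump = 0.8),
                       visit_coefficients = c(intercept = -2.2,
                                              goat_sheep = 0.44,
                                              carcass = 0.56,
                                              dist_road = 0.60,
                                              dist_hpfp = -0.86,
                                              breeding = 0.49,
                                              "breeding:dist_hpfp" = 0.31),
                       random_effect_sds = c(farm = 0.5, semester = 0.3,
                                             bird = 0.4),
                       fix_interval_s = 1200,
                       days_per_month = 16,
                       decoy_rates = c(high_altitude = 0.6, high_speed = 0.6,
                                       near_miss = 0.3),
                       known_disposal_fraction = 0.3,
                       prop_territorial = 0.4,
                       buffer_radius_m = 180,
                       forage_radius_m = 12000,
                       inactive_fraction = 0.05) {
  stopifnot(length(extent) == 4, extent[3] > extent[1], extent[4] > extent[2],
            n_farms >= 0, n_birds >= 0, n_semesters >= 1,
            all(random_effect_sds >= 0),
            fix_interval_s >= 1, fix_interval_s <= 1200,
            known_disposal_fraction >= 0, known_disposal_fraction <= 1)
  if (!"intercept" %in% names(disposal_coefficients) ||
      !"intercept" %in% names(visit_coefficients))
    stop("coefficient vectors need a named intercept")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate the landscape, farm registry and DEM
#'
#' Farms are placed by a clustered point process (Gaussian scatter around
#' uniform cluster centres) with a minimum separation, each with lognormal
#' per-semester herd sizes. The landscape holds roads (polylines), urban
#' polygons, one garbage dump and two supplementary feeding stations (dump
#' and stations jointly form the HPFP set), and a smooth strictly positive
#' DEM covering the extent.
#'
#' @param config a `sim_config`.
#' @return list with `farms` (data.frame), `landscape` (list of geometry
#'   sets), `dem` (a `dem_grid`), `semesters` (labels).
#' @export
simulate_landscape <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ex <- config$extent
  w <- ex[3] - ex[1]; h <- ex[4] - ex[2]
  semesters <- semester_seq(config$first_semester, config$n_semesters)
  min_sep <- 30
  if (config$n_farms > 0 &&
      config$n_farms * (2 * min_sep)^2 > 0.5 * w * h)
    stop("extent too small to place ", config$n_farms,
         " farms without coincident points")
  n <- config$n_farms
  if (n > 0) {
    k <- max(1, min(8, ceiling(n / 10)))
    ccx <- stats::runif(k, ex[1] + 0.15 * w, ex[3] - 0.15 * w)
    ccy <- stats::runif(k, ex[2] + 0.15 * h, ex[4] - 0.15 * h)
    xs <- ys <- numeric(n)
    placed <- 0
    tries <- 0
    while (placed < n) {
      tries <- tries + 1
      if (tries > 200 * n)
        stop("extent too small to place ", n, " farms without coincident points")
      ci <- sample.int(k, 1)
      px <- stats::rnorm(1, ccx[ci], 1500)
      py <- stats::rnorm(1, ccy[ci], 1500)
      if (px < ex[1] || px > ex[3] || py < ex[2] || py > ex[4]) next
      if (placed > 0 &&
          min((xs[seq_len(placed)] - px)^2 + (ys[seq_len(placed)] - py)^2) <
            min_sep^2) next
      placed <- placed + 1
      xs[placed] <- px; ys[placed] <- py
    }
    farms <- data.frame(farm_id = sprintf("F%04d", seq_len(n)),
                        x = xs, y = ys, stringsAsFactors = FALSE)
    for (s in semesters) {
      farms[[paste0("herd_", s)]] <- pmax(1, round(stats::rlnorm(
        n, config$herd_lognormal[["mu"]], config$herd_lognormal[["sigma"]])))
      farms[[paste0("active_", s)]] <- TRUE
    }
    n_inact <- round(config$inactive_fraction * n)
    if (n_inact > 0) {
      off <- sample.int(n, n_inact)
      for (i in off)
        farms[[paste0("active_", sample(semesters, 1))]][i] <- FALSE
    }
  } else {
    farms <- data.frame(farm_id = character(), x = numeric(), y = numeric(),
                        stringsAsFactors = FALSE)
    for (s in semesters) {
      farms[[paste0("herd_", s)]] <- numeric(0)
      farms[[paste0("active_", s)]] <- logical(0)
    }
  }
  # roads: three jittered polylines crossing the extent
  mkroad <- function(y0, slope) {
    xx <- seq(ex[1], ex[3], length.out = 12)
    cbind(xx, pmin(ex[4], pmax(ex[2],
      y0 + slope * (xx - ex[1]) + stats::rnorm(12, 0, h * 0.02))))
  }
  roads <- fv_lines(list(mkroad(ex[2] + 0.3 * h, 0.05),
                         mkroad(ex[2] + 0.7 * h, -0.04),
                         cbind(pmin(ex[3], pmax(ex[1],
                           ex[1] + 0.5 * w + stats::rnorm(12, 0, w * 0.02))),
                           seq(ex[2], ex[4], length.out = 12))))
  rect <- function(cx, cy, rw, rh)
    cbind(c(cx - rw, cx + rw, cx + rw, cx - rw),
          c(cy - rh, cy - rh, cy + rh, cy + rh))
  urban <- fv_polygons(list(
    rect(ex[1] + 0.2 * w, ex[2] + 0.2 * h, 900, 700),
    rect(ex[1] + 0.8 * w, ex[2] + 0.75 * h, 1100, 800)))
  dump <- fv_points(matrix(c(ex[1] + 0.55 * w, ex[2] + 0.5 * h), ncol = 2))
  stations <- fv_points(rbind(c(ex[1] + 0.25 * w, ex[2] + 0.65 * h),
                              c(ex[1] + 0.75 * w, ex[2] + 0.3 * h)))
  # smooth strictly positive DEM with a pad beyond the extent
  cs <- 200
  pad <- 2000
  nx <- ceiling((w + 2 * pad) / cs); ny <- ceiling((h + 2 * pad) / cs)
  gx <- ex[1] - pad + (seq_len(nx) - 0.5) * cs
  gy <- ex[2] - pad + (seq_len(ny) - 0.5) * cs
  z <- outer(gy, gx, function(yy, xx)
    300 + 120 * sin(xx / 4000) * cos(yy / 5000) + 80 * sin((xx + yy) / 9000))
  dem <- dem_grid(z, ex[1] - pad, ex[2] - pad, cs)
  list(farms = farms,
       landscape = list(roads = roads, urban = urban, dump = dump,
                        feeding_stations = stations),
       dem = dem, semesters = semesters)
}

# z-score helper returning the scaled vector (constant columns untouched)
.zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(x - mean(x))
  (x - mean(x)) / s
}

#' Simulate per-farm carcass-disposal answers
#'
#' Each farm's abandonment probability follows a logit-linear model in the
#' z-scored farm predictors (distances to the dump, feeding stations, roads
#' and urban areas, and herd size); a configurable fraction of farms is
#' flagged as "known" (interviewed).
#'
#' @param farms farm registry (from `simulate_landscape`).
#' @param landscape landscape list (same source).
#' @param coefficients named vector with `intercept` plus predictor terms.
#' @param known_fraction fraction of farms with observed answers.
#' @param seed RNG seed.
#' @return data.frame with `farm_id`, predictors, `p_true`, `answer_true`,
#'   `known`, `disposal_answer` (NA where unknown).
#' @export
simulate_disposal <- function(farms, landscape, coefficients,
                              known_fraction = 0.3, seed = 1) {
  if (nrow(farms) == 0)
    return(data.frame(farm_id = character(), p_true = numeric(),
                      answer_true = integer(), known = logical(),
                      disposal_answer = integer()))
  set.seed(seed)
  pts <- as.matrix(farms[, c("x", "y")])
  hpfp <- landscape
  herd_cols <- grep("^herd_", names(farms), value = TRUE)
  pred <- data.frame(
    farm_id = farms$farm_id,
    dist_dump = nearest_distance(pts, landscape$dump),
    dist_afs = nearest_distance(pts, landscape$feeding_stations),
    dist_road = nearest_distance(pts, landscape$roads),
    dist_urb = nearest_distance(pts, landscape$urban),
    goat_sheep = rowMeans(farms[, herd_cols, drop = FALSE]),
    stringsAsFactors = FALSE)
  terms <- setdiff(names(coefficients), "intercept")
  if (!all(terms %in% names(pred)))
    stop("unknown disposal predictor(s): ",
         paste(setdiff(terms, names(pred)), collapse = ", "))
  eta <- rep(coefficients[["intercept"]], nrow(pred))
  for (t in terms) eta <- eta + coefficients[[t]] * .zscore(pred[[t]])
  pred$p_true <- stats::plogis(eta)
  pred$answer_true <- stats::rbinom(nrow(pred), 1, pred$p_true)
  n_known <- round(known_fraction * nrow(pred))
  pred$known <- FALSE
  if (n_known > 0) pred$known[sample.int(nrow(pred), n_known)] <- TRUE
  pred$disposal_answer <- ifelse(pred$known, pred$answer_true, NA_integer_)
  pred
}

#' Simulate binomial visit numerators for a response design
#'
#' Draws `numerator ~ Binomial(denominator, plogis(X beta + u_farm +
#' u_semester [+ u_bird]))` with fresh random intercepts per grouping level.
#' Interaction terms named `"a:b"` use the product of the named columns.
#' Rows with non-positive denominators are rejected (dropped with a
#' message).
#'
#' @param design data.frame with covariate columns, grouping columns
#'   (`farm_id`, `semester`, optionally `bird_id`), and `denominator`.
#' @param coefficients named vector (`intercept` plus design columns /
#'   interactions).
#' @param random_effect_sds named vector with any of `farm`, `semester`,
#'   `bird` (SD 0 or a missing name means no effect for that factor).
#' @param seed RNG seed.
#' @return list with `rows` (design plus `numerator`, `p`),
#'   `random_effects` (named list of per-level values).
#' @export
simulate_visit_counts <- function(design, coefficients, random_effect_sds,
                                  seed = 1) {
  set.seed(seed)
  bad <- design$denominator <= 0
  if (any(bad)) {
    message(sum(bad), " rows with non-positive denominators rejected")
    design <- design[!bad, , drop = FALSE]
  }
  eta <- rep(coefficients[["intercept"]], nrow(design))
  for (t in setdiff(names(coefficients), "intercept")) {
    if (grepl(":", t)) {
      pp <- strsplit(t, ":", fixed = TRUE)[[1]]
      v <- design[[pp[1]]] * design[[pp[2]]]
    } else v <- design[[t]]
    if (is.null(v)) stop("design lacks column for coefficient ", t)
    eta <- eta + coefficients[[t]] * v
  }
  res <- list()
  groups <- c(farm = "farm_id", semester = "semester", bird = "bird_id")
  for (g in names(groups)) {
    col <- groups[[g]]
    sd_g <- if (g %in% names(random_effect_sds)) random_effect_sds[[g]] else 0
    if (!col %in% names(design) || sd_g <= 0) next
    lev <- sort(unique(as.character(design[[col]])))
    u <- stats::rnorm(length(lev), 0, sd_g)
    names(u) <- lev
    res[[g]] <- u
    eta <- eta + u[as.character(design[[col]])]
  }
  design$p <- stats::plogis(eta)
  design$numerator <- stats::rbinom(nrow(design), design$denominator, design$p)
  list(rows = design, random_effects = res)
}

#' Render GPS tracks realizing a set of true visit days
#'
#' For every true visit day at least one fix is placed inside the farm-area
#' polygon with altitude above ground below 25 m and speed below 2 m/s.
#' Decoy fixes over farms violate exactly one criterion each (high pass,
#' fast transit, or a near miss just outside the polygon); background fixes
#' fill each tracked day at the configured interval at cruising altitude and
#' speed, so no non-visit fix over a farm can qualify.
#'
#' @param true_visits data.frame with `bird_id`, `area_id`, `date`.
#' @param tracked_days data.frame with `bird_id`, `date` (all days with
#'   data; a superset of the visit days).
#' @param fa a `farm_areas` object.
#' @param dem a `dem_grid`.
#' @param config a `sim_config` (uses `fix_interval_s`, `decoy_rates`).
#' @param centers optional per-bird activity centres (named list of c(x, y));
#'   defaults to the extent centre.
#' @param seed RNG seed.
#' @return fixes data.frame: `bird_id`, `timestamp` (ISO-8601 UTC), `x`,
#'   `y`, `altitude_m`, `speed_ms`.
#' @export
render_tracks <- function(true_visits, tracked_days, fa, dem, config,
                          centers = NULL, seed = 1) {
  set.seed(seed)
  ex <- config$extent
  if (is.null(centers)) {
    centers <- list()
  }
  member_by_area <- split(seq_len(nrow(fa$farms)), fa$farms$area_id)
  area_ids <- fa$areas$area_id
  ground_at <- function(x, y) {
    g <- dem_elevation(dem, x, y)
    g[is.na(g)] <- 300
    g
  }
  rows <- vector("list", nrow(tracked_days))
  tracked_days$bird_id <- as.character(tracked_days$bird_id)
  key <- paste(true_visits$bird_id, true_visits$date)
  visits_by_day <- split(as.character(true_visits$area_id), key)
  n_bg <- max(2L, ceiling(8 * 3600 / config$fix_interval_s))
  for (i in seq_len(nrow(tracked_days))) {
    b <- tracked_days$bird_id[i]
    d <- tracked_days$date[i]
    ctr <- centers[[b]]
    if (is.null(ctr)) ctr <- c((ex[1] + ex[3]) / 2, (ex[2] + ex[4]) / 2)
    # background: jittered loop around the activity centre, cruising
    ang <- stats::runif(1, 0, 2 * pi) + seq(0, 2 * pi, length.out = n_bg)
    rad <- abs(stats::rnorm(n_bg, 4000, 1500))
    bx <- pmin(ex[3], pmax(ex[1], ctr[1] + rad * cos(ang)))
    by <- pmin(ex[4], pmax(ex[2], ctr[2] + rad * sin(ang)))
    bg <- data.frame(
      x = bx, y = by,
      altitude_m = ground_at(bx, by) + stats::runif(n_bg, 100, 400),
      speed_ms = stats::runif(n_bg, 5, 15))
    pieces <- list(bg)
    # programmed visits: inside the polygon, low and slow
    v_areas <- visits_by_day[[paste(b, d)]]
    for (a in v_areas) {
      mem <- member_by_area[[a]]
      fi <- mem[sample.int(length(mem), 1)]
      r <- stats::runif(2, 0, 0.8 * fa$radius_m)
      th <- stats::runif(2, 0, 2 * pi)
      vx <- fa$farms$x[fi] + r * cos(th)
      vy <- fa$farms$y[fi] + r * sin(th)
      pieces[[length(pieces) + 1L]] <- data.frame(
        x = vx, y = vy,
        altitude_m = ground_at(vx, vy) + stats::runif(2, 2, 15),
        speed_ms = stats::runif(2, 0, 1.5))
    }
    # decoys over farms, each violating exactly one criterion
    dr <- config$decoy_rates
    mkdecoy <- function(kind) {
      a <- area_ids[sample.int(length(area_ids), 1)]
      mem <- member_by_area[[a]]
      fi <- mem[sample.int(length(mem), 1)]
      if (kind == "near_miss") {
        for (try in 1:20) {
          r <- fa$radius_m + stats::runif(1, 5, 60)
          th <- stats::runif(1, 0, 2 * pi)
          px <- fa$farms$x[fi] + r * cos(th)
          py <- fa$farms$y[fi] + r * sin(th)
          if (is.na(locate_in_farm_areas(fa, c(px, py)))) {
            return(data.frame(x = px, y = py,
                              altitude_m = ground_at(px, py) + stats::runif(1, 0, 10),
                              speed_ms = stats::runif(1, 0, 1.5)))
          }
        }
        return(NULL)
      }
      r <- stats::runif(1, 0, 0.8 * fa$radius_m)
      th <- stats::runif(1, 0, 2 * pi)
      px <- fa$farms$x[fi] + r * cos(th)
      py <- fa$farms$y[fi] + r * sin(th)
      if (kind == "high_altitude")
        data.frame(x = px, y = py,
                   altitude_m = ground_at(px, py) + stats::runif(1, 40, 300),
                   speed_ms = stats::runif(1, 0, 1.5))
      else  # high_speed: low pass but too fast to be perched
        data.frame(x = px, y = py,
                   altitude_m = ground_at(px, py) + stats::runif(1, 0, 10),
                   speed_ms = stats::runif(1, 3, 12))
    }
    if (length(area_ids) > 0) {
      for (kind in c("high_altitude", "high_speed", "near_miss")) {
        nk <- stats::rpois(1, dr[[kind]])
        for (j in seq_len(nk)) {
          dk <- mkdecoy(kind)
          if (!is.null(dk)) pieces[[length(pieces) + 1L]] <- dk
        }
      }
    }
    day <- do.call(rbind, pieces)
    nfix <- nrow(day)
    secs <- sort(sample.int(8 * 3600, nfix)) + 8 * 3600
    day$bird_id <- b
    day$timestamp <- format(as.POSIXct(d, tz = "UTC") + secs,
                            "%Y-%m-%dT%H:%M:%SZ")
    rows[[i]] <- day[, c("bird_id", "timestamp", "x", "y",
                         "altitude_m", "speed_ms")]
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$bird_id, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a complete synthetic study
#'
#' Runs the whole generator: landscape + farms + DEM, farm areas, bird
#' roster (sexes, ages, per-semester territorial status with nests,
#' breeding success), disposal answers, programmed visit days drawn from the
#' configured binomial mixed model on real farm covariates, and rendered GPS
#' fixes that realize exactly those visit days.
#'
#' @param config a `sim_config`.
#' @return An object of class `farm_sim`: list with `config`, `farms`,
#'   `landscape`, `dem`, `semesters`, `fa` (farm areas), `birds`,
#'   `bird_semesters`, `tracked_days`, `fixes`, and `truth` (list with
#'   `visit_days`, `disposal`, `visit_coefficients`, `random_effects`,
#'   `visit_rows`).
#' @export
simulate_study <- function(config = sim_config()) {
  land <- simulate_landscape(config)
  set.seed(config$seed + 1L)
  semesters <- land$semesters
  fa <- build_farm_areas(land$farms, config$buffer_radius_m)
  ex <- config$extent
  nb <- config$n_birds
  birds <- data.frame(
    bird_id = sprintf("V%03d", seq_len(nb)),
    sex = rep(c("M", "F"), length.out = nb),
    birth_year = semester_year(semesters[1]) - sample(2:12, nb, TRUE),
    stringsAsFactors = FALSE)
  n_terr <- round(config$prop_territorial * nb)
  territorial <- c(rep(TRUE, n_terr), rep(FALSE, nb - n_terr))
  nest_x <- stats::runif(nb, ex[1] + 2000, ex[3] - 2000)
  nest_y <- stats::runif(nb, ex[2] + 2000, ex[4] - 2000)
  centers <- lapply(seq_len(nb), function(i) c(nest_x[i], nest_y[i]))
  names(centers) <- birds$bird_id
  bs <- expand.grid(bird_id = birds$bird_id, semester = semesters,
                    stringsAsFactors = FALSE)
  bs$territorial <- territorial[match(bs$bird_id, birds$bird_id)]
  bs$nest_x <- ifelse(bs$territorial, nest_x[match(bs$bird_id, birds$bird_id)], NA)
  bs$nest_y <- ifelse(bs$territorial, nest_y[match(bs$bird_id, birds$bird_id)], NA)
  bs$success <- ifelse(bs$territorial, stats::rbinom(nrow(bs), 1, 0.6), NA)
  # tracked days: days_per_month distinct days in every month
  td <- list()
  for (i in seq_len(nrow(bs))) {
    for (m in semester_months(bs$semester[i])) {
      first <- as.Date(paste0(m, "-01"))
      ndays <- as.integer(format(seq(first, by = "month", length.out = 2)[2] - 1, "%d"))
      pick <- sort(sample.int(ndays, min(config$days_per_month, ndays)))
      td[[length(td) + 1L]] <- data.frame(
        bird_id = bs$bird_id[i], date = first + pick - 1L,
        stringsAsFactors = FALSE)
    }
  }
  tracked_days <- do.call(rbind, td)
  n_days_bs <- stats::aggregate(
    list(n_days = tracked_days$date),
    by = list(bird_id = tracked_days$bird_id,
              semester = semester_of(tracked_days$date)),
    FUN = length)
  bs <- merge(bs, n_days_bs, by = c("bird_id", "semester"), all.x = TRUE)
  bs$n_days[is.na(bs$n_days)] <- 0L
  # disposal ground truth
  disposal <- simulate_disposal(land$farms, land$landscape,
                                config$disposal_coefficients,
                                config$known_disposal_fraction,
                                seed = config$seed + 2L)
  land$farms$disposal_answer <- disposal$disposal_answer[
    match(land$farms$farm_id, disposal$farm_id)]
  fa$farms$disposal_answer <- land$farms$disposal_answer[
    match(fa$farms$farm_id, land$farms$farm_id)]
  # design for the programmed visit model: bird x in-range farm x semester
  truth_carc <- tapply(disposal$answer_true[match(fa$farms$farm_id,
                                                  disposal$farm_id)],
                       fa$farms$area_id, max)
  design <- list()
  for (s in semesters) {
    cov <- farm_covariates(fa, land$landscape, s)
    cov$carcass <- as.numeric(truth_carc[cov$area_id])
    for (i in seq_len(nrow(bs))) {
      if (bs$semester[i] != s || bs$n_days[i] == 0) next
      ctr <- centers[[bs$bird_id[i]]]
      d <- sqrt((fa$areas$centroid_x - ctr[1])^2 +
                (fa$areas$centroid_y - ctr[2])^2)
      sel <- which(d <= config$forage_radius_m)
      if (!length(sel)) next
      rows <- cov[sel, , drop = FALSE]
      rows$bird_id <- bs$bird_id[i]
      rows$semester <- s
      rows$breeding <- semester_breeding(s)
      rows$denominator <- bs$n_days[i]
      design[[length(design) + 1L]] <- rows
    }
  }
  truth <- list(visit_days = data.frame(bird_id = character(),
                                        area_id = character(),
                                        date = as.Date(character())),
                disposal = disposal,
                visit_coefficients = config$visit_coefficients,
                random_effects = list(), visit_rows = NULL)
  fixes <- NULL
  if (length(design)) {
    design <- do.call(rbind, design)
    # z-score the continuous covariates entering the generative model
    for (cl in c("goat_sheep", "dist_road", "dist_hpfp", "carcass"))
      design[[cl]] <- .zscore(design[[cl]])
    svc <- simulate_visit_counts(design, config$visit_coefficients,
                                 config$random_effect_sds,
                                 seed = config$seed + 3L)
    truth$random_effects <- svc$random_effects
    truth$visit_rows <- svc$rows
    # materialize numerators as concrete visit dates among the tracked days
    tkey <- split(tracked_days$date,
                  paste(tracked_days$bird_id, semester_of(tracked_days$date)))
    vd <- list()
    rws <- svc$rows
    for (i in seq_len(nrow(rws))) {
      nv <- rws$numerator[i]
      if (nv == 0) next
      days <- tkey[[paste(rws$bird_id[i], rws$semester[i])]]
      pick <- sort(sample(days, nv))
      vd[[length(vd) + 1L]] <- data.frame(
        bird_id = rws$bird_id[i], area_id = rws$area_id[i], date = pick,
        stringsAsFactors = FALSE)
    }
    if (length(vd)) truth$visit_days <- do.call(rbind, vd)
  }
  fixes <- render_tracks(truth$visit_days, tracked_days, fa, land$dem,
                         config, centers, seed = config$seed + 4L)
  structure(list(config = config, farms = land$farms,
                 landscape = land$landscape, dem = land$dem,
                 semesters = semesters, fa = fa, birds = birds,
                 bird_semesters = bs, tracked_days = tracked_days,
                 fixes = fixes, truth = truth),
            class = "farm_sim")
}

#' @export
print.farm_sim <- function(x, ...) {
  cat("synthetic study:", nrow(x$farms), "farms ->", nrow(x$fa$areas),
      "farm areas;", nrow(x$birds), "birds;", length(x$semesters),
      "semesters;", nrow(x$fixes), "fixes;",
      nrow(x$truth$visit_days), "true visit days\n")
  invisible(x)
}
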