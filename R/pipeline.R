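# End-to-end orchestration: simulate (or load) -> farm geometry -> visit
# detection -> home ranges -> carcass model -> modelling tables -> inference
# -> report, behind one validated configuration with reproducible seeds.

#' Pipeline run configuration
#'
#' Every threshold defaults to the analysis constants: 180 m buffer radius,
#' 25 m / 2 m/s visit criteria, kernel smoothing factor 750 m with 100 m
#' cells, 15 tracked days per month for eligibility, averaging thresholds
#' 0.9 / 0.001, and 15 nearest neighbours for Moran's I.
#'
#' @param out_dir directory for artefacts.
#' @param seed integer seed driving the synthetic study and permutations.
#' @param buffer_radius_m farm-area buffer radius (m).
#' @param altitude_threshold,speed_threshold visit criteria (m, m/s).
#' @param kernel_h,kernel_cell kernel SD and grid cell (m).
#' @param min_days_per_month eligibility threshold.
#' @param single_model_weight,weight_floor averaging thresholds.
#' @param k_neighbors Moran's I neighbours.
#' @param sim a `sim_config` for the synthetic study (its seed is replaced
#'   by `seed`).
#' @param farm_terms,vulture_terms candidate pools passed to
#'   [run_analysis()] (NULL = full analysis menus).
#' @return validated list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("farmvisits_run_"),
                       seed = 1,
                       buffer_radius_m = 180,
                       altitude_threshold = 25, speed_threshold = 2,
                       kernel_h = 750, kernel_cell = 100,
                       min_days_per_month = 15,
                       single_model_weight = 0.9, weight_floor = 0.001,
                       k_neighbors = 15,
                       sim = sim_config(),
                       farm_terms = NULL,
                       vulture_terms = c("goat_sheep", "dist_road",
                                         "dist_k50", "area_k95", "breeding")) {
  thresholds <- c(buffer_radius_m, altitude_threshold, speed_threshold,
                  kernel_h, kernel_cell, min_days_per_month,
                  single_model_weight, weight_floor, k_neighbors)
  if (any(!is.finite(thresholds)) || any(thresholds <= 0))
    stop("all thresholds must be positive")
  sim$seed <- as.integer(seed)
  sim$buffer_radius_m <- buffer_radius_m
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 buffer_radius_m = buffer_radius_m,
                 altitude_threshold = altitude_threshold,
                 speed_threshold = speed_threshold,
                 kernel_h = kernel_h, kernel_cell = kernel_cell,
                 min_days_per_month = min_days_per_month,
                 single_model_weight = single_model_weight,
                 weight_floor = weight_floor, k_neighbors = k_neighbors,
                 sim = sim, farm_terms = farm_terms,
                 vulture_terms = vulture_terms),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; a `sim` mapping is
#' forwarded to [sim_config()].
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) {
    if (!is.null(y$sim$extent)) y$sim$extent <- as.numeric(y$sim$extent)
    y$sim <- do.call(sim_config, y$sim)
  }
  do.call(run_config, y)
}

#' Run the full pipeline
#'
#' Simulates a synthetic study (unless `sim_data` supplies one), builds
#' farm areas, detects visits, computes home ranges, fits and applies the
#' carcass model, assembles the FARM and VULTURE tables, runs the three
#' analyses, writes every artefact to `config$out_dir` and returns a
#' manifest with content hashes.
#'
#' @param config a `run_config`.
#' @param sim_data optional pre-built `farm_sim` (overrides simulation).
#' @return list with `manifest` (file, md5), `results` (per-analysis
#'   output), `detection` (precision/recall vs ground truth), `log`.
#' @export
run_pipeline <- function(config = run_config(), sim_data = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    log <<- c(log, msg)
    message(msg)
  }
  sim <- if (is.null(sim_data)) simulate_study(config$sim) else sim_data
  note("simulated study: ", nrow(sim$farms), " farms, ", nrow(sim$fixes),
       " fixes, ", nrow(sim$truth$visit_days), " true visit days")
  paths <- write_study(sim, file.path(config$out_dir, "input"))
  fa <- sim$fa
  note("farm areas: ", nrow(fa$areas), " from ", nrow(sim$farms), " farms")

  # visit detection
  vd <- aggregate_visit_days(sim$fixes, fa, sim$dem,
                             config$altitude_threshold,
                             config$speed_threshold)
  det <- visit_detection_accuracy(vd, sim$truth$visit_days)
  note("visit days detected: ", nrow(vd), " (precision ",
       round(det$precision, 4), ", recall ", round(det$recall, 4), ")")
  utils::write.csv(transform(vd, date = as.character(date)),
                   file.path(config$out_dir, "visit_days.csv"),
                   row.names = FALSE)
  elig <- coverage_and_eligibility(sim$fixes, sim$semesters,
                                   config$min_days_per_month)
  utils::write.csv(elig, file.path(config$out_dir, "coverage.csv"),
                   row.names = FALSE)
  note("eligible bird-semesters: ", sum(elig$eligible), " of ", nrow(elig))

  # home ranges per eligible bird-semester
  ranges <- list()
  areas_csv <- list()
  for (i in which(elig$eligible)) {
    b <- elig$bird_id[i]; s <- elig$semester[i]
    sel <- sim$fixes$bird_id == b &
      semester_of(substr(sim$fixes$timestamp, 1, 10)) == s
    if (!any(sel)) next
    hr <- home_range(cbind(sim$fixes$x[sel], sim$fixes$y[sel]),
                     h = config$kernel_h, cell_size = config$kernel_cell)
    ranges[[paste(b, s, sep = "|")]] <- hr
    areas_csv[[length(areas_csv) + 1L]] <- data.frame(
      bird_id = b, semester = s, area_k95_km2 = hr$area_k95_km2,
      area_k50_km2 = hr$area_k50_km2)
  }
  utils::write.csv(do.call(rbind, areas_csv),
                   file.path(config$out_dir, "homerange_areas.csv"),
                   row.names = FALSE)
  write_home_ranges_geojson(ranges,
                            file.path(config$out_dir, "homeranges.geojson"))
  note("home ranges computed: ", length(ranges))

  # carcass model on farms with observed answers
  disp <- sim$truth$disposal
  known <- disp[disp$known, , drop = FALSE]
  known$answer <- known$answer_true
  note("carcass model fitted on ", nrow(known), " interviewed farms")
  carc_fit <- select_disposal_model(known)
  farms_pred <- disp
  farms_pred$disposal_answer <- ifelse(disp$known, disp$answer_true,
                                       NA_integer_)
  carc_farm <- impute_carcass(farms_pred, carc_fit)
  carcass_area <- tapply(carc_farm[match(fa$farms$farm_id, disp$farm_id)],
                         fa$farms$area_id, max)
  write_farm_areas_geojson(fa, file.path(config$out_dir, "farm_areas.geojson"),
                           extra = list(carcass = as.numeric(
                             carcass_area[fa$areas$area_id])))

  # modelling tables
  farm_rows <- build_farm_table(vd, elig, fa, sim$landscape, sim$semesters,
                                carcass = carcass_area)
  vult <- build_vulture_tables(vd, elig, sim$bird_semesters, sim$birds, fa,
                               sim$landscape, ranges, carcass = carcass_area)
  note("FARM rows: ", nrow(farm_rows),
       "; territorial rows: ",
       if (is.null(vult$territorial)) 0 else nrow(vult$territorial),
       "; non-territorial rows: ",
       if (is.null(vult$non_territorial)) 0 else nrow(vult$non_territorial))

  results <- list()
  runs <- list(FARM = list(rows = farm_rows, terms = config$farm_terms),
               VULT_TERR = list(rows = vult$territorial,
                                terms = config$vulture_terms),
               VULT_NONTERR = list(rows = vult$non_territorial,
                                   terms = config$vulture_terms))
  for (an in names(runs)) {
    rows <- runs[[an]]$rows
    if (is.null(rows) || nrow(rows) < 20 ||
        length(unique(rows$farm_id)) < 3) {
      note(an, " skipped: too few rows")
      next
    }
    res <- run_analysis(an, rows, fa, terms = runs[[an]]$terms,
                        k_neighbors = min(config$k_neighbors,
                                          length(unique(rows$farm_id)) - 2),
                        seed = config$seed,
                        weight_floor = config$weight_floor,
                        single_model_weight = config$single_model_weight)
    results[[an]] <- res
    pre <- file.path(config$out_dir, tolower(an))
    utils::write.csv(res$ranking, paste0(pre, "_ranking.csv"),
                     row.names = FALSE)
    utils::write.csv(res$averaged$table, paste0(pre, "_averaged_model.csv"),
                     row.names = FALSE)
    dg <- res$diagnostics
    jsonlite::write_json(list(
      overdispersion = dg$overdispersion,
      pseudo_r2 = dg$pseudo_r2,
      vif = as.list(dg$vif),
      morans_i = if (!is.null(dg$morans_i))
        dg$morans_i[c("I", "p_value", "expected", "n")] else NULL),
      paste0(pre, "_diagnostics.json"), auto_unbox = TRUE, digits = NA)
    note(an, ": ", nrow(res$ranking), " retained models; top AICc ",
         round(res$ranking$aicc[1], 2))
  }

  desc <- descriptive_comparisons(vd, sim$bird_semesters, sim$birds,
                                  ranges, fa)
  utils::write.csv(desc$comparisons,
                   file.path(config$out_dir, "table3.csv"), row.names = FALSE)

  writeLines(log, file.path(config$out_dir, "run_log.txt"))
  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(config$out_dir, "run_log.txt"))
  manifest <- data.frame(file = sub(paste0("^", config$out_dir, "/?"), "",
                                    files),
                         md5 = as.character(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
                   row.names = FALSE)
  list(manifest = manifest, results = results, detection = det,
       descriptive = desc, log = log, sim = sim,
       farm_rows = farm_rows, vulture_rows = vult)
}

#' Precision and recall of detected visit days against ground truth
#'
#' @param detected data.frame (`bird_id`, `area_id`, `date`).
#' @param truth data.frame of true visit days.
#' @return list with `precision`, `recall`, `n_detected`, `n_true`.
#' @export
visit_detection_accuracy <- function(detected, truth) {
  keyd <- paste(detected$bird_id, detected$area_id, detected$date)
  keyt <- paste(truth$bird_id, truth$area_id, truth$date)
  tp <- length(intersect(keyd, keyt))
  list(precision = if (length(keyd)) tp / length(unique(keyd)) else NA_real_,
       recall = if (length(keyt)) tp / length(unique(keyt)) else NA_real_,
       n_detected = length(unique(keyd)), n_true = length(unique(keyt)))
}
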