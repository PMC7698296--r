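# Assembly of the modelling tables. FARM rows: one per active farm area and
# semester, numerator = number of distinct eligible birds with a visit day
# there, denominator = number of eligible tracked birds that semester.
# VULTURE rows: one per eligible bird-semester and candidate farm (centroid
# inside the bird's 95% isopleth), numerator = visit days on that farm,
# denominator = the bird's tracked days that semester; analysed separately
# for territorial and non-territorial birds.

.area_active <- function(fa, semester) {
  col <- paste0("active_", semester)
  if (!col %in% names(fa$farms))
    return(stats::setNames(rep(TRUE, nrow(fa$areas)), fa$areas$area_id))
  act <- tapply(fa$farms[[col]], fa$farms$area_id, any)
  stats::setNames(as.logical(act[fa$areas$area_id]), fa$areas$area_id)
}

#' Build the FARM modelling table
#'
#' @param visit_days data.frame (`bird_id`, `area_id`, `date`).
#' @param eligibility output of [coverage_and_eligibility()].
#' @param fa a `farm_areas` object.
#' @param landscape landscape list.
#' @param semesters semester labels to include.
#' @param carcass named per-area carcass values (observed 0/1 or imputed
#'   probability), e.g. from [impute_carcass()] aggregated by area.
#' @return data.frame of response rows with raw (unstandardized) covariates.
#' @export
build_farm_table <- function(visit_days, eligibility, fa, landscape,
                             semesters, carcass = NULL) {
  visit_days$semester <- semester_of(visit_days$date)
  out <- list()
  for (s in semesters) {
    elig <- eligibility[eligibility$semester == s & eligibility$eligible, ]
    if (nrow(elig) == 0) {
      message("semester ", s, " skipped: no eligible birds")
      next
    }
    active <- .area_active(fa, s)
    cov <- farm_covariates(fa, landscape, s)
    cov <- cov[active[cov$area_id], , drop = FALSE]
    vd <- visit_days[visit_days$semester == s &
                     visit_days$bird_id %in% elig$bird_id, ]
    nvis <- tapply(vd$bird_id, vd$area_id, function(b) length(unique(b)))
    cov$numerator <- as.integer(ifelse(is.na(nvis[cov$area_id]), 0,
                                       nvis[cov$area_id]))
    cov$denominator <- nrow(elig)
    cov$semester <- s
    cov$breeding <- semester_breeding(s)
    if (!is.null(carcass)) cov$carcass <- as.numeric(carcass[cov$area_id])
    out[[length(out) + 1L]] <- cov
  }
  if (!length(out))
    stop("no semester produced FARM rows")
  res <- do.call(rbind, out)
  res$farm_id <- res$area_id
  res$analysis <- "FARM"
  rownames(res) <- NULL
  res
}

#' Build the VULTURE modelling tables (territorial / non-territorial)
#'
#' @param visit_days data.frame (`bird_id`, `area_id`, `date`).
#' @param eligibility output of [coverage_and_eligibility()].
#' @param bird_semesters data.frame with `bird_id`, `semester`,
#'   `territorial`, `nest_x`/`nest_y` (territorial rows), `success`, plus a
#'   `sex` and `birth_year` join from the roster (columns `sex`,
#'   `birth_year` may sit in `birds` instead).
#' @param birds roster data.frame (`bird_id`, `sex`, `birth_year`).
#' @param fa a `farm_areas` object.
#' @param landscape landscape list.
#' @param home_ranges named list `bird|semester` -> `home_range`.
#' @param carcass named per-area carcass values.
#' @return list with `territorial` and `non_territorial` data.frames; visits
#'   to farms outside the home range are excluded and counted in the
#'   `out_of_range_visits` attribute of each table.
#' @export
build_vulture_tables <- function(visit_days, eligibility, bird_semesters,
                                 birds, fa, landscape, home_ranges,
                                 carcass = NULL) {
  visit_days$semester <- semester_of(visit_days$date)
  bs <- merge(bird_semesters, birds, by = "bird_id")
  terr_rows <- list(); nonterr_rows <- list()
  oor_terr <- 0L; oor_nonterr <- 0L
  for (i in seq_len(nrow(bs))) {
    b <- bs$bird_id[i]; s <- bs$semester[i]
    el <- eligibility[eligibility$bird_id == b & eligibility$semester == s, ]
    if (nrow(el) == 0 || !el$eligible || el$n_days < 1) next
    hr <- home_ranges[[paste(b, s, sep = "|")]]
    if (is.null(hr)) next
    # occupied nests that semester
    occ <- bs[bs$semester == s & bs$territorial %in% TRUE, , drop = FALSE]
    nests <- as.matrix(occ[, c("nest_x", "nest_y")])
    terr <- isTRUE(bs$territorial[i])
    bc <- list(
      territorial = terr,
      own_nest = if (terr) c(bs$nest_x[i], bs$nest_y[i]) else NULL,
      nests = nests, k50 = hr$k50, area_k95_km2 = hr$area_k95_km2)
    active <- .area_active(fa, s)
    cand <- intersect(candidate_farms(hr, fa),
                      names(active)[active])
    if (!length(cand)) next
    cov <- farm_covariates(fa, landscape, s, bird_context = bc)
    cov <- cov[cov$area_id %in% cand, , drop = FALSE]
    vd <- visit_days[visit_days$bird_id == b & visit_days$semester == s, ]
    oor <- sum(!vd$area_id %in% cand)
    nv <- table(vd$area_id[vd$area_id %in% cand])
    cov$numerator <- as.integer(ifelse(is.na(nv[cov$area_id]), 0,
                                       nv[cov$area_id]))
    cov$denominator <- el$n_days
    cov$bird_id <- b
    cov$semester <- s
    cov$breeding <- semester_breeding(s)
    cov$sex <- bs$sex[i]
    cov$age <- semester_year(s) - bs$birth_year[i]
    if (!is.null(carcass)) cov$carcass <- as.numeric(carcass[cov$area_id])
    cov$farm_id <- cov$area_id
    if (terr) {
      cov$success <- bs$success[i]
      cov$analysis <- "VULT_TERR"
      oor_terr <- oor_terr + oor
      terr_rows[[length(terr_rows) + 1L]] <- cov
    } else {
      cov$analysis <- "VULT_NONTERR"
      oor_nonterr <- oor_nonterr + oor
      nonterr_rows[[length(nonterr_rows) + 1L]] <- cov
    }
  }
  bindf <- function(lst, oor) {
    if (!length(lst)) return(NULL)
    d <- do.call(rbind, lst)
    rownames(d) <- NULL
    attr(d, "out_of_range_visits") <- oor
    d
  }
  list(territorial = bindf(terr_rows, oor_terr),
       non_territorial = bindf(nonterr_rows, oor_nonterr))
}

#' Standardize continuous covariates to mean 0, SD 1
#'
#' Factors (sex, breeding, success) are untouched. Zero-SD columns are
#' dropped with a warning. Scaling constants are stored in the `scaling`
#' attribute for back-transformation.
#'
#' @param rows modelling table.
#' @param cols continuous covariate columns to scale (defaults to the
#'   distance / herd / carcass / home-range-size columns present).
#' @return the table with scaled columns and a `scaling` attribute.
#' @export
standardize_rows <- function(rows, cols = NULL) {
  if (is.null(cols))
    cols <- intersect(c("dist_hpfp", "dist_urb", "dist_road", "dist_dump",
                        "dist_afs", "dist_terr", "dist_k50", "dist_nest",
                        "goat_sheep", "carcass", "area_k95", "age"),
                      names(rows))
  sc <- data.frame(column = character(), mean = numeric(), sd = numeric(),
                   stringsAsFactors = FALSE)
  for (cl in cols) {
    m <- mean(rows[[cl]]); s <- stats::sd(rows[[cl]])
    if (!is.finite(s) || s == 0) {
      warning("dropping constant covariate ", cl)
      rows[[cl]] <- NULL
      next
    }
    rows[[cl]] <- (rows[[cl]] - m) / s
    sc <- rbind(sc, data.frame(column = cl, mean = m, sd = s))
  }
  attr(rows, "scaling") <- sc
  rows
}

#' Back-transform standardized columns
#'
#' @param rows output of [standardize_rows()].
#' @return the table on the original covariate scales.
#' @export
unstandardize_rows <- function(rows) {
  sc <- attr(rows, "scaling")
  if (is.null(sc)) stop("rows carry no scaling attribute")
  for (i in seq_len(nrow(sc)))
    rows[[sc$column[i]]] <- rows[[sc$column[i]]] * sc$sd[i] + sc$mean[i]
  attr(rows, "scaling") <- NULL
  rows
}

.analysis_random <- function(analysis) {
  switch(analysis,
         FARM = c("farm_id", "semester"),
         VULT_TERR = ,
         VULT_NONTERR = c("farm_id", "semester", "bird_id"),
         stop("unknown analysis id: ", analysis))
}

.analysis_terms <- function(analysis, rows) {
  menu <- switch(analysis,
    FARM = c("dist_hpfp", "dist_urb", "dist_road", "goat_sheep", "carcass",
             "breeding"),
    VULT_TERR = c("dist_hpfp", "dist_urb", "dist_road", "dist_terr",
                  "dist_k50", "goat_sheep", "carcass", "area_k95",
                  "breeding", "sex", "age", "dist_nest", "success"),
    VULT_NONTERR = c("dist_hpfp", "dist_urb", "dist_road", "dist_terr",
                     "dist_k50", "goat_sheep", "carcass", "area_k95",
                     "breeding", "sex", "age"))
  intersect(menu, names(rows))
}

#' Run one full farm-use analysis
#'
#' Standardizes the continuous covariates, enumerates the candidate models
#' under the Spearman collinearity screen, fits each binomial mixed model,
#' ranks by AICc, discards uninformative-parameter models, averages (or
#' returns the single supported top model), and computes diagnostics: VIF
#' over the continuous covariates, overdispersion ratio and marginal /
#' conditional pseudo-R-squared of the top model, and Moran's I of per-farm
#' mean Pearson residuals over k-nearest-neighbour farm centroids.
#'
#' @param analysis one of `"FARM"`, `"VULT_TERR"`, `"VULT_NONTERR"`.
#' @param rows the matching modelling table (raw covariates).
#' @param fa the `farm_areas` object (for residual coordinates).
#' @param terms candidate fixed-effect pool (defaults to the analysis menu
#'   restricted to available columns).
#' @param interactions list of length-2 term pairs of biological interest;
#'   defaults to breeding x dist_hpfp, age x dist_k50, breeding x dist_terr
#'   where available.
#' @param k_neighbors neighbours for Moran's I (default 15).
#' @param seed seed for the Moran permutation null.
#' @param weight_floor,single_model_weight averaging thresholds.
#' @return list with `ranking`, `averaged`, `diagnostics`, `top_fit`,
#'   `scaling`, `n_rows`.
#' @export
run_analysis <- function(analysis, rows, fa, terms = NULL,
                         interactions = NULL, k_neighbors = 15, seed = 1,
                         weight_floor = 0.001, single_model_weight = 0.9) {
  if (is.null(rows) || nrow(rows) == 0) stop("empty modelling table")
  if (is.character(rows$sex))
    rows$sex <- as.integer(rows$sex == "M")  # reference level: female
  rows <- standardize_rows(rows)
  if (is.null(terms)) terms <- .analysis_terms(analysis, rows)
  if (is.null(interactions)) {
    cand <- list(c("breeding", "dist_hpfp"), c("age", "dist_k50"),
                 c("breeding", "dist_terr"))
    interactions <- Filter(function(p) all(p %in% terms), cand)
  }
  random <- .analysis_random(analysis)
  specs <- enumerate_candidates(terms, rows, interactions, random)
  fits <- vector("list", length(specs))
  for (i in seq_along(specs))
    fits[[i]] <- fit_binomial_glmm(rows, specs[[i]], keep_model = TRUE)
  conv <- Filter(function(f) f$converged, fits)
  if (!length(conv)) stop("no candidate model converged")
  retained <- prune_uninformative(conv)
  averaged <- model_average(retained, weight_floor, single_model_weight)
  top <- retained[[1]]
  cont <- intersect(terms, attr(rows, "scaling")$column)
  diag_vif <- if (length(cont) >= 2) vif(rows[, cont, drop = FALSE]) else NULL
  pr <- stats::residuals(top$model, type = "pearson")
  res_by_farm <- tapply(pr, rows$farm_id, mean)
  ctr <- fa$areas[match(names(res_by_farm), fa$areas$area_id),
                  c("centroid_x", "centroid_y")]
  mi <- if (length(res_by_farm) > k_neighbors + 1 &&
            stats::sd(res_by_farm) > 0)
    morans_i(as.numeric(res_by_farm), as.matrix(ctr),
             k_neighbors = k_neighbors, seed = seed)
  else NULL
  list(ranking = ranking_table(retained),
       averaged = averaged,
       diagnostics = list(
         vif = diag_vif,
         overdispersion = overdispersion_ratio(top),
         pseudo_r2 = pseudo_r2(top),
         morans_i = mi),
       top_fit = top,
       scaling = attr(rows, "scaling"),
       n_rows = nrow(rows))
}

#' Bird-semester summary and descriptive comparisons
#'
#' Per bird-semester: number of farms inside the home range, number of
#' distinct farms visited, and home-range size. Comparisons: Mann-Whitney
#' sex differences per territorial status and season (farms in home range
#' and farms visited), season differences per status and sex (farms
#' visited), and the Spearman correlation between farms visited and
#' home-range size for non-territorial bird-semesters.
#'
#' @param visit_days data.frame (`bird_id`, `area_id`, `date`).
#' @param bird_semesters data.frame with `bird_id`, `semester`,
#'   `territorial`.
#' @param birds roster (`bird_id`, `sex`).
#' @param home_ranges named list `bird|semester` -> `home_range`.
#' @param fa a `farm_areas` object.
#' @return list with `summary` (per bird-semester) and `comparisons`
#'   (data.frame of W statistics and p-values; empty groups are reported as
#'   NA).
#' @export
descriptive_comparisons <- function(visit_days, bird_semesters, birds,
                                    home_ranges, fa) {
  visit_days$semester <- semester_of(visit_days$date)
  bs <- merge(bird_semesters, birds[, c("bird_id", "sex")], by = "bird_id")
  bs$breeding <- semester_breeding(bs$semester)
  bs$n_farms_hr <- NA_real_; bs$n_farms_visited <- NA_real_
  bs$area_k95 <- NA_real_
  for (i in seq_len(nrow(bs))) {
    hr <- home_ranges[[paste(bs$bird_id[i], bs$semester[i], sep = "|")]]
    if (is.null(hr)) next
    bs$n_farms_hr[i] <- length(candidate_farms(hr, fa))
    bs$area_k95[i] <- hr$area_k95_km2
    vd <- visit_days[visit_days$bird_id == bs$bird_id[i] &
                     visit_days$semester == bs$semester[i], ]
    bs$n_farms_visited[i] <- length(unique(vd$area_id))
  }
  bs <- bs[!is.na(bs$n_farms_hr), , drop = FALSE]
  comps <- list()
  addcomp <- function(label, a, b) {
    if (length(a) >= 2 && length(b) >= 2) {
      mw <- mann_whitney_u(a, b)
      comps[[length(comps) + 1L]] <<- data.frame(
        comparison = label, W = mw$W, p = mw$p_value,
        n1 = length(a), n2 = length(b), stringsAsFactors = FALSE)
    } else {
      comps[[length(comps) + 1L]] <<- data.frame(
        comparison = label, W = NA_real_, p = NA_real_,
        n1 = length(a), n2 = length(b), stringsAsFactors = FALSE)
    }
  }
  for (terr in c(TRUE, FALSE)) for (br in c(1, 0)) {
    g <- bs[bs$territorial == terr & bs$breeding == br, ]
    lab <- paste0(ifelse(terr, "terr", "nonterr"), "_",
                  ifelse(br == 1, "breeding", "nonbreeding"))
    addcomp(paste0("sex_hr_", lab),
            g$n_farms_hr[g$sex == "M"], g$n_farms_hr[g$sex == "F"])
    addcomp(paste0("sex_visited_", lab),
            g$n_farms_visited[g$sex == "M"], g$n_farms_visited[g$sex == "F"])
  }
  for (terr in c(TRUE, FALSE)) for (sx in c("M", "F")) {
    g <- bs[bs$territorial == terr & bs$sex == sx, ]
    addcomp(paste0("season_visited_", ifelse(terr, "terr", "nonterr"), "_", sx),
            g$n_farms_visited[g$breeding == 1],
            g$n_farms_visited[g$breeding == 0])
  }
  nt <- bs[!bs$territorial, ]
  rho <- if (nrow(nt) >= 3 && stats::sd(nt$n_farms_visited) > 0 &&
             stats::sd(nt$area_k95) > 0)
    spearman_rho(nt$n_farms_visited, nt$area_k95) else NA_real_
  list(summary = bs,
       comparisons = do.call(rbind, comps),
       spearman_visited_vs_k95 = rho)
}
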