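# Parameter-recovery experiment: simulate farm-use response tables from
# known coefficients and random-effect SDs, run the full enumerate - fit -
# prune - average procedure, and score sign agreement and coverage of the
# true values. This is the package's own calibration check that the
# multimodel machinery recovers effects of the magnitudes seen in farm-use
# analyses.

#' One simulated farm-use modelling table
#'
#' Standard-normal continuous covariates, a balanced 0/1 season factor, and
#' crossed farm / semester grouping; numerators drawn from the configured
#' binomial mixed model.
#'
#' @param n_rows number of rows.
#' @param denominator binomial denominator per row.
#' @param coefficients named true coefficients (`intercept` plus covariate
#'   terms; interactions as `"a:b"`).
#' @param random_effect_sds named c(farm, semester) (optionally bird) SDs.
#' @param n_farms,n_semesters grouping sizes.
#' @param seed RNG seed.
#' @return list with `rows` and `random_effects` (see
#'   [simulate_visit_counts()]).
#' @export
simulate_response_table <- function(n_rows = 2000, denominator = 50,
                                    coefficients, random_effect_sds,
                                    n_farms = 100, n_semesters = 8,
                                    seed = 1) {
  set.seed(seed)
  terms <- setdiff(names(coefficients), "intercept")
  mains <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  design <- data.frame(
    farm_id = sample(sprintf("f%03d", seq_len(n_farms)), n_rows, TRUE),
    semester = sample(semester_seq("2013S1", n_semesters), n_rows, TRUE),
    stringsAsFactors = FALSE)
  for (v in mains) {
    design[[v]] <- if (v == "breeding") semester_breeding(design$semester)
                   else stats::rnorm(n_rows)
  }
  design$denominator <- denominator
  simulate_visit_counts(design, coefficients, random_effect_sds,
                        seed = seed + 1L)
}

#' Coefficient-recovery experiment for the multimodel procedure
#'
#' For each replicate, simulates a farm-use table from the true
#' coefficients, enumerates all admissible candidate models over the main
#' effects (plus the listed interactions), fits each binomial GLMM, prunes
#' uninformative parameters, model-averages, and compares the averaged
#' estimates with the truth.
#'
#' @param coefficients named true coefficients; defaults to farm-analysis
#'   magnitudes (herd size 0.44, carcass-free pool: road 0.60, HPFP -0.86,
#'   breeding 0.49, breeding x HPFP 0.31).
#' @param random_effect_sds named SDs (default farm 0.5, semester 0.3).
#' @param n_rows,denominator simulated table size (defaults 2000 / 50).
#' @param n_reps number of replicates (default 50).
#' @param seed base seed; replicate r uses `seed + r`.
#' @return list with `estimates` (replicate x term), `se`, `truth`,
#'   `sign_rate` and `within3se_rate` per term (terms with |beta| >= 0.3
#'   flagged in `strong_terms`).
#' @export
coefficient_recovery <- function(coefficients = c(intercept = -2.2,
                                                  goat_sheep = 0.44,
                                                  dist_road = 0.60,
                                                  dist_hpfp = -0.86,
                                                  breeding = 0.49,
                                                  "breeding:dist_hpfp" = 0.31),
                                 random_effect_sds = c(farm = 0.5,
                                                       semester = 0.3),
                                 n_rows = 2000, denominator = 50,
                                 n_reps = 50, seed = 100) {
  terms <- setdiff(names(coefficients), "intercept")
  ints <- lapply(terms[grepl(":", terms)],
                 function(t) strsplit(t, ":", fixed = TRUE)[[1]])
  mains <- setdiff(terms, terms[grepl(":", terms)])
  est <- se <- matrix(NA_real_, n_reps, length(terms),
                      dimnames = list(NULL, terms))
  for (r in seq_len(n_reps)) {
    tab <- simulate_response_table(n_rows, denominator, coefficients,
                                   random_effect_sds, seed = seed + r)
    rows <- tab$rows
    specs <- enumerate_candidates(mains, rows, ints,
                                  random = c("farm_id", "semester"))
    fits <- lapply(specs, function(s)
      fit_binomial_glmm(rows, s, keep_model = FALSE))
    fits <- Filter(function(f) f$converged, fits)
    avg <- model_average(prune_uninformative(fits))
    tabm <- avg$table
    for (t in terms) {
      nm <- if (grepl(":", t)) {
        pp <- strsplit(t, ":", fixed = TRUE)[[1]]
        cand <- c(t, paste(rev(pp), collapse = ":"))
        intersect(cand, tabm$term)[1]
      } else t
      i <- match(nm, tabm$term)
      if (!is.na(i)) { est[r, t] <- tabm$estimate[i]; se[r, t] <- tabm$se[i] }
    }
  }
  truth <- coefficients[terms]
  filled <- ifelse(is.na(est), 0, est)
  sign_rate <- colMeans(sign(filled) == matrix(sign(truth), n_reps,
                                               length(terms), byrow = TRUE))
  cover <- abs(est - matrix(truth, n_reps, length(terms), byrow = TRUE)) <=
    3 * se
  within3 <- colMeans(cover, na.rm = TRUE)
  list(estimates = est, se = se, truth = truth,
       sign_rate = sign_rate, within3se_rate = within3,
       strong_terms = names(truth)[abs(truth) >= 0.3])
}
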