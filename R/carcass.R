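# Carcass-abandonment submodel: a binomial GLM fitted on interviewed farms
# predicts the probability that a farmer abandons carcasses; farms without
# an interview receive the predicted probability, interviewed farms keep
# their observed 0/1 answer.

.disposal_predictors <- c("dist_dump", "dist_afs", "dist_road",
                          "goat_sheep", "dist_urb")

#' Fit one candidate carcass-abandonment GLM
#'
#' Logistic regression of the 0/1 abandonment answer on a subset of the five
#' farm predictors (distance to the garbage dump, distance to the nearest
#' artificial feeding station, distance to the nearest road, herd size, and
#' distance to the nearest urban area). Reports AICc (with `n` = number of
#' fitted farms) and the adjusted explained deviance
#' `1 - ((n - 1) / (n - k)) * (dev_res / dev_null)` (the explained-deviance
#' analogue of adjusted R-squared).
#'
#' @param records data.frame with `answer` (0/1) plus predictor columns.
#' @param term_set character vector of predictor names (may be empty for the
#'   intercept-only model).
#' @return An object of class `fv_fit` with an extra
#'   `adjusted_explained_deviance` field and a `separation` flag.
#' @export
fit_disposal_glm <- function(records, term_set = .disposal_predictors) {
  if (!all(term_set %in% names(records)))
    stop("missing predictor column(s): ",
         paste(setdiff(term_set, names(records)), collapse = ", "))
  if (any(is.na(records$answer))) stop("fitting records must have observed answers")
  rhs <- if (length(term_set)) paste(term_set, collapse = " + ") else "1"
  form <- stats::as.formula(paste("answer ~", rhs))
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, data = records, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  k <- length(beta)
  n <- nrow(records)
  ll <- as.numeric(stats::logLik(fit))
  d2 <- 1 - fit$deviance / fit$null.deviance
  adj_d2 <- 1 - ((n - 1) / (n - k)) * (1 - d2)
  structure(list(spec = model_spec(term_set), coefficients = beta,
                 se = sqrt(diag(stats::vcov(fit))), varcomp = numeric(0),
                 log_likelihood = ll, k = k, n = n, aicc = aicc(ll, k, n),
                 converged = fit$converged && !separation,
                 singular = FALSE, separation = separation,
                 adjusted_explained_deviance = adj_d2, model = fit),
            class = "fv_fit")
}

#' Select the carcass-abandonment model by AICc
#'
#' Fits all subsets of the five predictors (minus pairs whose |Spearman
#' correlation| exceeds 0.5, which never co-occur), drops separation-flagged
#' fits, ranks the rest by AICc, discards models with uninformative
#' parameters (nested model within 2 AICc of a simpler retained one), and
#' returns the top model.
#'
#' @param records data.frame with `answer` and the five predictor columns.
#' @param predictors candidate predictor names.
#' @param rho_max collinearity threshold (default 0.5).
#' @return the selected `fv_fit`, with the full pruned ranking in the
#'   `ranking` attribute.
#' @export
select_disposal_model <- function(records, predictors = .disposal_predictors,
                                  rho_max = 0.5) {
  specs <- enumerate_candidates(predictors, records, random = character(0),
                                rho_max = rho_max)
  fits <- lapply(specs, function(s) fit_disposal_glm(records, s$fixed))
  fits <- Filter(function(f) f$converged, fits)
  if (length(fits) < 1) stop("no admissible candidate model converged")
  retained <- prune_uninformative(fits)
  top <- retained[[1]]
  attr(top, "ranking") <- ranking_table(retained)
  top
}

#' Impute the carcass covariate for all farms
#'
#' Interviewed farms keep their observed 0/1 answer; farms with an unknown
#' answer receive the predicted abandonment probability from the selected
#' model. Values therefore mix hard 0/1 with probabilities in (0, 1),
#' exactly as used downstream.
#'
#' @param farms data.frame with `disposal_answer` (0/1/NA) and the predictor
#'   columns required by `selected_fit`.
#' @param selected_fit an `fv_fit` from `select_disposal_model` (or
#'   `fit_disposal_glm`).
#' @return numeric vector of carcass values aligned with `farms` rows.
#' @export
impute_carcass <- function(farms, selected_fit) {
  need <- selected_fit$spec$fixed
  if (!all(need %in% names(farms)))
    stop("farms lack predictor column(s): ",
         paste(setdiff(need, names(farms)), collapse = ", "))
  unknown <- is.na(farms$disposal_answer)
  if (any(unknown) && anyNA(farms[unknown, need, drop = FALSE]))
    stop("missing predictor values for farms needing imputation")
  out <- as.numeric(farms$disposal_answer)
  if (any(unknown))
    out[unknown] <- stats::predict(selected_fit$model,
                                   newdata = farms[unknown, , drop = FALSE],
                                   type = "response")
  out
}

#' Tabulate farmer interview answers on carcass disposal
#'
#' @param records data.frame with a `category` column over the fixed
#'   vocabulary: abandon, dump, feeding_station, collection_service, buried,
#'   mortuary, never.
#' @return list with `counts` (per category), `n` (respondents),
#'   `abandoners`, `non_abandoners`.
#' @export
tabulate_disposal <- function(records) {
  vocab <- c("abandon", "dump", "feeding_station", "collection_service",
             "buried", "mortuary", "never")
  cats <- as.character(records$category)
  bad <- setdiff(unique(cats), vocab)
  if (length(bad)) stop("unknown disposal category: ", paste(bad, collapse = ", "))
  counts <- table(factor(cats, levels = vocab))
  list(counts = counts, n = length(cats),
       abandoners = unname(counts["abandon"]),
       non_abandoners = length(cats) - unname(counts["abandon"]))
}

#' Read the packaged (or any) disposal interview table
#'
#' @param path CSV with columns `farm_id`, `category`; defaults to the
#'   interview breakdown shipped with the package.
#' @return data.frame.
#' @export
read_disposal_interviews <- function(path = system.file(
    "extdata", "disposal_interviews.csv", package = "farmvisits")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
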