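# Binomial GLMMs with crossed random intercepts, fitted by Laplace-
# approximated maximum likelihood through lme4, plus the AICc-based
# multimodel machinery: candidate enumeration under a Spearman collinearity
# screen, Akaike weights, uninformative-parameter pruning, and full model
# averaging with relative importance and 85% confidence intervals.

#' Model specification
#'
#' @param fixed character vector of fixed-effect terms (column names in the
#'   modelling table; interactions as `"a:b"`). May be empty (intercept-only).
#' @param random character vector of grouping columns for random intercepts
#'   (e.g. `c("farm_id", "semester")`).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(fixed = character(0), random = character(0)) {
  ints <- fixed[grepl(":", fixed)]
  for (it in ints) {
    mains <- strsplit(it, ":", fixed = TRUE)[[1]]
    if (!all(mains %in% fixed))
      stop("interaction ", it, " without both main effects")
  }
  if (length(ints) > 1) stop("at most one two-way interaction per model")
  structure(list(fixed = fixed, random = random), class = "model_spec")
}

.spec_formula <- function(spec) {
  rhs <- if (length(spec$fixed)) paste(spec$fixed, collapse = " + ") else "1"
  re <- if (length(spec$random))
    paste(sprintf("(1 | %s)", spec$random), collapse = " + ") else ""
  txt <- paste("cbind(numerator, denominator - numerator) ~", rhs,
               if (nzchar(re)) paste("+", re) else "")
  stats::as.formula(txt)
}

#' Fit a binomial GLMM (or GLM) for one candidate specification
#'
#' Response rows carry `numerator` and `denominator` columns; the model is a
#' logit-link binomial with the given fixed effects and one random intercept
#' per grouping factor, estimated by Laplace-approximated ML (`lme4::glmer`
#' with derivative checking disabled as the documented optimizer
#' configuration). With no random terms an ordinary logistic GLM is fitted.
#'
#' The AICc parameter count `k` is the number of fixed coefficients plus the
#' number of random-intercept variance components; `n` is the number of rows.
#'
#' @param rows modelling data.frame with `numerator`, `denominator`, the
#'   covariate columns, and the grouping columns.
#' @param spec a `model_spec`.
#' @param keep_model keep the fitted lme4/glm object (needed for residual
#'   diagnostics)?
#' @return An object of class `fv_fit`: list with `spec`, `coefficients`,
#'   `se`, `varcomp` (random-intercept SDs), `log_likelihood`, `k`, `n`,
#'   `aicc`, `converged`, `singular`, and optionally `model`.
#' @export
fit_binomial_glmm <- function(rows, spec, keep_model = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  if (any(rows$denominator < 1)) stop("all rows need denominator >= 1")
  if (any(rows$numerator < 0 | rows$numerator > rows$denominator))
    stop("numerators must lie in [0, denominator]")
  for (g in spec$random) {
    rows[[g]] <- factor(rows[[g]])
    if (nlevels(rows[[g]]) < 2)
      stop("random factor ", g, " needs >= 2 levels")
  }
  form <- .spec_formula(spec)
  converged <- TRUE
  if (length(spec$random)) {
    fit <- withCallingHandlers(
      lme4::glmer(form, data = rows, family = stats::binomial(),
                  control = lme4::glmerControl(calc.derivs = FALSE)),
      warning = function(w) {
        if (grepl("converge", conditionMessage(w), ignore.case = TRUE))
          converged <<- FALSE
        invokeRestart("muffleWarning")
      })
    beta <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    vc <- lme4::VarCorr(fit)
    varcomp <- vapply(vc, function(v) attr(v, "stddev"), numeric(1))
    names(varcomp) <- names(vc)
    singular <- any(varcomp < 1e-6)
    ll <- as.numeric(stats::logLik(fit))
  } else {
    fit <- stats::glm(form, data = rows, family = stats::binomial())
    converged <- fit$converged
    beta <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    varcomp <- numeric(0)
    singular <- FALSE
    ll <- as.numeric(stats::logLik(fit))
  }
  k <- length(beta) + length(varcomp)
  n <- nrow(rows)
  structure(list(spec = spec, coefficients = beta, se = se,
                 varcomp = varcomp, log_likelihood = ll, k = k, n = n,
                 aicc = aicc(ll, k, n), converged = converged,
                 singular = singular,
                 model = if (keep_model) fit else NULL),
            class = "fv_fit")
}

#' @export
print.fv_fit <- function(x, ...) {
  cat("binomial", if (length(x$spec$random)) "GLMM" else "GLM", "fit:",
      deparse(.spec_formula(x$spec)), "\n")
  cat("  logLik", format(x$log_likelihood), " k", x$k, " AICc",
      format(x$aicc), if (!x$converged) " [non-convergence]" else "", "\n")
  invisible(x)
}

#' AICc: Akaike information criterion for small samples
#'
#' `-2 * logLik + 2k + 2k(k + 1)/(n - k - 1)`.
#'
#' @param log_likelihood maximized log-likelihood.
#' @param k number of estimated parameters (fixed coefficients plus variance
#'   components).
#' @param n sample size (number of modelling rows).
#' @return AICc value.
#' @export
aicc <- function(log_likelihood, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  -2 * log_likelihood + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from AICc values
#'
#' @param aicc_values numeric vector (non-finite entries receive weight 0).
#' @return weights summing to 1 over the finite entries.
#' @export
akaike_weights <- function(aicc_values) {
  w <- rep(0, length(aicc_values))
  ok <- is.finite(aicc_values)
  if (!any(ok)) stop("no finite AICc values")
  d <- aicc_values[ok] - min(aicc_values[ok])
  ew <- exp(-d / 2)
  w[ok] <- ew / sum(ew)
  w
}

#' Enumerate candidate model specifications
#'
#' All subsets of the term pool (including the intercept-only model), except
#' that two terms whose |Spearman correlation| exceeds `rho_max` in `data`
#' never co-occur; additionally, for every admissible subset containing both
#' main effects of a listed interaction, the subset plus that interaction is
#' added (one interaction per model). Deterministic order: by number of
#' terms, then lexicographically.
#'
#' @param terms character vector of candidate main-effect columns.
#' @param data modelling data.frame (used for the collinearity screen).
#' @param interactions list of length-2 character vectors of interest.
#' @param random grouping columns attached to every spec.
#' @param rho_max collinearity threshold on |Spearman rho| (default 0.5).
#' @return list of `model_spec` objects.
#' @export
enumerate_candidates <- function(terms, data, interactions = list(),
                                 random = character(0), rho_max = 0.5) {
  if (length(terms) == 0) stop("empty term pool")
  p <- length(terms)
  banned <- matrix(FALSE, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i < j) {
      xi <- as.numeric(data[[terms[i]]]); xj <- as.numeric(data[[terms[j]]])
      # a constant column carries no collinearity information
      rho <- if (stats::sd(xi) == 0 || stats::sd(xj) == 0) 0
             else spearman_rho(xi, xj)
      banned[i, j] <- banned[j, i] <- abs(rho) > rho_max
    }
  }
  specs <- list()
  for (mask in 0:(2^p - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    if (length(idx) >= 2 && any(banned[idx, idx])) next
    sel <- terms[idx]
    specs[[length(specs) + 1L]] <- model_spec(sel, random)
    for (pair in interactions) {
      if (all(pair %in% sel))
        specs[[length(specs) + 1L]] <-
          model_spec(c(sel, paste(pair, collapse = ":")), random)
    }
  }
  keys <- vapply(specs, function(s) paste(sort(s$fixed), collapse = "+"),
                 character(1))
  specs <- specs[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  nk <- vapply(specs, function(s) length(s$fixed), integer(1))
  specs[order(nk, keys)]
}

#' Discard models with uninformative parameters
#'
#' Walking the candidates in AICc order, a model is discarded when some
#' retained model with strictly lower AICc is nested within it (its fixed
#' terms are a strict subset) and the AICc difference is at most
#' `delta_max`: the extra terms did not explain enough deviance to buy a net
#' AICc reduction.
#'
#' @param fits list of `fv_fit` objects.
#' @param delta_max nesting AICc margin (default 2).
#' @return the retained sublist, sorted by AICc.
#' @export
prune_uninformative <- function(fits, delta_max = 2) {
  fits <- fits[order(vapply(fits, function(f) f$aicc, numeric(1)))]
  retained <- list()
  for (f in fits) {
    uninformative <- FALSE
    for (r in retained) {
      if (r$aicc < f$aicc &&
          f$aicc - r$aicc <= delta_max &&
          length(r$spec$fixed) < length(f$spec$fixed) &&
          all(r$spec$fixed %in% f$spec$fixed)) {
        uninformative <- TRUE
        break
      }
    }
    if (!uninformative) retained[[length(retained) + 1L]] <- f
  }
  retained
}

#' Full model averaging with relative importance and 85% CIs
#'
#' If the best retained model holds at least `single_model_weight` of the
#' Akaike weight it is returned alone. Otherwise every retained model with
#' weight above `weight_floor` enters a full (zero-substitution) average:
#' each coefficient is weight-averaged with 0 substituted where the term is
#' absent, the unconditional SE combines within-model variance and
#' between-model spread, relative importance (RI) is the summed weight of
#' models containing the term, and 85% confidence limits are
#' `estimate +/- z_0.925 * SE`.
#'
#' @param fits list of `fv_fit` objects (typically `prune_uninformative`
#'   output); non-converged fits are dropped from the ranking.
#' @param weight_floor minimum Akaike weight for inclusion (default 0.001).
#' @param single_model_weight weight above which the top model is returned
#'   unaveraged (default 0.9).
#' @param conditional average only over models containing each term
#'   (conditional averaging) instead of substituting zeros.
#' @return An object of class `averaged_model`: list with `table` (term,
#'   estimate, se, lo85, hi85, ri), `single` (logical), `weights`, `fits`.
#' @export
model_average <- function(fits, weight_floor = 0.001,
                          single_model_weight = 0.9, conditional = FALSE) {
  fits <- Filter(function(f) f$converged, fits)
  if (length(fits) == 0) stop("no converged candidate models")
  av <- vapply(fits, function(f) f$aicc, numeric(1))
  w <- akaike_weights(av)
  o <- order(av)
  fits <- fits[o]; w <- w[o]
  zq <- stats::qnorm(0.925)
  if (w[1] >= single_model_weight || length(fits) == 1) {
    f <- fits[[1]]
    tab <- data.frame(term = names(f$coefficients),
                      estimate = unname(f$coefficients),
                      se = unname(f$se),
                      lo85 = unname(f$coefficients - zq * f$se),
                      hi85 = unname(f$coefficients + zq * f$se),
                      ri = NA_real_, stringsAsFactors = FALSE)
    return(structure(list(table = tab, single = TRUE, weights = w,
                          fits = fits), class = "averaged_model"))
  }
  keep <- w > weight_floor
  fits <- fits[keep]; w <- w[keep] / sum(w[keep])
  terms <- unique(unlist(lapply(fits, function(f) names(f$coefficients))))
  est <- se <- ri <- numeric(length(terms))
  for (t in seq_along(terms)) {
    tn <- terms[t]
    b <- vapply(fits, function(f)
      if (tn %in% names(f$coefficients)) unname(f$coefficients[tn]) else 0,
      numeric(1))
    s <- vapply(fits, function(f)
      if (tn %in% names(f$coefficients)) unname(f$se[tn]) else 0, numeric(1))
    has <- vapply(fits, function(f) tn %in% names(f$coefficients), logical(1))
    ri[t] <- sum(w[has])
    if (conditional) {
      wc <- w[has] / sum(w[has])
      est[t] <- sum(wc * b[has])
      se[t] <- sum(wc * sqrt(s[has]^2 + (b[has] - est[t])^2))
    } else {
      est[t] <- sum(w * b)
      se[t] <- sum(w * sqrt(s^2 + (b - est[t])^2))
    }
  }
  tab <- data.frame(term = terms, estimate = est, se = se,
                    lo85 = est - zq * se, hi85 = est + zq * se, ri = ri,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, single = FALSE, weights = w, fits = fits),
            class = "averaged_model")
}

#' @export
print.averaged_model <- function(x, ...) {
  cat(if (x$single) "single top model (Akaike weight >= 0.9)\n"
      else sprintf("full model average over %d models\n", length(x$fits)))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Candidate ranking table
#'
#' @param fits list of `fv_fit` objects.
#' @return data.frame with model terms, k, AICc, delta AICc and weight.
#' @export
ranking_table <- function(fits) {
  av <- vapply(fits, function(f) f$aicc, numeric(1))
  o <- order(av)
  fits <- fits[o]; av <- av[o]
  data.frame(
    model = vapply(fits, function(f)
      if (length(f$spec$fixed)) paste(f$spec$fixed, collapse = " + ")
      else "(intercept)", character(1)),
    k = vapply(fits, function(f) f$k, numeric(1)),
    aicc = av, delta_aicc = av - av[1],
    weight = akaike_weights(av),
    converged = vapply(fits, function(f) f$converged, logical(1)),
    stringsAsFactors = FALSE)
}
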