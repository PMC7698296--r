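# Model diagnostics: collinearity (VIF), overdispersion, Nakagawa-style
# pseudo-R-squared for logit GLMMs, spatial autocorrelation of residuals
# (Moran's I over k-nearest-neighbour weights), and the rank-based
# descriptive tests used in the farm-use comparisons.

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is from the OLS regression of
#' column `j` on all other columns (plus an intercept).
#'
#' @param X numeric matrix or data.frame of predictor columns (no intercept
#'   column).
#' @return named numeric vector of VIFs.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("VIF needs at least two predictor columns")
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    aliased <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X) + 1)] - 1]
    stop("rank-deficient design; aliased terms: ",
         paste(aliased, collapse = ", "))
  }
  out <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(X)
  out
}

#' Overdispersion ratio
#'
#' Sum of squared Pearson residuals divided by the residual degrees of
#' freedom (`n` rows minus `k` estimated parameters, fixed coefficients plus
#' variance components).
#'
#' @param fit an `fv_fit` (with its kept model object) or a fitted
#'   `glmerMod`/`glm` plus explicit `k`.
#' @param k parameter count (taken from an `fv_fit` automatically).
#' @return the dispersion ratio.
#' @export
overdispersion_ratio <- function(fit, k = NULL) {
  if (inherits(fit, "fv_fit")) {
    if (is.null(fit$model)) stop("fit was not kept; refit with keep_model = TRUE")
    k <- fit$k
    n <- fit$n
    model <- fit$model
  } else {
    model <- fit
    n <- stats::nobs(model)
    if (is.null(k)) stop("supply k for a raw model object")
  }
  pr <- stats::residuals(model, type = "pearson")
  sum(pr^2) / (n - k)
}

#' Marginal and conditional pseudo-R-squared for a logit GLMM
#'
#' Variance-partition formulation for the latent (logit) scale:
#' marginal = var(fixed linear predictor) / total, conditional =
#' (fixed + random-intercept variances) / total, with the logistic
#' distribution-specific variance pi^2 / 3 completing the denominator.
#'
#' @param fit an `fv_fit` with its model kept.
#' @return list with `marginal` and `conditional`.
#' @export
pseudo_r2 <- function(fit) {
  stopifnot(inherits(fit, "fv_fit"))
  if (is.null(fit$model)) stop("fit was not kept; refit with keep_model = TRUE")
  if (length(fit$spec$random)) {
    X <- lme4::getME(fit$model, "X")
  } else {
    X <- stats::model.matrix(fit$model)
  }
  eta_fixed <- as.numeric(X %*% fit$coefficients)
  var_f <- stats::var(eta_fixed)
  var_r <- sum(fit$varcomp^2)
  var_d <- pi^2 / 3
  tot <- var_f + var_r + var_d
  list(marginal = var_f / tot, conditional = (var_f + var_r) / tot)
}

#' Moran's I of residuals over k-nearest-neighbour weights
#'
#' Row-standardized k-nearest-neighbour weights; `I = (z' W z) / (z' z)`
#' with centred residuals `z` (the usual `n / S0` factor is absorbed by row
#' standardization). The p-value comes from random permutations of the
#' residuals over the locations.
#'
#' @param residuals numeric vector (e.g. per-farm mean Pearson residuals).
#' @param coords two-column matrix of locations.
#' @param k_neighbors number of nearest neighbours (default 15).
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed for the permutation null.
#' @param alternative `"greater"` (positive autocorrelation, default),
#'   `"less"`, or `"two.sided"`.
#' @return list with `I`, `p_value`, `expected` (permutation mean), `n`.
#' @export
morans_i <- function(residuals, coords, k_neighbors = 15, n_perm = 999,
                     seed = 1, alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  coords <- as.matrix(coords)
  n <- length(residuals)
  stopifnot(nrow(coords) == n)
  if (n < k_neighbors + 1) stop("need more locations than neighbours")
  if (stats::sd(residuals) == 0) stop("constant residuals")
  dd <- as.matrix(stats::dist(coords))
  diag(dd) <- Inf
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(dd[i, ])[seq_len(k_neighbors)]
    W[i, nb] <- 1 / k_neighbors
  }
  stat <- function(z) {
    z <- z - mean(z)
    sum(z * (W %*% z)) / sum(z^2)
  }
  I_obs <- stat(residuals)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  I_perm <- vapply(seq_len(n_perm), function(i) stat(sample(residuals)),
                   numeric(1))
  p <- switch(alternative,
    greater = (1 + sum(I_perm >= I_obs)) / (n_perm + 1),
    less = (1 + sum(I_perm <= I_obs)) / (n_perm + 1),
    two.sided = (1 + sum(abs(I_perm - mean(I_perm)) >=
                           abs(I_obs - mean(I_perm)))) / (n_perm + 1))
  list(I = I_obs, p_value = p, expected = mean(I_perm), n = n)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two independent samples via `stats::wilcox.test`:
#' exact enumeration when both samples together hold at most 12 untied
#' values, tie-corrected normal approximation otherwise.
#'
#' @param a,b numeric samples.
#' @return list with `W` (rank-sum statistic of the first sample) and
#'   `p_value`.
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- (length(a) + length(b) <= 12) && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = use_exact,
                                            correct = !use_exact))
  list(W = unname(wt$statistic), p_value = wt$p.value)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks.
#'
#' @param x,y numeric vectors of equal length.
#' @return the correlation coefficient.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector")
  stats::cor(x, y, method = "spearman")
}
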