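# lightweight stand-in fits for testing ranking/averaging arithmetic
stub_fit <- function(terms, aicc, coefficients = NULL, se = NULL) {
  if (is.null(coefficients))
    coefficients <- setNames(rep(0.5, length(terms) + 1),
                             c("(Intercept)", terms))
  if (is.null(se)) se <- setNames(rep(0.1, length(coefficients)),
                                  names(coefficients))
  structure(list(spec = model_spec(terms), coefficients = coefficients,
                 se = se, varcomp = numeric(0), log_likelihood = NA,
                 k = length(coefficients), n = 100, aicc = aicc,
                 converged = TRUE, singular = FALSE, model = NULL),
            class = "fv_fit")
}

test_that("AICc arithmetic is exact", {
  expect_equal(aicc(-100, 3, 100), 206.25)
  expect_equal(aicc(-100, 0, 100), 200)        # k = 0 reduces to -2 logLik
  expect_equal(aicc(-100, 3, 1e9), 206, tolerance = 1e-6)  # AICc -> AIC
  expect_error(aicc(-100, 3, 4), "n must exceed")
})

test_that("Akaike weights normalize and match the two-model closed form", {
  expect_equal(akaike_weights(c(120, 120)), c(0.5, 0.5))
  w <- akaike_weights(c(100, 102))
  expect_equal(w, c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               tolerance = 1e-7)
  set.seed(2)
  any10 <- akaike_weights(runif(10, 100, 140))
  expect_lt(abs(sum(any10) - 1), 1e-12)
})

test_that("candidate enumeration matches the power-set oracle", {
  set.seed(14)
  d <- data.frame(a = rnorm(60), b = rnorm(60), c = rnorm(60))
  specs <- enumerate_candidates(c("a", "b", "c"), d)
  expect_equal(length(specs), 8)
  # collinear pair: only null, a, b remain
  d2 <- d; d2$b <- 0.9 * d2$a + 0.1 * rnorm(60)
  expect_equal(length(enumerate_candidates(c("a", "b"), d2)), 3)
  # interaction: null, a, b, a+b, a+b+a:b
  s5 <- enumerate_candidates(c("a", "b"), d, interactions = list(c("a", "b")))
  expect_equal(length(s5), 5)
  expect_true(any(vapply(s5, function(s) "a:b" %in% s$fixed, logical(1))))
  # brute-force oracle on a larger pool with a known banned pair
  d6 <- data.frame(matrix(rnorm(6 * 80), 80, 6))
  names(d6) <- letters[1:6]
  d6$f <- 0.92 * d6$e + 0.08 * rnorm(80)
  specs6 <- enumerate_candidates(letters[1:6], d6)
  # oracle: subsets of 6 terms not containing both e and f
  n_oracle <- sum(vapply(0:63, function(m) {
    sel <- letters[1:6][bitwAnd(m, 2^(0:5)) > 0]
    !all(c("e", "f") %in% sel)
  }, logical(1)))
  expect_equal(length(specs6), n_oracle)
})

test_that("uninformative-parameter pruning follows the nesting rule", {
  a <- stub_fit("x1", 100)
  b <- stub_fit(c("x1", "x2"), 101.5)   # nested, within 2 -> discarded
  keep <- prune_uninformative(list(a, b))
  expect_equal(length(keep), 1)
  expect_equal(keep[[1]]$spec$fixed, "x1")
  # net AICc reduction: retained
  b2 <- stub_fit(c("x1", "x2"), 99.5)
  expect_equal(length(prune_uninformative(list(a, b2))), 2)
  # non-nested models one AICc apart: both retained
  c1 <- stub_fit("x1", 100); c2 <- stub_fit("x2", 101)
  expect_equal(length(prune_uninformative(list(c1, c2))), 2)
})

test_that("model averaging implements full zero-substitution averaging", {
  # single dominant model returned unaveraged
  dom <- list(stub_fit("x1", 100), stub_fit("x2", 110))
  avg <- model_average(dom)
  expect_true(avg$single)
  expect_equal(sort(avg$table$term), sort(c("(Intercept)", "x1")))
  # two equal-weight models sharing a term: average = mean of estimates
  f1 <- stub_fit("x1", 100, c("(Intercept)" = 0, x1 = 1.0),
                 c("(Intercept)" = 0.1, x1 = 0.2))
  f2 <- stub_fit(c("x1", "x2"), 100,
                 c("(Intercept)" = 0, x1 = 2.0, x2 = 0.4),
                 c("(Intercept)" = 0.1, x1 = 0.2, x2 = 0.1))
  avg2 <- model_average(list(f1, f2))
  expect_false(avg2$single)
  t_x1 <- avg2$table[avg2$table$term == "x1", ]
  expect_equal(t_x1$estimate, 1.5)
  expect_equal(t_x1$ri, 1)
  # term in half the weight mass: full average halves it, RI = 0.5
  t_x2 <- avg2$table[avg2$table$term == "x2", ]
  expect_equal(t_x2$estimate, 0.2)
  expect_equal(t_x2$ri, 0.5)
  # averaged estimate of an everywhere-present term stays in the hull
  expect_true(t_x1$estimate >= 1 && t_x1$estimate <= 2)
  # 85% CI uses the 92.5% normal quantile
  expect_equal(t_x1$hi85 - t_x1$estimate, qnorm(0.925) * t_x1$se)
})

test_that("GLMM with zero-variance groups degenerates to the GLM", {
  set.seed(31)
  d <- glmm_table(n = 300, sd_farm = 0, sd_sem = 0, seed = 31)
  f <- fit_binomial_glmm(d, model_spec(c("x1", "x2"),
                                       c("farm_id", "semester")))
  g <- glm(cbind(numerator, denominator - numerator) ~ x1 + x2,
           data = d, family = binomial)
  expect_lt(max(abs(f$coefficients - coef(g))), 1e-4)
  expect_true(f$singular)
  expect_equal(f$k, length(coef(g)) + 2)
})

test_that("the fit matches an independent mixed-model implementation", {
  d <- read.csv(system.file("extdata", "glmm_fixture.csv",
                            package = "farmvisits"))
  f <- fit_binomial_glmm(d, model_spec(c("x1", "x2"),
                                       c("farm_id", "semester")))
  tmb <- glmmTMB::glmmTMB(
    cbind(numerator, denominator - numerator) ~ x1 + x2 +
      (1 | farm_id) + (1 | semester),
    data = d, family = binomial)
  expect_lt(max(abs(f$coefficients - glmmTMB::fixef(tmb)$cond)), 1e-3)
  vc <- sqrt(unlist(glmmTMB::VarCorr(tmb)$cond))
  expect_lt(max(abs(sort(f$varcomp) - sort(as.numeric(vc)))), 1e-3)
  expect_lt(abs(f$log_likelihood - as.numeric(logLik(tmb))), 1e-3)
})

test_that("fits validate their inputs", {
  d <- glmm_table(n = 50)
  d$denominator[1] <- 0
  expect_error(fit_binomial_glmm(d, model_spec("x1", "farm_id")),
               "denominator")
  d2 <- glmm_table(n = 50)
  d2$farm_id <- "same"
  expect_error(fit_binomial_glmm(d2, model_spec("x1", "farm_id")),
               "levels")
  expect_error(model_spec("a:b"), "main effects")
})
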