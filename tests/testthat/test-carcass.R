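# synthetic interviewed-farm records with known logistic structure
disposal_records <- function(n, beta = c(intercept = 0, dist_urb = 0,
                                         dist_dump = 0), seed = 1) {
  set.seed(seed)
  d <- data.frame(dist_dump = rnorm(n), dist_afs = rnorm(n),
                  dist_road = rnorm(n), goat_sheep = rnorm(n),
                  dist_urb = rnorm(n))
  eta <- beta[["intercept"]]
  for (t in setdiff(names(beta), "intercept")) eta <- eta + beta[[t]] * d[[t]]
  d$answer <- rbinom(n, 1, plogis(eta))
  d
}

test_that("intercept-only fit on balanced outcomes gives logit(0.5)", {
  d <- disposal_records(50)
  d$answer <- rep(c(0, 1), 25)
  f <- fit_disposal_glm(d, character(0))
  expect_lt(abs(f$coefficients[["(Intercept)"]]), 1e-8)
  expect_equal(f$k, 1)
})

test_that("single-predictor fit matches a hand-coded Newton-Raphson oracle", {
  d <- disposal_records(200, c(intercept = -0.5, dist_urb = 0.8), seed = 3)
  f <- fit_disposal_glm(d, "dist_urb")
  # independent IRLS: Newton-Raphson on the logistic log-likelihood
  X <- cbind(1, d$dist_urb); y <- d$answer
  b <- c(0, 0)
  for (it in 1:50) {
    p <- plogis(X %*% b)
    W <- as.numeric(p * (1 - p))
    step <- solve(t(X) %*% (W * X), t(X) %*% (y - p))
    b <- b + step
    if (max(abs(step)) < 1e-12) break
  }
  expect_lt(max(abs(f$coefficients - as.numeric(b))), 1e-6)
})

test_that("selection recovers a strong predictor and rejects noise", {
  hits <- 0; nulls <- 0
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    d <- disposal_records(400, c(intercept = 0, dist_urb = 1.2), seed = 100 + r)
    top <- select_disposal_model(d)
    if ("dist_urb" %in% top$spec$fixed) hits <- hits + 1
    d0 <- disposal_records(400, c(intercept = 0), seed = 200 + r)
    top0 <- select_disposal_model(d0)
    if (length(top0$spec$fixed) == 0) nulls <- nulls + 1
  }
  expect_gte(hits / n_rep, 0.9)
  expect_gte(nulls / n_rep, 0.5)
})

test_that("simulation from urban+dump coefficients recovers the signs", {
  ok <- 0
  n_rep <- 50
  for (r in seq_len(n_rep)) {
    d <- disposal_records(2000, c(intercept = 0.3, dist_urb = 0.9,
                                  dist_dump = 0.8), seed = 300 + r)
    f <- fit_disposal_glm(d, c("dist_urb", "dist_dump"))
    if (f$coefficients[["dist_urb"]] > 0 && f$coefficients[["dist_dump"]] > 0)
      ok <- ok + 1
  }
  expect_gte(ok / n_rep, 0.9)
})

test_that("collinear predictors never co-occur in candidates", {
  d <- disposal_records(300, seed = 9)
  d$dist_dump <- 0.95 * d$dist_urb + 0.05 * rnorm(300)  # |rho| ~ 0.95
  specs <- enumerate_candidates(c("dist_urb", "dist_dump"), d)
  expect_equal(length(specs), 3)  # null, urb, dump
  for (s in specs)
    expect_false(all(c("dist_urb", "dist_dump") %in% s$fixed))
})

test_that("imputation keeps observed answers and bounds predictions", {
  d <- disposal_records(150, c(intercept = 0.2, dist_urb = 0.7), seed = 5)
  fit <- fit_disposal_glm(d, "dist_urb")
  farms <- d
  farms$disposal_answer <- farms$answer
  farms$disposal_answer[1:60] <- NA
  carc <- impute_carcass(farms, fit)
  expect_equal(carc[61:150], farms$answer[61:150])
  expect_true(all(carc[1:60] > 0 & carc[1:60] < 1))
  # at the fitting sample's predictor means the prediction equals the
  # inverse-logit of the fitted linear predictor at the means
  atmean <- farms[1, ]
  atmean$disposal_answer <- NA
  atmean$dist_urb <- mean(d$dist_urb)
  expect_equal(impute_carcass(atmean, fit),
               plogis(sum(fit$coefficients * c(1, mean(d$dist_urb)))))
  # all-unknown registry: all strictly in (0, 1)
  allu <- farms; allu$disposal_answer <- NA
  cu <- impute_carcass(allu, fit)
  expect_true(all(cu > 0 & cu < 1))
  # missing predictor for an unknown farm
  bad <- farms[, setdiff(names(farms), "dist_urb")]
  expect_error(impute_carcass(bad, fit), "predictor")
})

test_that("adjusted explained deviance and AICc behave as defined", {
  d <- disposal_records(200, c(intercept = 0, dist_urb = 1), seed = 7)
  f1 <- fit_disposal_glm(d, "dist_urb")
  f0 <- fit_disposal_glm(d, character(0))
  expect_gte(f1$adjusted_explained_deviance, f0$adjusted_explained_deviance)
  expect_lt(abs(f0$adjusted_explained_deviance), 1e-10)
  # AICc is invariant to predictor standardization
  d2 <- d; d2$dist_urb <- as.numeric(scale(d2$dist_urb))
  f2 <- fit_disposal_glm(d2, "dist_urb")
  expect_lt(abs(f1$aicc - f2$aicc), 1e-6)
})

test_that("the interview tabulation reproduces the survey breakdown", {
  recs <- read_disposal_interviews()
  tab <- tabulate_disposal(recs)
  expect_equal(tab$n, 94)
  expect_equal(tab$abandoners, 57)
  expect_equal(tab$non_abandoners, 37)
  expect_equal(unname(tab$counts["collection_service"]), 21)
  # empty table: all zeros
  tab0 <- tabulate_disposal(data.frame(category = character(0)))
  expect_equal(tab0$n, 0)
  expect_true(all(tab0$counts == 0))
  expect_error(tabulate_disposal(data.frame(category = "composted")),
               "unknown")
})
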