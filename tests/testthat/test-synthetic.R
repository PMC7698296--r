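small_cfg <- function(seed = 3, ...) {
  sim_config(seed = seed, n_farms = 25, n_birds = 3, n_semesters = 1,
             days_per_month = 15, extent = c(0, 0, 20000, 15000), ...)
}

test_that("the generator is deterministic in its seed", {
  s1 <- simulate_study(small_cfg())
  s2 <- simulate_study(small_cfg())
  expect_identical(s1$farms, s2$farms)
  expect_identical(s1$fixes, s2$fixes)
  expect_identical(s1$truth$visit_days, s2$truth$visit_days)
  s3 <- simulate_study(small_cfg(seed = 4))
  expect_false(identical(s1$fixes, s3$fixes))
})

test_that("landscape generation respects its contract", {
  land <- simulate_landscape(small_cfg())
  ex <- small_cfg()$extent
  expect_equal(nrow(land$farms), 25)
  expect_true(all(land$farms$x >= ex[1] & land$farms$x <= ex[3]))
  expect_true(all(land$farms$y >= ex[2] & land$farms$y <= ex[4]))
  expect_true(all(land$farms$herd_2014S1 > 0))
  expect_gte(nrow(unclass(land$landscape$feeding_stations)), 2)
  expect_equal(nrow(unclass(land$landscape$dump)), 1)
  # DEM strictly positive over the farms
  z <- dem_elevation(land$dem, land$farms$x, land$farms$y)
  expect_true(all(z > 0))
  # degenerate case: zero farms
  land0 <- simulate_landscape(sim_config(n_farms = 0))
  expect_equal(nrow(land0$farms), 0)
  # impossible density is rejected
  expect_error(simulate_landscape(sim_config(n_farms = 500,
                                             extent = c(0, 0, 1000, 1000))),
               "too small")
})

test_that("disposal simulation matches its logistic ground truth", {
  land <- simulate_landscape(sim_config(n_farms = 400, seed = 6,
                                        extent = c(0, 0, 60000, 60000)))
  # all coefficients zero: abandonment fraction near 0.5
  d0 <- simulate_disposal(land$farms, land$landscape,
                          c(intercept = 0), known_fraction = 0.3, seed = 2)
  expect_lt(abs(mean(d0$answer_true) - 0.5), 0.08)
  expect_equal(sum(d0$known), 120)
  # saturated intercept: all answers 1
  d1 <- simulate_disposal(land$farms, land$landscape,
                          c(intercept = 30), seed = 2)
  expect_true(all(d1$answer_true == 1))
  expect_error(simulate_disposal(land$farms, land$landscape,
                                 c(intercept = 0, bogus = 1)),
               "unknown disposal predictor")
})

test_that("visit-count simulation has the configured moments", {
  design <- data.frame(farm_id = rep(sprintf("f%02d", 1:50), each = 20),
                       semester = "2014S1", x = 0, denominator = 100)
  # beta = 0, no random effects: numerators average 50
  s0 <- simulate_visit_counts(design, c(intercept = 0, x = 0),
                              c(farm = 0, semester = 0), seed = 3)
  expect_lt(abs(mean(s0$rows$numerator) - 50), 1)
  # farm-level variance inflates between-farm spread of numerators
  s2 <- simulate_visit_counts(design, c(intercept = 0, x = 0),
                              c(farm = 2, semester = 0), seed = 3)
  bf0 <- var(tapply(s0$rows$numerator, s0$rows$farm_id, mean))
  bf2 <- var(tapply(s2$rows$numerator, s2$rows$farm_id, mean))
  expect_gt(bf2, bf0 * 5)
  expect_equal(length(s2$random_effects$farm), 50)
  # determinism and denominator rejection
  s3 <- simulate_visit_counts(design, c(intercept = 0, x = 0),
                              c(farm = 2, semester = 0), seed = 3)
  expect_identical(s2$rows$numerator, s3$rows$numerator)
  design$denominator[1] <- 0
  expect_message(s4 <- simulate_visit_counts(design, c(intercept = 0, x = 0),
                                             c(farm = 0), seed = 1),
                 "rejected")
  expect_equal(nrow(s4$rows), nrow(design) - 1)
})

test_that("rendered tracks reproduce ground truth exactly", {
  sim <- simulate_study(small_cfg(seed = 7))
  vd <- aggregate_visit_days(sim$fixes, sim$fa, sim$dem)
  acc <- visit_detection_accuracy(vd, sim$truth$visit_days)
  expect_equal(acc$precision, 1)
  expect_equal(acc$recall, 1)
  # decoys-only tracks yield no visit day at all
  tracked <- data.frame(bird_id = "V001",
                        date = as.Date("2014-03-01") + 0:9)
  empty_truth <- data.frame(bird_id = character(), area_id = character(),
                            date = as.Date(character()))
  cfg <- small_cfg()
  cfg$decoy_rates <- c(high_altitude = 3, high_speed = 3, near_miss = 2)
  fx <- render_tracks(empty_truth, tracked, sim$fa, sim$dem, cfg, seed = 9)
  vd0 <- aggregate_visit_days(fx, sim$fa, sim$dem)
  expect_equal(nrow(vd0), 0)
  # every true visit day has a qualifying fix even with zero decoys
  cfg0 <- small_cfg()
  cfg0$decoy_rates <- c(high_altitude = 0, high_speed = 0, near_miss = 0)
  truth1 <- data.frame(bird_id = "V001", area_id = sim$fa$areas$area_id[1],
                       date = as.Date("2014-03-02"))
  fx1 <- render_tracks(truth1, tracked, sim$fa, sim$dem, cfg0, seed = 10)
  vd1 <- aggregate_visit_days(fx1, sim$fa, sim$dem)
  expect_equal(nrow(vd1), 1)
  expect_equal(vd1$area_id, sim$fa$areas$area_id[1])
})

test_that("study outputs round-trip through the plain-text formats", {
  sim <- simulate_study(small_cfg())
  dir <- withr::local_tempdir()
  paths <- write_study(sim, dir)
  expect_true(all(file.exists(paths)))
  farms <- read_farms_csv(file.path(dir, "farms.csv"))
  expect_equal(farms$farm_id, sim$farms$farm_id)
  fixes <- read_fixes_csv(file.path(dir, "fixes.csv"))
  expect_equal(nrow(fixes), nrow(sim$fixes))
  land <- read_landscape_geojson(file.path(dir, "landscape.geojson"))
  expect_equal(unclass(land$dump), unclass(sim$landscape$dump),
               ignore_attr = TRUE)
  expect_equal(length(unclass(land$roads)), length(unclass(sim$landscape$roads)))
  dem <- read_dem_asc(file.path(dir, "dem.asc"))
  expect_equal(dim(dem$z), dim(sim$dem$z))
})
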