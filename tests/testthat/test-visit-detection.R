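# one farm area at the origin on flat ground (elevation 100 m)
vd_fixture <- function() {
  list(fa = build_farm_areas(toy_farms(matrix(c(0, 0), ncol = 2))),
       dem = flat_dem(100))
}

mkfix <- function(x, y, agl, speed, bird = "B1",
                  ts = "2014-03-01T10:00:00Z") {
  data.frame(bird_id = bird, timestamp = ts, x = x, y = y,
             altitude_m = 100 + agl, speed_ms = speed,
             stringsAsFactors = FALSE)
}

test_that("visit criteria are strict and require containment", {
  fx <- vd_fixture()
  inside_ok <- mkfix(10, 0, agl = 10, speed = 1)
  expect_true(classify_fixes(inside_ok, fx$fa, fx$dem)$is_visit)
  # altitude above ground exactly at the 25 m threshold: not a visit
  expect_false(classify_fixes(mkfix(10, 0, 25, 1), fx$fa, fx$dem)$is_visit)
  expect_true(classify_fixes(mkfix(10, 0, 24.99, 1), fx$fa, fx$dem)$is_visit)
  # speed exactly 2 m/s: not a visit
  expect_false(classify_fixes(mkfix(10, 0, 10, 2), fx$fa, fx$dem)$is_visit)
  # 1 m outside the polygon, grounded and still: not a visit
  expect_false(classify_fixes(mkfix(181, 0, 0, 0), fx$fa, fx$dem)$is_visit)
  # on the boundary: counts as inside
  expect_true(classify_fixes(mkfix(180, 0, 0, 0), fx$fa, fx$dem)$is_visit)
})

test_that("fixes outside the DEM are excluded with a reported count", {
  fx <- vd_fixture()
  fixes <- rbind(mkfix(10, 0, 10, 1), mkfix(99999, 0, 10, 1))
  expect_message(out <- classify_fixes(fixes, fx$fa, fx$dem), "outside the DEM")
  expect_equal(nrow(out), 1)
  expect_equal(attr(out, "n_outside_dem"), 1)
})

test_that("qualifying fixes collapse to one visit day per bird-area-date", {
  fx <- vd_fixture()
  ts1 <- sprintf("2014-03-01T%02d:00:00Z", 8:17)
  many <- do.call(rbind, lapply(ts1, function(t) mkfix(10, 0, 5, 1, ts = t)))
  vd <- aggregate_visit_days(many, fx$fa, fx$dem)
  expect_equal(nrow(vd), 1)
  expect_equal(vd$date, as.Date("2014-03-01"))
  two_days <- rbind(mkfix(10, 0, 5, 1, ts = "2014-03-01T10:00:00Z"),
                    mkfix(10, 0, 5, 1, ts = "2014-03-02T10:00:00Z"))
  expect_equal(nrow(aggregate_visit_days(two_days, fx$fa, fx$dem)), 2)
})

test_that("detection is invariant to fix order and monotone in thresholds", {
  fx <- vd_fixture()
  set.seed(8)
  n <- 200
  fixes <- data.frame(
    bird_id = sample(c("B1", "B2"), n, TRUE),
    timestamp = sprintf("2014-03-%02dT%02d:%02d:00Z",
                        sample(1:20, n, TRUE), sample(6:20, n, TRUE),
                        sample(0:59, n, TRUE)),
    x = runif(n, -400, 400), y = runif(n, -400, 400),
    altitude_m = 100 + runif(n, 0, 60), speed_ms = runif(n, 0, 5),
    stringsAsFactors = FALSE)
  vd1 <- aggregate_visit_days(fixes, fx$fa, fx$dem)
  vd2 <- aggregate_visit_days(fixes[sample(n), ], fx$fa, fx$dem)
  expect_equal(vd1, vd2)
  # raising thresholds never removes a visit day
  vd_loose <- aggregate_visit_days(fixes, fx$fa, fx$dem,
                                   altitude_threshold = 60,
                                   speed_threshold = 6)
  key <- function(d) paste(d$bird_id, d$area_id, d$date)
  expect_true(all(key(vd1) %in% key(vd_loose)))
})

test_that("coverage and eligibility enforce the 15-day month rule", {
  # bird A: every day of 2014S1; bird B: only 14 days in February
  days_a <- semester_dates("2014S1")
  days_b <- c(seq(as.Date("2014-01-01"), as.Date("2014-01-31"), by = "day"),
              seq(as.Date("2014-02-01"), as.Date("2014-02-14"), by = "day"),
              seq(as.Date("2014-03-01"), as.Date("2014-06-30"), by = "day"))
  fixes <- rbind(
    data.frame(bird_id = "A", timestamp = paste0(days_a, "T10:00:00Z")),
    data.frame(bird_id = "B", timestamp = paste0(days_b, "T10:00:00Z")))
  cov <- coverage_and_eligibility(fixes, "2014S1")
  a <- cov[cov$bird_id == "A", ]; b <- cov[cov$bird_id == "B", ]
  expect_true(a$eligible)
  expect_equal(a$n_days, length(days_a))
  expect_false(b$eligible)
  expect_equal(b$n_days, length(days_b))
  # a bird with no fixes at all is ineligible with denominator 0
  cov2 <- coverage_and_eligibility(fixes[fixes$bird_id == "A", ],
                                   c("2014S1", "2014S2"))
  s2 <- cov2[cov2$semester == "2014S2", ]
  expect_false(s2$eligible)
  expect_equal(s2$n_days, 0L)
})

test_that("visit distance summary matches hand-computed values", {
  fx <- vd_fixture()
  one <- mkfix(50, 0, 5, 1)
  s1 <- visit_distance_summary(one, fx$fa, fx$dem)
  expect_equal(s1$mean_m, 50)
  expect_equal(s1$sd_m, 0)
  two <- rbind(mkfix(0, 0, 5, 1), mkfix(100, 0, 5, 1))
  s2 <- visit_distance_summary(two, fx$fa, fx$dem)
  expect_equal(s2$mean_m, 50)
  expect_equal(s2$n, 2)
  none <- mkfix(10, 0, 60, 1)
  expect_error(visit_distance_summary(none, fx$fa, fx$dem), "no qualifying")
})
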