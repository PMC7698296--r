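# three-farm / three-bird fixture on flat ground
rt_fixture <- function() {
  farms <- toy_farms(rbind(c(0, 0), c(5000, 0), c(10000, 0)),
                     semesters = "2014S1", herd = c(50, 100, 150))
  fa <- build_farm_areas(farms)
  land <- toy_landscape()
  elig <- data.frame(bird_id = c("A", "B", "C"), semester = "2014S1",
                     eligible = TRUE, n_days = c(120, 110, 100),
                     stringsAsFactors = FALSE)
  list(farms = farms, fa = fa, land = land, elig = elig)
}

test_that("FARM rows count distinct eligible birds over eligible trackers", {
  f <- rt_fixture()
  a1 <- f$fa$farms$area_id[1]
  vd <- data.frame(bird_id = c("A", "A", "B"),
                   area_id = a1,
                   date = as.Date(c("2014-03-01", "2014-03-05", "2014-04-02")))
  rows <- build_farm_table(vd, f$elig, f$fa, f$land, "2014S1")
  expect_equal(nrow(rows), 3)
  r1 <- rows[rows$area_id == a1, ]
  expect_equal(r1$numerator, 2)   # A and B, days collapse to birds
  expect_equal(r1$denominator, 3)
  expect_true(all(rows$numerator[rows$area_id != a1] == 0))
  expect_equal(unique(rows$breeding), 1)
})

test_that("inactive farm areas produce no FARM row", {
  f <- rt_fixture()
  f$fa$farms$active_2014S1[3] <- FALSE
  vd <- data.frame(bird_id = "A", area_id = f$fa$farms$area_id[1],
                   date = as.Date("2014-03-01"))
  rows <- build_farm_table(vd, f$elig, f$fa, f$land, "2014S1")
  expect_equal(nrow(rows), 2)
  expect_false(f$fa$farms$area_id[3] %in% rows$area_id)
})

test_that("semesters without eligible birds are skipped with a message", {
  f <- rt_fixture()
  f$elig$eligible <- FALSE
  vd <- data.frame(bird_id = "A", area_id = f$fa$farms$area_id[1],
                   date = as.Date("2014-03-01"))
  expect_message(expect_error(
    build_farm_table(vd, f$elig, f$fa, f$land, "2014S1"), "no semester"),
    "skipped")
})

test_that("VULTURE rows pair bird-semesters with in-range candidate farms", {
  f <- rt_fixture()
  # D is a second territory holder (not tracked) so that A has a
  # different-from-own occupied nest for dist_terr
  birds <- data.frame(bird_id = c("A", "B", "C", "D"),
                      sex = c("M", "F", "M", "F"),
                      birth_year = c(2008, 2010, 2012, 2005),
                      stringsAsFactors = FALSE)
  bs <- data.frame(bird_id = c("A", "B", "C", "D"), semester = "2014S1",
                   territorial = c(TRUE, FALSE, FALSE, TRUE),
                   nest_x = c(200, NA, NA, 7000),
                   nest_y = c(200, NA, NA, 6000),
                   success = c(1, NA, NA, 0), stringsAsFactors = FALSE)
  # home range around farm 1 only (fixes cluster at the origin)
  set.seed(2)
  ranges <- list()
  for (b in c("A", "B"))
    ranges[[paste(b, "2014S1", sep = "|")]] <-
      home_range(cbind(rnorm(40, 0, 800), rnorm(40, 0, 800)))
  a1 <- f$fa$farms$area_id[1]; a3 <- f$fa$farms$area_id[3]
  vd <- data.frame(bird_id = c("A", "A", "A", "B"),
                   area_id = c(a1, a1, a3, a1),
                   date = as.Date(c("2014-03-01", "2014-03-02",
                                    "2014-03-03", "2014-05-01")))
  tabs <- build_vulture_tables(vd, f$elig, bs, birds, f$fa, f$land, ranges)
  tt <- tabs$territorial; nt <- tabs$non_territorial
  expect_equal(unique(tt$bird_id), "A")
  expect_equal(unique(nt$bird_id), "B")  # C has no home range
  # numerator: A visited area 1 on 2 days; denominator = tracked days
  expect_equal(tt$numerator[tt$area_id == a1], 2)
  expect_equal(unique(tt$denominator), 120)
  # the visit to out-of-range farm 3 is excluded but logged
  expect_false(a3 %in% tt$area_id)
  expect_equal(attr(tt, "out_of_range_visits"), 1L)
  # territorial rows carry nest-based covariates, non-territorial do not
  expect_true(all(c("dist_nest", "success") %in% names(tt)))
  expect_false("dist_nest" %in% names(nt))
  expect_true("dist_terr" %in% names(nt))
  # age = semester year minus birth year
  expect_equal(unique(tt$age), 6)
})

test_that("removing a bird leaves other birds' rows unchanged", {
  f <- rt_fixture()
  birds <- data.frame(bird_id = c("A", "B"), sex = c("M", "F"),
                      birth_year = c(2008, 2010), stringsAsFactors = FALSE)
  bs <- data.frame(bird_id = c("A", "B"), semester = "2014S1",
                   territorial = FALSE, nest_x = NA, nest_y = NA,
                   success = NA, stringsAsFactors = FALSE)
  set.seed(3)
  ranges <- list()
  for (b in c("A", "B"))
    ranges[[paste(b, "2014S1", sep = "|")]] <-
      home_range(cbind(rnorm(30, 0, 900), rnorm(30, 0, 900)))
  # one occupied nest must exist for dist_terr of non-territorial birds
  bs2 <- rbind(bs, data.frame(bird_id = "T", semester = "2014S1",
                              territorial = TRUE, nest_x = 4000,
                              nest_y = 3000, success = 0))
  birds2 <- rbind(birds, data.frame(bird_id = "T", sex = "M",
                                    birth_year = 2005))
  vd <- data.frame(bird_id = "A", area_id = f$fa$farms$area_id[1],
                   date = as.Date("2014-03-01"))
  both <- build_vulture_tables(vd, f$elig, bs2, birds2, f$fa, f$land, ranges)
  onlyA <- build_vulture_tables(
    vd, f$elig, bs2[bs2$bird_id != "B", ], birds2[birds2$bird_id != "B", ],
    f$fa, f$land, ranges)
  a_both <- both$non_territorial[both$non_territorial$bird_id == "A", ]
  a_only <- onlyA$non_territorial
  expect_equal(a_both, a_only, ignore_attr = TRUE)
})

test_that("standardization is an invertible z-score on continuous columns", {
  set.seed(5)
  rows <- data.frame(dist_road = runif(40, 0, 9000),
                     goat_sheep = rpois(40, 80),
                     breeding = rep(0:1, 20),
                     constant = 5)
  expect_warning(std <- standardize_rows(rows, c("dist_road", "goat_sheep",
                                                 "constant")),
                 "constant")
  expect_null(std$constant)
  expect_lt(abs(mean(std$dist_road)), 1e-10)
  expect_lt(abs(sd(std$dist_road) - 1), 1e-10)
  expect_identical(std$breeding, rows$breeding)  # factors untouched
  back <- unstandardize_rows(std)
  expect_equal(back$dist_road, rows$dist_road)
  expect_equal(back$goat_sheep, as.numeric(rows$goat_sheep))
})

test_that("run_analysis recovers a planted effect end to end", {
  set.seed(55)
  # plant a strong herd-size effect in a FARM-like table
  n_s <- 4
  fa_stub <- build_farm_areas(toy_farms(
    cbind(runif(40, 0, 30000), runif(40, 0, 30000))))
  n_f <- nrow(fa_stub$areas)
  grid <- expand.grid(farm_id = fa_stub$areas$area_id,
                      semester = semester_seq("2013S1", n_s),
                      stringsAsFactors = FALSE)
  grid$goat_sheep <- rlnorm(nrow(grid), 4, 0.6)
  grid$dist_road <- runif(nrow(grid), 0, 8000)
  grid$breeding <- semester_breeding(grid$semester)
  grid$denominator <- 30
  z <- scale(log(grid$goat_sheep))
  eta <- -1.5 + 1.2 * as.numeric(z)
  grid$numerator <- rbinom(nrow(grid), 30, plogis(eta))
  res <- run_analysis("FARM", grid, fa_stub,
                      terms = c("goat_sheep", "dist_road", "breeding"),
                      interactions = list(), k_neighbors = 10, seed = 2)
  est <- res$averaged$table
  expect_gt(est$estimate[est$term == "goat_sheep"], 0.5)
  expect_true(all(c("overdispersion", "pseudo_r2") %in%
                  names(res$diagnostics)))
  # determinism: identical rerun
  res2 <- run_analysis("FARM", grid, fa_stub,
                       terms = c("goat_sheep", "dist_road", "breeding"),
                       interactions = list(), k_neighbors = 10, seed = 2)
  expect_equal(res$ranking, res2$ranking)
  expect_equal(res$averaged$table, res2$averaged$table)
})

test_that("descriptive comparisons detect planted group differences", {
  set.seed(66)
  n_per <- 20
  bs <- data.frame(bird_id = sprintf("b%02d", 1:(2 * n_per)),
                   semester = "2014S1",
                   territorial = FALSE, stringsAsFactors = FALSE)
  birds <- data.frame(bird_id = bs$bird_id,
                      sex = rep(c("M", "F"), each = n_per),
                      stringsAsFactors = FALSE)
  farms <- toy_farms(cbind(seq(0, 39000, by = 1000), 0),
                     semesters = "2014S1")
  fa <- build_farm_areas(farms)
  ranges <- list(); vd <- list()
  for (i in seq_len(nrow(bs))) {
    male <- birds$sex[i] == "M"
    # males range over many farms, females over few
    nfarm <- if (male) 25 else 5
    xs <- seq(0, by = 1000, length.out = nfarm)
    ranges[[paste(bs$bird_id[i], "2014S1", sep = "|")]] <-
      home_range(cbind(c(xs, xs), rnorm(2 * nfarm, 0, 300)), cell_size = 200)
    visited <- sample(fa$farms$area_id[seq_len(nfarm)],
                      if (male) 15 else 3)
    vd[[i]] <- data.frame(bird_id = bs$bird_id[i], area_id = visited,
                          date = as.Date("2014-03-01") + seq_along(visited))
  }
  out <- descriptive_comparisons(do.call(rbind, vd), bs, birds, ranges, fa)
  sexcomp <- out$comparisons[out$comparisons$comparison ==
                             "sex_visited_nonterr_breeding", ]
  expect_lt(sexcomp$p, 0.05)
  expect_gt(out$spearman_visited_vs_k95, 0.7)
})
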