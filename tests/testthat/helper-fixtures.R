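# Shared fixture builders; everything is generated in code under fixed seeds.

# flat-ground DEM covering [-5000, 15000]^2 at 250 m cells
flat_dem <- function(elev = 100) {
  nx <- 80
  dem_grid(matrix(elev, nx, nx), -5000, -5000, 250)
}

# a minimal landscape around the origin
toy_landscape <- function() {
  list(roads = fv_lines(list(cbind(c(-5000, 15000), c(-2000, -2000)))),
       urban = fv_polygons(list(cbind(c(8000, 10000, 10000, 8000),
                                      c(8000, 8000, 10000, 10000)))),
       dump = fv_points(matrix(c(6000, 0), ncol = 2)),
       feeding_stations = fv_points(rbind(c(0, 9000), c(12000, 5000))))
}

# farms with per-semester herd/active columns
toy_farms <- function(xy, semesters = "2014S1", herd = 100) {
  f <- data.frame(farm_id = sprintf("F%03d", seq_len(nrow(xy))),
                  x = xy[, 1], y = xy[, 2], stringsAsFactors = FALSE)
  for (s in semesters) {
    f[[paste0("herd_", s)]] <- rep_len(herd, nrow(f))
    f[[paste0("active_", s)]] <- rep_len(TRUE, nrow(f))
  }
  f
}

# binomial GLMM table with known effects, for inference tests
glmm_table <- function(n = 300, nf = 25, ns = 4, beta = c(-1, 0.7, -0.4),
                       sd_farm = 0.6, sd_sem = 0.3, denominator = 40,
                       seed = 11) {
  set.seed(seed)
  d <- data.frame(farm_id = sample(sprintf("f%02d", 1:nf), n, TRUE),
                  semester = sample(sprintf("s%d", 1:ns), n, TRUE),
                  x1 = rnorm(n), x2 = rnorm(n), stringsAsFactors = FALSE)
  uf <- rnorm(nf, 0, sd_farm); us <- rnorm(ns, 0, sd_sem)
  eta <- beta[1] + beta[2] * d$x1 + beta[3] * d$x2 +
    uf[as.integer(factor(d$farm_id))] + us[as.integer(factor(d$semester))]
  d$denominator <- denominator
  d$numerator <- rbinom(n, denominator, plogis(eta))
  d
}

# brute-force component oracle: pairwise threshold graph + transitive closure
oracle_components <- function(xy, r) {
  n <- nrow(xy)
  reach <- (as.matrix(dist(xy)) < 2 * r) | diag(n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (all(nxt == reach)) break
    reach <- nxt
  }
  comp <- integer(n); k <- 0
  for (i in seq_len(n)) if (comp[i] == 0) {
    k <- k + 1
    comp[reach[i, ]] <- k
  }
  comp
}

same_partition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}
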