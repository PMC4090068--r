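# a unit-ESW fit: uniform key with w = 1000 m gives mu = 1 km, p = 1, CV = 0
unit_esw_fit <- function(n = 30) {
  set.seed(99)
  fit_detection(as_sightings(runif(n, 0, 1000)),
                detection_spec("uniform", truncation_m = 1000))
}

test_that("abundance follows the Horvitz-Thompson formula", {
  fit <- unit_esw_fit(30)
  obs <- as_sightings(runif(30, 0, 1000),
                      group_size = rep(c(1, 1, 1, 2, 1), 6),
                      transect_id = rep(1:5, each = 6))
  tr <- data.frame(transect_id = 1:5, stratum = "Rowley", length_km = 30)
  est <- estimate_abundance(fit, obs, tr, "Rowley", area_km2 = 1000)
  # N = n / (2 mu L) * A * s-bar = 30 / (2 * 1 * 150) * 1000 * 1.2 = 120
  expect_equal(est$n_hat, 120)
  expect_equal(est$density_groups_km2, 0.1)
  expect_equal(est$mean_group_size, 1.2)
  expect_equal(est$cv, est$se / est$n_hat)
  expect_lt(est$ci[1], est$n_hat)
  expect_gt(est$ci[2], est$n_hat)
})

test_that("empty stratum yields zero abundance with undefined CV", {
  fit <- unit_esw_fit(30)
  obs <- as_sightings(runif(30, 0, 1000), transect_id = 1)
  obs$stratum <- "Other"
  tr <- data.frame(transect_id = 1:2, stratum = "Rowley",
                   length_km = c(30, 40))
  expect_warning(est <- estimate_abundance(fit, obs, tr, "Rowley", 1000),
                 "no observations")
  expect_equal(est$n_hat, 0)
  expect_true(est$undefined_cv)
})

test_that("single transect requires an encounter-variance override", {
  fit <- unit_esw_fit(30)
  obs <- as_sightings(runif(30, 0, 1000), transect_id = 1)
  tr <- data.frame(transect_id = 1, stratum = "Rowley", length_km = 150)
  expect_error(estimate_abundance(fit, obs, tr, "Rowley", 1000),
               "single transect")
  est <- estimate_abundance(fit, obs, tr, "Rowley", 1000,
                            cv_encounter_override = 0.2)
  expect_equal(unname(est$cv_components["encounter"]), 0.2)
})

test_that("encounter-rate variance matches the replicate-lines formula", {
  fit <- unit_esw_fit(30)
  obs <- as_sightings(runif(30, 0, 1000),
                      transect_id = c(rep(1, 12), rep(2, 10), rep(3, 8)))
  tr <- data.frame(transect_id = 1:3, stratum = "Rowley",
                   length_km = c(40, 50, 60))
  est <- estimate_abundance(fit, obs, tr, "Rowley", 1000)
  L <- 150; er <- 30 / L
  nk <- c(12, 10, 8); lk <- c(40, 50, 60)
  var_er <- 3 / (L^2 * 2) * sum(lk^2 * (nk / lk - er)^2)
  expect_equal(unname(est$cv_components["encounter"]), sqrt(var_er) / er)
  # zero-count transects enter the between-transect variance
  tr4 <- rbind(tr, data.frame(transect_id = 4, stratum = "Rowley",
                              length_km = 50))
  est4 <- estimate_abundance(fit, obs, tr4, "Rowley", 1000)
  expect_gt(est4$cv_components["encounter"], est$cv_components["encounter"])
})

test_that("satellite-style full-coverage census is far more precise than the
           transect survey", {
  # the census CV carries only a detection component; the transect CV adds
  # encounter-rate and group-size components an order of magnitude larger
  sat <- fit_closed_mt(capture_summary(90, 40, 38))
  expect_lt(sat$cv, 0.05)
  set.seed(8)
  sc <- generate_scene(sim_config(n_bears = 100, n_rocks = 0,
                                  n_ephemeral = 0, seed = 8))
  sv <- simulate_line_transect(sc)
  fit <- fit_detection(sv$sightings,
                       detection_spec("halfnormal", truncation_m = 2300))
  est <- estimate_abundance(fit, sv$sightings, sv$transects, "Rowley",
                            sc$area_km2)
  expect_gt(est$cv, 2 * sat$cv)
})
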