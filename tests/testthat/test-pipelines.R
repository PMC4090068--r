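test_that("satellite pipeline reproduces the worked example from fixture tables", {
  tabs <- make_fixture_tables()
  rep <- run_satellite_pipeline(run_config(seed = 1), observer_tables = tabs)
  expect_equal(rep$summary$n1, 90)
  expect_equal(rep$summary$n2, 40)
  expect_equal(rep$summary$m, 38)
  expect_equal(rep$n_hat, 94)
  expect_equal(round_half_up(rep$ci[2]), 105)
  expect_equal(rep$detection$p_conditional_pct[2], 42L)
})

test_that("pipelines are reproducible from config and seed", {
  cfg <- run_config(seed = 7, scene = list(n_rocks = 0, n_ephemeral = 0))
  a <- run_satellite_pipeline(cfg)
  b <- run_satellite_pipeline(cfg)
  expect_identical(a$summary, b$summary)
  expect_identical(a$ci, b$ci)
  expect_identical(a$log, b$log)
  aa <- suppressWarnings(run_aerial_pipeline(cfg))
  bb <- suppressWarnings(run_aerial_pipeline(cfg))
  expect_identical(aa$aicc_table, bb$aicc_table)
  expect_identical(aa$n_hat, bb$n_hat)
})

test_that("pipeline errors surface with their stage name", {
  tabs <- make_fixture_tables()
  tabs$B <- tabs$B[0, ]
  expect_error(run_satellite_pipeline(run_config(), observer_tables = tabs),
               "stage 'fit'.*unidentifiable")
  # a single transect surfaces the encounter-variance error
  set.seed(1)
  s <- as_sightings(runif(30, 0, 2000), transect_id = 1)
  tr <- data.frame(transect_id = 1, stratum = "Rowley", length_km = 150)
  expect_error(
    suppressWarnings(run_aerial_pipeline(run_config(seed = 2),
                                         sightings = s, transects = tr,
                                         area_km2 = 1100)),
    "single transect")
})

test_that("aerial pipeline averages injected per-model rows", {
  pre <- data.frame(model = c("Uniform/Cosine", "Half-normal/None",
                              "Half-normal/VIS", "Half-normal/LIGHT",
                              "Hazard/None"),
                    n_hat = c(97, 104, 105, 108, 100),
                    se = c(17.8, 21.0, 21.3, 22.1, 22.5),
                    delta_aicc = c(0, 0.15, 1.12, 1.38, 2.62))
  rep <- run_aerial_pipeline(run_config(seed = 1), precomputed = pre)
  expect_equal(round_half_up(rep$n_hat), 102)
  expect_equal(round_half_up(rep$ci[2]), 152)
  expect_equal(round_half_up(rep$ci[1]), 69)
})

test_that("aerial pipeline fits the candidate set end to end", {
  cfg <- run_config(seed = 11, scene = list(n_rocks = 0, n_ephemeral = 0))
  rep <- suppressWarnings(run_aerial_pipeline(cfg))
  expect_s3_class(rep, "aerial_report")
  expect_true(rep$precheck$cds_permissible)
  expect_gte(nrow(rep$aicc_table), 3)
  expect_equal(min(rep$aicc_table$delta_aicc), 0)
  expect_true(all(rep$aicc_table$p <= 1 + 1e-9))
  expect_gte(rep$n_hat, min(rep$average$members$n_hat) - 1e-9)
  expect_lte(rep$n_hat, max(rep$average$members$n_hat) + 1e-9)
})

test_that("the half-normal model is retained when it generated the data", {
  R <- 60
  hits <- 0
  for (r in seq_len(R)) {
    cfg <- run_config(seed = 3000 + r,
                      scene = list(n_rocks = 0, n_ephemeral = 0))
    rep <- tryCatch(suppressWarnings(run_aerial_pipeline(cfg)),
                    error = function(e) NULL)
    if (is.null(rep)) next
    mem <- rep$average$members
    if (any(grepl("Half-normal", mem$model) & mem$included)) hits <- hits + 1
  }
  expect_gte(hits / R, 0.9)
})

test_that("estimate comparison reports overlap and precision ordering", {
  sat <- run_satellite_pipeline(run_config(seed = 5),
                                observer_tables = make_fixture_tables())
  pre <- data.frame(n_hat = c(97, 104, 105, 108, 100),
                    se = c(17.8, 21.0, 21.3, 22.1, 22.5),
                    delta_aicc = c(0, 0.15, 1.12, 1.38, 2.62))
  aer <- run_aerial_pipeline(run_config(seed = 5), precomputed = pre)
  cmp <- compare_estimates(sat, aer)
  expect_true(cmp$ci_overlap)
  expect_gt(cmp$cv_ratio, 1)
  # identical reports give CV ratio one
  expect_equal(compare_estimates(sat, sat)$cv_ratio, 1)
})
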