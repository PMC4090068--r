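test_that("uniform data under the bare uniform key give mu = w, p = 1", {
  set.seed(1)
  obs <- as_sightings(runif(80, 0, 2300))
  fit <- fit_detection(obs, detection_spec("uniform", truncation_m = 2300))
  expect_equal(fit$esw_m, 2300)
  expect_equal(fit$p, 1)
  expect_equal(fit$K, 0)
  expect_equal(fit$logLik, -80 * log(2300))
})

test_that("half-normal ESW by quadrature matches the closed form", {
  # sigma = 1000 m, w = 2300 m: mu = sigma sqrt(pi/2) erf(w / sigma sqrt(2))
  spec <- detection_spec("halfnormal", truncation_m = 2300)
  mu_quad <- polarcensus:::esw_integral(log(1000), spec, sigma = 1000)
  expect_equal(mu_quad, esw_halfnormal_closed(1000, 2300), tolerance = 1e-6)
  expect_equal(mu_quad, 1226.4, tolerance = 1e-3)
  for (s in c(200, 500, 800, 1500, 5000)) {
    expect_lt(abs(polarcensus:::esw_integral(log(s), spec, sigma = s) -
                    esw_halfnormal_closed(s, 2300)), 0.1)
  }
})

test_that("half-normal fit recovers the generating scale", {
  set.seed(2)
  obs <- as_sightings(rhalfnorm_trunc(5000, 800, 2300))
  fit <- fit_detection(obs, detection_spec("halfnormal", truncation_m = 2300))
  sigma_hat <- exp(fit$theta[1])
  se_sigma <- sigma_hat * sqrt(fit$vcov[1, 1])  # delta method on log scale
  expect_lt(abs(sigma_hat - 800), 2 * se_sigma)
  expect_lt(abs(sigma_hat - 800), 40)
  expect_equal(fit$esw_m, esw_halfnormal_closed(sigma_hat, 2300),
               tolerance = 1e-4)
})

test_that("hazard-rate fit recovers its parameters and respects b >= 1", {
  set.seed(3)
  w <- 2300
  # sample from a hazard-rate detection function by rejection
  g <- function(x) 1 - exp(-(x / 800)^(-2.5))
  x <- numeric(0)
  while (length(x) < 2000) {
    cand <- runif(5000, 0, w)
    x <- c(x, cand[runif(5000) < g(cand)])
  }
  obs <- as_sightings(x[1:2000])
  fit <- fit_detection(obs, detection_spec("hazard", truncation_m = w))
  b_hat <- 1 + exp(fit$theta[2])
  expect_gt(b_hat, 1)
  expect_equal(exp(fit$theta[1]), 800, tolerance = 0.15)
  expect_equal(b_hat, 2.5, tolerance = 0.2)
})

test_that("cosine-adjusted uniform key fits a humped distance distribution", {
  set.seed(4)
  w <- 2300
  x <- rhalfnorm_trunc(400, 900, w)
  fit <- suppressWarnings(select_cosine_adjustments(as_sightings(x), w))
  expect_gt(fit$K, 0)  # adjustments were selected for non-uniform data
  expect_lt(fit$esw_m, w)
  expect_true(fit$p > 0 && fit$p <= 1)
})

test_that("fitted density integrates to one for every key", {
  set.seed(5)
  w <- 2300
  x <- rhalfnorm_trunc(300, 800, w)
  fits <- list(
    fit_detection(as_sightings(x), detection_spec("halfnormal",
                                                  truncation_m = w)),
    fit_detection(as_sightings(x), detection_spec("hazard",
                                                  truncation_m = w)),
    suppressWarnings(fit_detection(as_sightings(x),
      detection_spec("uniform", adjustment = 1:2, truncation_m = w))))
  for (fit in fits) {
    ftail <- polarcensus:::fitted_cdf(fit, w)
    expect_equal(ftail, 1, tolerance = 1e-4)
  }
})

test_that("ESW is nondecreasing in sigma and p never exceeds one", {
  w <- 2300
  hn <- detection_spec("halfnormal", truncation_m = w)
  hz <- detection_spec("hazard", truncation_m = w)
  sig <- c(100, 300, 800, 2000, 8000)
  mu_hn <- vapply(sig, function(s)
    polarcensus:::esw_integral(log(s), hn, sigma = s), 0)
  mu_hz <- vapply(sig, function(s)
    polarcensus:::esw_integral(c(log(s), log(1.5)), hz, sigma = s), 0)
  expect_true(all(diff(mu_hn) > 0))
  expect_true(all(diff(mu_hz) > 0))
  expect_true(all(mu_hn / w <= 1 & mu_hn > 0))
  expect_true(all(mu_hz / w <= 1 + 1e-9 & mu_hz > 0))
})

test_that("covariate models estimate class-specific scales", {
  set.seed(6)
  w <- 2300
  # visibility truly halves the detection scale
  n_per <- 600
  x_good <- rhalfnorm_trunc(n_per, 1000, w)
  x_poor <- rhalfnorm_trunc(n_per, 500, w)
  obs <- rbind(as_sightings(x_good), as_sightings(x_poor))
  obs$vis <- rep(c("excellent", "poor/fair"), each = n_per)
  fit <- fit_detection(obs, detection_spec("halfnormal", covariates = "vis",
                                           truncation_m = w))
  expect_equal(fit$K, 2)
  sig <- sort(unique(fit$sigma_i))
  expect_equal(sig[1], 500, tolerance = 0.12)
  expect_equal(sig[2], 1000, tolerance = 0.12)
  expect_true(all(fit$p_i > 0 & fit$p_i <= 1))
})

test_that("sparse data are rejected and small samples warned about", {
  expect_error(fit_detection(as_sightings(runif(5, 0, 100)),
                             detection_spec("halfnormal",
                                            truncation_m = 2300)),
               "at least 10")
  set.seed(7)
  expect_warning(fit_detection(as_sightings(rhalfnorm_trunc(15, 800, 2300)),
                               detection_spec("halfnormal",
                                              truncation_m = 2300)),
                 "fewer than 20")
})
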