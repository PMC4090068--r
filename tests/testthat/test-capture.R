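test_that("capture summary validates its counts", {
  s <- capture_summary(90, 40, 38)
  expect_equal(s$M_t1, 92)
  expect_error(capture_summary(5, 4, 5), "exceed")
  expect_error(capture_summary(-1, 4, 0), "nonnegative")
})

test_that("identical tables match completely; distant tables not at all", {
  pts <- data.frame(point_id = paste0("p", 1:8), observer = "A",
                    x_m = seq(0, 7000, by = 1000), y_m = 0)
  ptsB <- transform(pts, point_id = paste0("q", 1:8), observer = "B")
  mo <- match_observer_points(pts, ptsB)
  expect_equal(mo$summary$m, 8)
  expect_true(all(mo$histories$h == "11"))

  far <- transform(ptsB, y_m = 500)  # all pairwise distances > 30 m
  mo2 <- match_observer_points(pts, far)
  expect_equal(mo2$summary$m, 0)
  expect_false(any(mo2$histories$h == "11"))
})

test_that("duplicate point ids are rejected", {
  bad <- data.frame(point_id = c("p1", "p1"), x_m = c(0, 10), y_m = c(0, 0))
  ok <- data.frame(point_id = "q1", x_m = 0, y_m = 0)
  expect_error(match_observer_points(bad, ok), "duplicate")
})

test_that("matching recovers the simulator's true joint detections", {
  for (seed in c(11, 12, 13)) {
    sc <- generate_scene(sim_config(n_bears = 94, n_rocks = 0,
                                    n_ephemeral = 0, seed = seed))
    obs <- simulate_observers(sc)
    mo <- match_observer_points(obs$A, obs$B)
    m_truth <- length(intersect(obs$A$true_id, obs$B$true_id))
    expect_equal(mo$summary$m, m_truth)
    expect_equal(mo$summary$n1, nrow(obs$A))
    expect_equal(mo$summary$n2, nrow(obs$B))
  }
})

test_that("closed-population fit reproduces the worked example", {
  fit <- fit_closed_mt(capture_summary(90, 40, 38))
  expect_equal(fit$N_hat, 94)
  expect_gte(fit$N_hat, fit$summary$M_t1)
  expect_gte(fit$ci[1], fit$summary$M_t1)
  expect_lte(fit$ci[1], fit$N_hat)
  expect_lte(fit$N_hat, fit$ci[2])
  expect_equal(round_half_up(fit$ci[2]), 105)
  expect_true(fit$p1_hat > 0 && fit$p1_hat <= 1)
})

test_that("degenerate complete-overlap data give N = M with p = 1", {
  fit <- fit_closed_mt(capture_summary(7, 7, 7))
  expect_equal(fit$N_hat, 7)
  expect_equal(fit$N_hat_continuous, 7)
  expect_equal(fit$p1_hat, 1)
  expect_equal(fit$ci, c(7, 7))
})

test_that("no duplicates means unidentifiable abundance", {
  expect_error(fit_closed_mt(capture_summary(6, 4, 0)), "unidentifiable")
})

test_that("integer MLE agrees with the exhaustive multinomial grid oracle", {
  # frozen small case computed from the oracle (not Lincoln-Petersen)
  expect_equal(mt_mle_grid_oracle(6, 4, 2), 10)
  expect_equal(fit_closed_mt(capture_summary(6, 4, 2))$N_hat, 10)
  set.seed(42)
  for (i in 1:200) {
    n1 <- sample(3:120, 1)
    n2 <- sample(3:120, 1)
    m <- sample(seq_len(min(n1, n2)), 1)
    expect_equal(fit_closed_mt(capture_summary(n1, n2, m))$N_hat,
                 mt_mle_grid_oracle(n1, n2, m),
                 info = sprintf("n1=%d n2=%d m=%d", n1, n2, m))
  }
})

test_that("integer MLE is bracketed by the distinct count and Lincoln-Petersen", {
  set.seed(7)
  for (i in 1:100) {
    N <- sample(50:200, 1)
    p1 <- runif(1, 0.3, 0.95); p2 <- runif(1, 0.3, 0.95)
    d1 <- rbinom(N, 1, p1); d2 <- rbinom(N, 1, p2)
    s <- capture_summary(sum(d1), sum(d2), sum(d1 & d2))
    if (s$m < 1) next
    fit <- fit_closed_mt(s)
    lp <- lincoln_petersen(s)$estimate
    expect_gte(fit$N_hat, s$M_t1)
    expect_lte(fit$N_hat, ceiling(lp))
    expect_lte(fit$N_hat_continuous, lp + 1e-6)
  }
})

test_that("closed-form estimators match hand arithmetic", {
  s <- capture_summary(90, 40, 38)
  lp <- lincoln_petersen(s)
  expect_equal(lp$estimate, 90 * 40 / 38)
  expect_equal(lp$variance, 90 * 40 * 52 * 2 / 38^3)
  expect_equal(chapman(capture_summary(6, 4, 2))$estimate, 7 * 5 / 3 - 1)
  k <- capture_summary(12, 12, 12)
  expect_equal(lincoln_petersen(k)$estimate, 12)
  expect_equal(lincoln_petersen(k)$variance, 0)
  expect_error(lincoln_petersen(capture_summary(5, 3, 0)), "m >= 1")
})

test_that("lognormal f0 interval matches hand arithmetic and edge cases", {
  # hand: f0 = 2.7368, var = 6.8232 -> C = 4.8417, upper = 105.25
  ci <- lognormal_f0_ci(2.736842, 6.823152, 92)
  C <- exp(1.96 * sqrt(log(1 + 6.823152 / 2.736842^2)))
  expect_equal(ci[2], 92 + 2.736842 * C, tolerance = 1e-4)
  expect_equal(C, 4.84, tolerance = 0.01)
  expect_equal(lognormal_f0_ci(0, 0, 92), c(92, 92))
  expect_equal(lognormal_f0_ci(3, 0, 92), c(95, 95))
  expect_error(lognormal_f0_ci(2, -1, 92), "nonnegative")
})

test_that("observer detection report gives conditional percentages", {
  s <- capture_summary(90, 40, 38)
  rep <- observer_detection_report(s, fit_closed_mt(s))
  expect_equal(rep$p_conditional_pct[rep$observer == "B"], 42L)
  expect_equal(rep$p_conditional_pct[rep$observer == "A"], 95L)
  k <- capture_summary(9, 9, 9)
  repk <- observer_detection_report(k)
  expect_equal(repk$p_conditional_pct, c(100L, 100L))
  s2 <- capture_summary(6, 4, 2)
  rep2 <- observer_detection_report(s2)
  expect_equal(rep2$p_conditional_pct, c(50L, 33L))
})
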