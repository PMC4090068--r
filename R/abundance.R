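#' Stratum abundance from a fitted detection function
#'
#' Horvitz-Thompson-style line-transect estimate restricted to one stratum:
#' group density \eqn{D = n / (2 \mu L)} (with \eqn{\mu} in km), abundance
#' \eqn{\hat N = D \cdot A \cdot \bar s} for independent individuals. The
#' detection function is typically fitted to data pooled across strata while
#' encounter rate and group size come from the target stratum. For covariate
#' models the group density is \eqn{\sum_i (1/p_i) / (2 w L)} over the
#' stratum's observations.
#'
#' Variance combines three components on the CV scale,
#' \eqn{CV(\hat N)^2 = CV(n/L)^2 + CV(\mu)^2 + CV(\bar s)^2}, with the
#' encounter-rate variance from length-weighted between-transect replication
#' (the replicate-lines estimator
#' \eqn{\widehat{var}(n/L) = \frac{K}{L^2 (K-1)} \sum_k l_k^2 (n_k/l_k -
#' n/L)^2}). The interval on \eqn{\hat N} is lognormal.
#'
#' @param fit a [fit_detection()] result (pooled data).
#' @param observations sightings data.frame (`transect_id, stratum,
#'   perp_distance_m, group_size`, plus covariates when used).
#' @param transects transect data.frame (`transect_id, stratum, length_km`).
#' @param stratum stratum label to estimate.
#' @param area_km2 stratum area A, km2.
#' @param cv_encounter_override optional encounter-rate CV, required when the
#'   stratum has a single transect (between-transect variance undefined).
#' @param alpha two-sided error rate.
#' @return object of class `abundance_estimate`: `stratum`, `n_groups`,
#'   `length_km`, `area_km2`, `density_groups_km2`, `mean_group_size`,
#'   `n_hat`, `se`, `cv`, `ci`, `cv_components`, `model_label`,
#'   `undefined_cv` flag.
#' @export
estimate_abundance <- function(fit, observations, transects, stratum,
                               area_km2, cv_encounter_override = NULL,
                               alpha = 0.05) {
  stopifnot(inherits(fit, "detection_fit"))
  w_km <- m_to_km(fit$spec$truncation_m)
  tr <- transects[transects$stratum == stratum, , drop = FALSE]
  if (nrow(tr) == 0) fail_input("no transects in stratum ", stratum)
  L <- sum(tr$length_km)
  obs <- observations[observations$stratum == stratum &
                        observations$perp_distance_m <= fit$spec$truncation_m, ,
                      drop = FALSE]
  n <- nrow(obs)

  if (n == 0) {
    est <- structure(list(stratum = stratum, n_groups = 0L, length_km = L,
                          area_km2 = area_km2, density_groups_km2 = 0,
                          mean_group_size = NA_real_, n_hat = 0,
                          se = NA_real_, cv = NA_real_, ci = c(0, 0),
                          cv_components = c(encounter = NA, esw = NA,
                                            group_size = NA),
                          model_label = fit$label, undefined_cv = TRUE),
                     class = "abundance_estimate")
    warning("no observations in stratum; abundance 0 with undefined CV")
    return(est)
  }

  mu_km <- m_to_km(fit$esw_m)
  has_cov <- length(fit$spec$covariates) > 0
  if (has_cov) {
    # per-observation detection probabilities for the stratum's rows
    sub_fit <- fit
    Xs <- scale_design(obs, fit$spec$covariates)
    nbeta <- ncol(Xs)
    sig <- as.vector(exp(Xs %*% fit$theta[seq_len(nbeta)]))
    us <- unique(sig)
    mu_u <- vapply(us, function(s) esw_integral(fit$theta, fit$spec, s), 0)
    p_i <- mu_u[match(sig, us)] / fit$spec$truncation_m
    D_groups <- sum(1 / p_i) / (2 * w_km * L)
  } else {
    D_groups <- n / (2 * mu_km * L)
  }

  s_bar <- mean(obs$group_size)
  n_hat <- D_groups * area_km2 * s_bar

  # encounter-rate variance from between-transect replication
  K <- nrow(tr)
  n_k <- as.numeric(table(factor(obs$transect_id,
                                 levels = tr$transect_id)))
  er <- n / L
  if (!is.null(cv_encounter_override)) {
    cv_er <- cv_encounter_override
  } else if (K < 2) {
    fail_input("encounter-rate variance undefined with a single transect; ",
               "supply cv_encounter_override")
  } else {
    var_er <- K / (L^2 * (K - 1)) *
      sum(tr$length_km^2 * (n_k / tr$length_km - er)^2)
    cv_er <- sqrt(var_er) / er
  }
  cv_mu <- if (is.finite(fit$se_esw_m)) fit$se_esw_m / fit$esw_m else NA_real_
  cv_s <- if (n > 1) sd(obs$group_size) / (s_bar * sqrt(n)) else 0
  cv_n <- sqrt(cv_er^2 + cv_mu^2 + cv_s^2)
  se <- cv_n * n_hat
  ci <- lognormal_ci(n_hat, cv_n, alpha)

  structure(list(stratum = stratum, n_groups = n, length_km = L,
                 area_km2 = area_km2, density_groups_km2 = D_groups,
                 mean_group_size = s_bar, n_hat = n_hat, se = se, cv = cv_n,
                 ci = ci,
                 cv_components = c(encounter = cv_er, esw = cv_mu,
                                   group_size = cv_s),
                 model_label = fit$label, undefined_cv = FALSE),
            class = "abundance_estimate")
}

#' @export
print.abundance_estimate <- function(x, ...) {
  cat(sprintf("Abundance (%s, %s): %.1f independent bears\n",
              x$stratum, x$model_label, x$n_hat))
  cat(sprintf("  n = %d groups over %.1f km; D = %.4f groups/km2; s-bar = %.2f\n",
              x$n_groups, x$length_km, x$density_groups_km2,
              x$mean_group_size))
  if (!x$undefined_cv)
    cat(sprintf("  SE %.1f (CV %.1f%%); 95%% CI (%.1f, %.1f)\n",
                x$se, 100 * x$cv, x$ci[1], x$ci[2]))
  invisible(x)
}
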