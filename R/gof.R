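# Asymptotic upper tail of the Cramer-von Mises statistic (Csorgo & Faraway
# series via modified Bessel functions; terms are added until they vanish).
# Written here because no installed package exposes this distribution; the
# test suite checks it against a Monte-Carlo oracle.
pcvm_asymptotic <- function(q, lower_tail = FALSE) {
  cdf_one <- function(x) {
    if (x <= 0) return(0)
    tot <- 0
    for (j in 0:12) {
      z <- (4 * j + 1)^2 / (16 * x)
      term <- exp(lgamma(j + 0.5) - lgamma(0.5) - lgamma(j + 1)) *
        sqrt(4 * j + 1) * besselK(z, 0.25, expon.scaled = TRUE) * exp(-2 * z)
      tot <- tot + term
      if (term < 1e-12 * max(tot, 1e-300)) break
    }
    min(max(tot / (pi * sqrt(x)), 0), 1)
  }
  p <- vapply(q, cdf_one, 0)
  if (lower_tail) p else 1 - p
}

#' Goodness of fit of a detection function
#'
#' Three tests of the fitted distance distribution \eqn{F(x) = \int_0^x
#' g/\mu}: a chi-squared test on equal-width distance bins (adjacent bins
#' merged until every expected count is at least 5, degrees of freedom
#' reduced by the number of estimated parameters), a Kolmogorov-Smirnov test
#' and a Cramer-von Mises test on the probability-integral transforms
#' \eqn{u_i = F_i(x_i)}.
#'
#' @param fit a [fit_detection()] result (or any object providing the same
#'   interface).
#' @param observations optional data.frame of distances to test; defaults to
#'   the data the model was fitted to.
#' @param n_bins initial number of equal-width bins (default 10).
#' @param params_estimated if `TRUE` (default) the chi-squared degrees of
#'   freedom are reduced by `fit$K`; set `FALSE` when the tested parameters
#'   were not estimated from these data.
#' @return list with `chisq_p`, `ks_p`, `cvm_p` and the underlying
#'   statistics (`chisq_stat`, `chisq_df`, `ks_stat`, `cvm_stat`). The
#'   chi-squared entry is `NA` with a warning when fewer than 2 usable bins
#'   remain.
#' @export
goodness_of_fit <- function(fit, observations = NULL, n_bins = 10,
                            params_estimated = TRUE) {
  obs <- if (is.null(observations)) fit$data else observations
  w <- fit$spec$truncation_m
  obs <- obs[obs$perp_distance_m >= 0 & obs$perp_distance_m <= w, ,
             drop = FALSE]
  x <- obs$perp_distance_m
  n <- length(x)
  has_cov <- !is.null(fit$sigma_i) && length(fit$spec$covariates) > 0

  u <- if (has_cov && is.null(observations)) {
    vapply(seq_len(n), function(i) fitted_cdf(fit, x[i], row = i), 0)
  } else fitted_cdf(fit, x)

  # chi-squared on equal-width distance bins
  brks <- seq(0, w, length.out = n_bins + 1)
  cdf_at <- if (has_cov && is.null(observations)) {
    sapply(seq_len(n), function(i) fitted_cdf(fit, brks, row = i))
  } else matrix(fitted_cdf(fit, brks), ncol = 1)[, rep(1, n), drop = FALSE]
  expected <- rowSums(cdf_at[-1, , drop = FALSE] -
                        cdf_at[-(n_bins + 1), , drop = FALSE])
  observed <- tabulate(findInterval(x, brks, rightmost.closed = TRUE),
                       nbins = n_bins)
  # merge adjacent bins left to right until expected >= 5
  eo <- cbind(expected, observed)
  i <- 1
  while (i <= nrow(eo)) {
    if (eo[i, 1] < 5 && nrow(eo) > 1) {
      j <- if (i < nrow(eo)) i + 1 else i - 1
      eo[j, ] <- eo[j, ] + eo[i, ]
      eo <- eo[-i, , drop = FALSE]
      i <- max(1, i - 1)
    } else i <- i + 1
  }
  K <- if (params_estimated) fit$K else 0L
  df <- nrow(eo) - 1 - K
  if (nrow(eo) < 2 || df < 1) {
    warning("too few usable bins for the chi-squared test")
    chisq_stat <- NA_real_; chisq_p <- NA_real_; df <- NA_integer_
  } else {
    chisq_stat <- sum((eo[, 2] - eo[, 1])^2 / eo[, 1])
    chisq_p <- pchisq(chisq_stat, df, lower.tail = FALSE)
  }

  ks <- suppressWarnings(ks.test(u, "punif"))
  us <- sort(u)
  cvm_stat <- 1 / (12 * n) + sum((us - (2 * seq_len(n) - 1) / (2 * n))^2)
  cvm_p <- pcvm_asymptotic(cvm_stat)

  list(chisq_p = chisq_p, ks_p = unname(ks$p.value), cvm_p = cvm_p,
       chisq_stat = chisq_stat, chisq_df = df,
       ks_stat = unname(ks$statistic), cvm_stat = cvm_stat)
}
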