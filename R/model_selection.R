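#' Small-sample Akaike information criterion
#'
#' \deqn{AICc = -2\log L + 2K + \frac{2K(K+1)}{n - K - 1}}
#'
#' @param logLik maximised log-likelihood.
#' @param K number of estimated parameters.
#' @param n sample size; must exceed `K + 1`.
#' @return AICc value.
#' @examples
#' aicc(-100, 2, 56)
#' @export
aicc <- function(logLik, K, n) {
  if (n <= K + 1) fail_input("AICc requires n > K + 1")
  -2 * logLik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Akaike differences and weights over a candidate set
#'
#' \eqn{\Delta_i = AICc_i - \min_j AICc_j}; models with \eqn{\Delta_i <}
#' `cutoff` receive weights \eqn{w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}}
#' (normalised over the retained set); the rest are excluded (weight 0).
#'
#' @param aicc_values vector of AICc values (differences work equally, since
#'   only \eqn{\Delta_i} matters).
#' @param cutoff retention threshold on \eqn{\Delta_i} (default 3).
#' @return data.frame with `delta`, `included`, `weight`.
#' @examples
#' akaike_weights(c(0, 0.15, 1.12, 1.38, 2.62))
#' @export
akaike_weights <- function(aicc_values, cutoff = 3) {
  delta <- aicc_values - min(aicc_values)
  included <- delta < cutoff
  raw <- exp(-delta / 2) * included
  data.frame(delta = delta, included = included, weight = raw / sum(raw))
}

#' Model-averaged abundance with unconditional variance
#'
#' Averages member abundance estimates with Akaike weights,
#' \eqn{\bar N = \sum_i w_i \hat N_i}, and combines within-model variance
#' with between-model spread into the unconditional standard error
#' \eqn{SE_u = \sum_i w_i \sqrt{\mathrm{var}_i + (\hat N_i - \bar N)^2}}.
#' The confidence interval is lognormal with \eqn{CV = SE_u / \bar N}.
#'
#' @param estimates either a data.frame with columns `n_hat` and `se` (one
#'   row per model) or a list of [estimate_abundance()] results.
#' @param aicc_values AICc values (or AICc differences) matching the
#'   estimates.
#' @param cutoff models with \eqn{\Delta AICc} at or above this are excluded
#'   (default 3).
#' @param labels optional model labels.
#' @param alpha two-sided error rate.
#' @return object of class `model_average`: `n_bar`, `se_unconditional`,
#'   `cv`, `ci`, and `members` (data.frame of member estimates, deltas and
#'   weights).
#' @examples
#' model_average(data.frame(n_hat = c(97, 104, 105, 108, 100),
#'                          se = c(17.8, 21.0, 21.3, 22.1, 22.5)),
#'               c(0, 0.15, 1.12, 1.38, 2.62))
#' @export
model_average <- function(estimates, aicc_values, cutoff = 3, labels = NULL,
                          alpha = 0.05) {
  if (is.list(estimates) && !is.data.frame(estimates) &&
      all(vapply(estimates, inherits, TRUE, "abundance_estimate"))) {
    if (is.null(labels))
      labels <- vapply(estimates, function(e) e$model_label, "")
    estimates <- data.frame(
      n_hat = vapply(estimates, function(e) e$n_hat, 0),
      se = vapply(estimates, function(e) e$se, 0))
  }
  if (!all(c("n_hat", "se") %in% names(estimates)))
    fail_input("estimates must provide n_hat and se")
  if (nrow(estimates) == 0) fail_input("empty candidate set")
  if (nrow(estimates) != length(aicc_values))
    fail_input("one AICc value per estimate is required")
  wt <- akaike_weights(aicc_values, cutoff)
  if (!any(wt$included)) fail_input("no model below the delta-AICc cutoff")
  w <- wt$weight
  n_bar <- sum(w * estimates$n_hat)
  se_u <- sum(w * sqrt(estimates$se^2 + (estimates$n_hat - n_bar)^2))
  cv <- se_u / n_bar
  ci <- lognormal_ci(n_bar, cv, alpha)
  members <- data.frame(
    model = if (is.null(labels)) paste0("model_", seq_len(nrow(estimates)))
            else labels,
    n_hat = estimates$n_hat, se = estimates$se,
    delta_aicc = wt$delta, included = wt$included, weight = w)
  structure(list(n_bar = n_bar, se_unconditional = se_u, cv = cv, ci = ci,
                 members = members, alpha = alpha),
            class = "model_average")
}

#' @export
print.model_average <- function(x, ...) {
  cat(sprintf("Model-averaged abundance: %.1f (SE %.1f, CV %.1f%%), 95%% CI (%.1f, %.1f)\n",
              x$n_bar, x$se_unconditional, 100 * x$cv, x$ci[1], x$ci[2]))
  print(x$members, row.names = FALSE, digits = 4)
  invisible(x)
}
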