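#' @importFrom stats optimize optim optimHess integrate runif rnorm rbinom
#'   pnorm pchisq qnorm quantile ks.test sd median rmultinom
#' @importFrom utils read.csv write.csv head
NULL

# meters <-> kilometers; every unit conversion in the package goes through
# these two helpers so the convention (distances m, lengths km, areas km2)
# lives in one place.
m_to_km <- function(x) x / 1000
km_to_m <- function(x) x * 1000

#' Round half away from zero
#'
#' Reported integer estimates use commercial rounding (round half away from
#' zero) rather than IEEE round-half-even, so 105.5 reports as 106.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# Derive a deterministic sub-stream seed from a master seed and an integer
# offset. Kept strictly below 2^31 - 1. A single master seed therefore fixes
# every random draw the package makes.
derive_seed <- function(seed, offset) {
  ((abs(as.numeric(seed)) %% 1e6) * 2039 + abs(offset) * 7919) %% 2147483646 + 1
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# state (delegates to withr).
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

#' Two-sided lognormal confidence interval from an estimate and its CV
#'
#' The interval convention used throughout distance sampling: with
#' \eqn{C = \exp(z \sqrt{\ln(1 + CV^2)})}, the interval is
#' \eqn{(\hat N / C,\; \hat N \cdot C)}.
#'
#' @param estimate positive point estimate.
#' @param cv coefficient of variation (SE / estimate).
#' @param alpha two-sided error rate (default 0.05).
#' @return numeric length-2 vector `c(low, high)`.
#' @export
lognormal_ci <- function(estimate, cv, alpha = 0.05) {
  if (!is.finite(cv) || cv < 0) stop("cv must be a nonnegative finite number")
  if (estimate <= 0) return(c(0, 0))
  z <- qnorm(1 - alpha / 2)
  C <- exp(z * sqrt(log(1 + cv^2)))
  c(estimate / C, estimate * C)
}

# stop() with a consistent prefix used by the validators
fail_input <- function(...) stop(..., call. = FALSE)
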