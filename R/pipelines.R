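#' Run the satellite census pipeline
#'
#' End to end: observer point tables (read from files, passed in memory, or
#' simulated from a synthetic scene) are matched into two-occasion capture
#' histories; the closed-population M_t model with observer-specific
#' detection is fitted; abundance, detection probabilities and the lognormal
#' f0 interval are reported. Every applied parameter and the seed are
#' recorded in the report's `log`, so a run is auditable without its config
#' file.
#'
#' @param config a [run_config()].
#' @param observer_tables optional list with data.frames `A` and `B`
#'   (columns `point_id, x_m, y_m`); when `NULL`, tables are simulated from
#'   a synthetic scene under the config.
#' @return object of class `satellite_report`: `summary`, `fit`, `n_hat`,
#'   `ci`, `cv`, `detection` (observer report), `log`.
#' @export
run_satellite_pipeline <- function(config = run_config(),
                                   observer_tables = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- "input"
  res <- tryCatch({
    if (is.null(observer_tables)) {
      stage <- "simulate"
      sc <- generate_scene(sim_config(
        island_area_km2 = config$scene$island_area_km2,
        island_aspect = config$scene$island_aspect,
        n_bears = config$scene$n_bears,
        n_rocks = config$scene$n_rocks,
        n_ephemeral = config$scene$n_ephemeral,
        mean_group_size = config$scene$mean_group_size,
        min_sep_m = config$scene$min_sep_m,
        obs_probs = config$satellite$obs_probs,
        jitter_max_m = config$satellite$jitter_max_m,
        seed = config$seed))
      observer_tables <- joint_review(simulate_observers(sc))
    }
    stage <- "match"
    mo <- match_observer_points(observer_tables$A, observer_tables$B,
                                config$satellite$match_radius_m)
    stage <- "fit"
    fit <- fit_closed_mt(mo$summary)
    stage <- "report"
    det <- observer_detection_report(mo$summary, fit)
    structure(list(summary = mo$summary, fit = fit,
                   n_hat = fit$N_hat, ci = fit$ci, cv = fit$cv,
                   detection = det,
                   log = list(seed = config$seed,
                              match_radius_m = config$satellite$match_radius_m,
                              obs_probs = config$satellite$obs_probs,
                              n1 = mo$summary$n1, n2 = mo$summary$n2,
                              m = mo$summary$m, M_t1 = mo$summary$M_t1)),
              class = "satellite_report")
  }, error = function(e) {
    stop("satellite pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  res
}

#' @export
print.satellite_report <- function(x, ...) {
  cat("== Satellite census ==\n")
  print(x$summary)
  print(x$fit)
  invisible(x)
}

# candidate detection-function set of the aerial analysis
aerial_model_set <- function(sightings, w) {
  fits <- list()
  fits[["Uniform/Cosine"]] <- function()
    select_cosine_adjustments(sightings, w)
  fits[["Half-normal/None"]] <- function()
    fit_detection(sightings, detection_spec("halfnormal", truncation_m = w))
  fits[["Half-normal/VIS"]] <- function()
    fit_detection(sightings, detection_spec("halfnormal", covariates = "vis",
                                            truncation_m = w))
  fits[["Half-normal/LIGHT"]] <- function()
    fit_detection(sightings, detection_spec("halfnormal",
                                            covariates = "light",
                                            truncation_m = w))
  fits[["Hazard/None"]] <- function()
    fit_detection(sightings, detection_spec("hazard", truncation_m = w))
  fits
}

#' Run the aerial line-transect pipeline
#'
#' Huggins double-observer pre-check of perfect detection on the line, then
#' the candidate detection-function set (uniform+cosine, half-normal,
#' half-normal with VIS or LIGHT scale covariates, hazard-rate) fitted to
#' the pooled sightings, an AICc table, a stratum abundance estimate per
#' model, and the Akaike-weighted model average (models with
#' \eqn{\Delta AICc} below the cutoff) with unconditional variance.
#'
#' Alternatively, `precomputed` supplies per-model rows
#' (`n_hat, se, delta_aicc`) from an external analysis, in which case only
#' the averaging stage runs.
#'
#' @param config a [run_config()].
#' @param sightings,transects survey tables (see [read_sightings()]); when
#'   `NULL`, a synthetic survey is simulated under the config.
#' @param double_observer optional conditional double-observer records for
#'   the pre-check; simulated when `NULL` and the survey is synthetic.
#' @param stratum stratum to estimate (default `"Rowley"`).
#' @param area_km2 stratum area; defaults to the scene area.
#' @param precomputed optional data.frame `n_hat, se, delta_aicc` (and
#'   optionally `model`) replacing the fitting stages.
#' @return object of class `aerial_report`: `precheck`, `aicc_table`,
#'   `fits`, `estimates`, `average`, `n_hat`, `ci`, `cv`, `log`.
#' @export
run_aerial_pipeline <- function(config = run_config(), sightings = NULL,
                                transects = NULL, double_observer = NULL,
                                stratum = "Rowley", area_km2 = NULL,
                                precomputed = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- "input"
  tryCatch({
    if (!is.null(precomputed)) {
      stage <- "average"
      avg <- model_average(precomputed[, c("n_hat", "se")],
                           precomputed$delta_aicc,
                           cutoff = config$aerial$aicc_cutoff,
                           labels = precomputed$model)
      return(structure(list(precheck = NULL, aicc_table = NULL,
                            fits = NULL, estimates = NULL, average = avg,
                            n_hat = avg$n_bar, ci = avg$ci, cv = avg$cv,
                            log = list(seed = config$seed,
                                       mode = "precomputed",
                                       cutoff = config$aerial$aicc_cutoff)),
                       class = "aerial_report"))
    }
    if (is.null(sightings)) {
      stage <- "simulate"
      sc <- generate_scene(sim_config(
        island_area_km2 = config$scene$island_area_km2,
        island_aspect = config$scene$island_aspect,
        n_bears = config$scene$n_bears,
        n_rocks = 0, n_ephemeral = 0,
        mean_group_size = config$scene$mean_group_size,
        min_sep_m = config$scene$min_sep_m,
        aerial_sigma_m = config$aerial$sigma_m,
        truncation_m = config$aerial$truncation_m,
        transect_spacing_km = config$aerial$transect_spacing_km,
        seed = config$seed))
      sv <- simulate_line_transect(sc, stratum = stratum)
      sightings <- sv$sightings
      transects <- sv$transects
      if (is.null(area_km2)) area_km2 <- sc$area_km2
    }
    if (is.null(area_km2)) fail_input("area_km2 is required")
    w <- config$aerial$truncation_m

    stage <- "huggins precheck"
    if (is.null(double_observer))
      double_observer <- simulate_double_observer(
        max(nrow(sightings), 20), config$aerial$huggins_p_front,
        config$aerial$huggins_p_rear, seed = derive_seed(config$seed, 5))
    precheck <- check_perfect_detection(
      fit_huggins_double_observer(double_observer))

    stage <- "detection fitting"
    diag <- character(0)
    fits <- list()
    for (nm in names(aerial_model_set(sightings, w))) {
      f <- tryCatch(aerial_model_set(sightings, w)[[nm]](),
                    error = function(e) conditionMessage(e))
      if (inherits(f, "detection_fit")) fits[[nm]] <- f
      else diag <- c(diag, paste0(nm, ": ", f))
    }
    if (length(fits) == 0)
      fail_input("all detection models failed:\n  ",
                 paste(diag, collapse = "\n  "))

    stage <- "abundance"
    # models whose variance could not be stabilised are dropped with a note
    usable <- vapply(fits, function(f) is.finite(f$se_esw_m), TRUE)
    diag <- c(diag, paste0(names(fits)[!usable], ": unstable ESW variance"))
    fits <- fits[usable]
    if (length(fits) == 0)
      fail_input("all detection models failed:\n  ",
                 paste(diag, collapse = "\n  "))
    aiccs <- vapply(fits, function(f) aicc(f$logLik, f$K, f$n), 0)
    estimates <- lapply(fits, estimate_abundance, observations = sightings,
                        transects = transects, stratum = stratum,
                        area_km2 = area_km2)
    aicc_table <- data.frame(
      model = names(fits),
      delta_aicc = aiccs - min(aiccs),
      esw_m = vapply(fits, function(f) f$esw_m, 0),
      p = vapply(fits, function(f) f$p, 0),
      n_hat = vapply(estimates, function(e) e$n_hat, 0),
      se = vapply(estimates, function(e) e$se, 0),
      row.names = NULL)
    aicc_table <- aicc_table[order(aicc_table$delta_aicc), ]

    stage <- "average"
    avg <- model_average(estimates, aiccs,
                         cutoff = config$aerial$aicc_cutoff,
                         labels = names(fits))
    # when detection was imperfect on the line, scale by 1/p(0)
    inflate <- if (precheck$cds_permissible) 1 else precheck$inflation
    structure(list(precheck = precheck, aicc_table = aicc_table,
                   fits = fits, estimates = estimates, average = avg,
                   n_hat = avg$n_bar * inflate,
                   ci = avg$ci * inflate, cv = avg$cv,
                   log = list(seed = config$seed, truncation_m = w,
                              stratum = stratum, area_km2 = area_km2,
                              cutoff = config$aerial$aicc_cutoff,
                              p0_inflation = inflate,
                              n_sightings = nrow(sightings))),
              class = "aerial_report")
  }, error = function(e) {
    stop("aerial pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
}

#' @export
print.aerial_report <- function(x, ...) {
  cat("== Aerial line-transect survey ==\n")
  if (!is.null(x$precheck)) cat(" ", x$precheck$message, "\n")
  if (!is.null(x$aicc_table)) {
    cat("  AICc table:\n")
    print(x$aicc_table, row.names = FALSE, digits = 4)
  }
  print(x$average)
  invisible(x)
}

#' Compare the satellite and aerial abundance estimates
#'
#' Reports both point estimates with their intervals and CVs, whether the
#' two 95% intervals overlap, and the ratio of the aerial to the satellite
#' CV. No inferential test is performed.
#'
#' @param satellite_report a [run_satellite_pipeline()] result.
#' @param aerial_report a [run_aerial_pipeline()] result.
#' @return object of class `comparison_report`.
#' @export
compare_estimates <- function(satellite_report, aerial_report) {
  s <- satellite_report; a <- aerial_report
  for (r in list(s, a))
    if (!all(c("n_hat", "ci", "cv") %in% names(r)))
      fail_input("reports must carry n_hat, ci and cv")
  overlap <- max(s$ci[1], a$ci[1]) <= min(s$ci[2], a$ci[2])
  structure(list(
    satellite = list(n_hat = s$n_hat, ci = s$ci, cv = s$cv),
    aerial = list(n_hat = a$n_hat, ci = a$ci, cv = a$cv),
    ci_overlap = overlap,
    cv_ratio = a$cv / s$cv), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("== Platform comparison ==\n")
  cat(sprintf("  satellite: %.0f (%.1f - %.1f), CV %.1f%%\n",
              x$satellite$n_hat, x$satellite$ci[1], x$satellite$ci[2],
              100 * x$satellite$cv))
  cat(sprintf("  aerial:    %.0f (%.1f - %.1f), CV %.1f%%\n",
              x$aerial$n_hat, x$aerial$ci[1], x$aerial$ci[2],
              100 * x$aerial$cv))
  cat(sprintf("  CIs overlap: %s; CV ratio (aerial/satellite): %.1f\n",
              x$ci_overlap, x$cv_ratio))
  invisible(x)
}
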