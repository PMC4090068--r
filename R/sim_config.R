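#' Simulation configuration for a synthetic survey scene
#'
#' Bundles every parameter of the synthetic island scene: geometry, true
#' number of independent bears, confuser counts, the two image analysts'
#' detection probabilities, the aerial detection scale, and the random seed.
#' Defaults emulate the study system: a ~1,100 km2 low-relief island holding
#' ~94 independent bears at the end of the ice-free season, reviewed by two
#' analysts with detection probabilities of about 0.96 and 0.42, and flown at
#' 7-km transect spacing with a half-normal aerial detection scale of 800 m
#' (effective strip width ~1.0-1.2 km).
#'
#' @param island_area_km2 island area, km2 (> 0).
#' @param island_aspect ratio of the island's long axis to its short axis.
#' @param n_bears true number of independent-bear groups placed (>= 1).
#' @param n_rocks persistent bright confusers present on every date.
#' @param n_ephemeral ephemeral bright confusers (foam, small floes), each
#'   assigned to a single acquisition date.
#' @param obs_probs length-2 vector of per-bear detection probabilities for
#'   image observers A and B, each in (0, 1].
#' @param aerial_sigma_m half-normal detection scale for the helicopter
#'   survey, meters (> 0).
#' @param truncation_m perpendicular truncation distance, meters.
#' @param transect_spacing_km spacing of parallel transects, km (> 0).
#' @param mean_group_size mean independent-bear group size in [1, 2]; sizes
#'   are drawn as 1 or 2 with P(2) = mean - 1.
#' @param min_sep_m hard-core minimum separation between placed objects,
#'   meters; keeps 2-m objects resolvable and point matching unambiguous.
#' @param jitter_max_m maximum digitization jitter applied to observer
#'   points, meters.
#' @param background_reflectance mean background top-of-atmosphere
#'   reflectance of the rendered scene.
#' @param noise_sd pixel noise standard deviation of rendered rasters
#'   (0 gives noise-free pairs).
#' @param pixel_m rendered pixel size, meters.
#' @param seed master integer seed; all sub-streams derive from it.
#' @return object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_bears = 94, seed = 1)
#' cfg$island_area_km2
#' @export
sim_config <- function(island_area_km2 = 1100,
                       island_aspect = 2.6,
                       n_bears = 94,
                       n_rocks = 200,
                       n_ephemeral = 50,
                       obs_probs = c(0.96, 0.42),
                       aerial_sigma_m = 800,
                       truncation_m = 2300,
                       transect_spacing_km = 7,
                       mean_group_size = 1.03,
                       min_sep_m = 30,
                       jitter_max_m = 5,
                       background_reflectance = 0.08,
                       noise_sd = 0.01,
                       pixel_m = 0.5,
                       seed = 1L) {
  if (!is.numeric(island_area_km2) || island_area_km2 <= 0)
    fail_input("island_area_km2 must be strictly positive")
  if (island_aspect < 1) fail_input("island_aspect must be >= 1")
  if (n_bears < 1 || n_bears != round(n_bears))
    fail_input("n_bears must be a positive integer")
  if (n_rocks < 0 || n_ephemeral < 0)
    fail_input("confuser counts must be nonnegative")
  if (length(obs_probs) != 2 || any(obs_probs <= 0) || any(obs_probs > 1))
    fail_input("obs_probs must be two probabilities in (0, 1]")
  if (aerial_sigma_m <= 0) fail_input("aerial_sigma_m must be > 0")
  if (truncation_m < 0) fail_input("truncation_m must be >= 0")
  if (transect_spacing_km <= 0) fail_input("transect_spacing_km must be > 0")
  if (mean_group_size < 1 || mean_group_size > 2)
    fail_input("mean_group_size must lie in [1, 2]")
  if (pixel_m <= 0) fail_input("pixel_m must be > 0")
  structure(list(
    island_area_km2 = island_area_km2, island_aspect = island_aspect,
    n_bears = as.integer(n_bears), n_rocks = as.integer(n_rocks),
    n_ephemeral = as.integer(n_ephemeral), obs_probs = obs_probs,
    aerial_sigma_m = aerial_sigma_m, truncation_m = truncation_m,
    transect_spacing_km = transect_spacing_km,
    mean_group_size = mean_group_size, min_sep_m = min_sep_m,
    jitter_max_m = jitter_max_m,
    background_reflectance = background_reflectance, noise_sd = noise_sd,
    pixel_m = pixel_m, seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic survey configuration\n")
  cat(sprintf("  island: %.0f km2 (aspect %.1f), %d bears, %d rocks, %d ephemeral\n",
              x$island_area_km2, x$island_aspect, x$n_bears, x$n_rocks,
              x$n_ephemeral))
  cat(sprintf("  image observers p = (%.2f, %.2f); aerial sigma = %.0f m, w = %.0f m\n",
              x$obs_probs[1], x$obs_probs[2], x$aerial_sigma_m, x$truncation_m))
  cat(sprintf("  transect spacing %.1f km; seed %d\n",
              x$transect_spacing_km, x$seed))
  invisible(x)
}
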