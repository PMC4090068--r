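#' Simulate the helicopter line-transect survey over a scene
#'
#' Computes each bear group's perpendicular distance to the nearest transect
#' and detects it with half-normal probability
#' \eqn{g(x) = \exp(-x^2 / 2\sigma^2)} when the distance does not exceed the
#' truncation. Detected rows carry the nearest transect id, the perpendicular
#' distance in meters, the group size, and categorical visibility and light
#' covariates drawn independently of detection (no true covariate effect by
#' default).
#'
#' @param scene a [generate_scene()] result (transects must exist).
#' @param sigma_m half-normal detection scale, m; defaults to the scene
#'   configuration.
#' @param truncation_m perpendicular truncation distance, m.
#' @param vis_probs named probabilities for the visibility classes
#'   `poor/fair` and `excellent`.
#' @param light_probs named probabilities for the light classes `overcast`,
#'   `mostly cloudy`, `partly cloudy/clear`.
#' @param stratum stratum label written on every row (default `"Rowley"`).
#' @param seed optional seed override.
#' @return list with `sightings` (data.frame `transect_id, stratum,
#'   perp_distance_m, group_size, vis, light`) and `transects` (data.frame
#'   `transect_id, stratum, length_km`).
#' @examples
#' sc <- generate_scene(sim_config(n_bears = 50, seed = 3))
#' sv <- simulate_line_transect(sc)
#' head(sv$sightings)
#' @export
simulate_line_transect <- function(scene, sigma_m = NULL, truncation_m = NULL,
                                   vis_probs = c("poor/fair" = 0.3,
                                                 "excellent" = 0.7),
                                   light_probs = c("overcast" = 1 / 3,
                                                   "mostly cloudy" = 1 / 3,
                                                   "partly cloudy/clear" = 1 / 3),
                                   stratum = "Rowley", seed = NULL) {
  stopifnot(inherits(scene, "pc_scene"))
  if (nrow(scene$transects) == 0) fail_input("scene has no transects")
  cfg <- scene$config
  if (is.null(sigma_m)) sigma_m <- cfg$aerial_sigma_m
  if (is.null(truncation_m)) truncation_m <- cfg$truncation_m
  if (sigma_m <= 0) fail_input("sigma_m must be > 0")
  if (is.null(seed)) seed <- derive_seed(cfg$seed, 3)

  tx <- scene$transects$x_m
  # transects are vertical chords spanning the island, so the perpendicular
  # distance from an interior point is the horizontal offset to the nearest
  # transect x position
  dmat <- abs(outer(scene$bears$x, tx, "-"))
  nearest <- apply(dmat, 1, which.min)
  perp <- dmat[cbind(seq_len(nrow(dmat)), nearest)]

  with_seed(seed, {
    gprob <- exp(-perp^2 / (2 * sigma_m^2))
    det <- perp <= truncation_m & runif(length(perp)) < gprob
    n <- sum(det)
    sightings <- data.frame(
      transect_id = scene$transects$transect_id[nearest[det]],
      stratum = rep_len(stratum, n),
      perp_distance_m = perp[det],
      group_size = scene$bears$group_size[det],
      vis = sample(names(vis_probs), n, TRUE, prob = vis_probs),
      light = sample(names(light_probs), n, TRUE, prob = light_probs),
      row.names = NULL)
    transects <- data.frame(transect_id = scene$transects$transect_id,
                            stratum = stratum,
                            length_km = scene$transects$length_km)
    list(sightings = sightings, transects = transects)
  })
}
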