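#' Simulate two independent image observers
#'
#' Each bear group is detected independently by observer A with probability
#' `obs_probs[1]` and by observer B with probability `obs_probs[2]`; the two
#' reviews of the same image are the two occasions of the closed-population
#' experiment. Detected points receive a small uniform digitization jitter.
#' Optionally, ephemeral confusers visible on the target date enter the raw
#' lists as false positives; [joint_review()] models the observers'
#' subsequent joint examination, which removes all non-bear points.
#'
#' @param scene a [generate_scene()] result.
#' @param obs_probs optional length-2 override of the scene's detection
#'   probabilities.
#' @param include_false_positives if `TRUE`, target-date ephemeral objects
#'   can appear in each observer's raw list (with the same per-observer
#'   detection probability).
#' @param seed optional seed override; defaults to a sub-stream of the scene
#'   seed.
#' @return list with observer point tables `A` and `B`, each a data.frame
#'   `point_id, observer, x_m, y_m, true_id, true_type`, where `true_id`
#'   carries the simulation identity used only by test oracles.
#' @examples
#' sc <- generate_scene(sim_config(n_bears = 10, seed = 2))
#' obs <- simulate_observers(sc)
#' nrow(obs$A); nrow(obs$B)
#' @export
simulate_observers <- function(scene, obs_probs = NULL,
                               include_false_positives = FALSE, seed = NULL) {
  stopifnot(inherits(scene, "pc_scene"))
  cfg <- scene$config
  p <- if (is.null(obs_probs)) cfg$obs_probs else obs_probs
  if (length(p) != 2 || any(p <= 0) || any(p > 1))
    fail_input("obs_probs must be two probabilities in (0, 1]")
  if (is.null(seed)) seed <- derive_seed(cfg$seed, 2)

  targets <- data.frame(x = scene$bears$x, y = scene$bears$y,
                        true_id = paste0("bear_", scene$bears$id),
                        true_type = "bear")
  if (include_false_positives && nrow(scene$ephemeral) > 0) {
    eph <- scene$ephemeral[scene$ephemeral$date == "target", , drop = FALSE]
    if (nrow(eph) > 0)
      targets <- rbind(targets,
                       data.frame(x = eph$x, y = eph$y,
                                  true_id = paste0("eph_", eph$id),
                                  true_type = "ephemeral"))
  }

  with_seed(seed, {
    tabs <- lapply(1:2, function(k) {
      det <- runif(nrow(targets)) < p[k]
      d <- targets[det, , drop = FALSE]
      n <- nrow(d)
      r <- cfg$jitter_max_m * sqrt(runif(n))
      th <- runif(n, 0, 2 * pi)
      data.frame(point_id = paste0(c("A", "B")[k], seq_len(n)),
                 observer = c("A", "B")[k],
                 x_m = d$x + r * cos(th), y_m = d$y + r * sin(th),
                 true_id = d$true_id, true_type = d$true_type,
                 row.names = NULL)
    })
    list(A = tabs[[1]], B = tabs[[2]])
  })
}

#' Joint review of candidate points
#'
#' Models the observers' joint re-examination of the imagery: points that are
#' not bears are removed from both lists; no points are added. With the
#' simulator's identity labels this is exact; on real tables it is a no-op
#' filter on the `true_type` column when present.
#'
#' @param observer_tables list with elements `A` and `B` as returned by
#'   [simulate_observers()].
#' @return the same structure with non-bear rows dropped.
#' @export
joint_review <- function(observer_tables) {
  lapply(observer_tables, function(d) {
    if (!is.null(d$true_type)) d[d$true_type == "bear", , drop = FALSE] else d
  })
}
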