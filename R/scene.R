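#' Generate a synthetic survey scene
#'
#' Builds the complete ground truth for one survey: an elliptical island
#' polygon of the configured area, independent-bear groups placed by a
#' uniform (hard-core) point process, persistent rocks, ephemeral bright
#' confusers assigned to one acquisition date each, and parallel transects
#' perpendicular to the island's long axis at the configured spacing, clipped
#' to the island.
#'
#' All coordinates are meters in a planar CRS centred on the island. The same
#' `sim_config` (including its seed) always regenerates an identical scene.
#'
#' @param config a [sim_config()].
#' @return object of class `pc_scene`: list with `island` (polygon matrix,
#'   m), `area_km2`, `bears` (data.frame `id, x, y, group_size`), `rocks`
#'   (`id, x, y`), `ephemeral` (`id, x, y, date` with date in
#'   `{"target","reference"}`), and `transects` (data.frame `transect_id,
#'   x_m, y0_m, y1_m, length_km`).
#' @examples
#' sc <- generate_scene(sim_config(n_bears = 20, n_rocks = 5, seed = 1))
#' nrow(sc$bears)
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  poly <- make_island_polygon(config$island_area_km2, config$island_aspect)

  pts <- with_seed(derive_seed(config$seed, 1), {
    all_pts <- runif_in_polygon(
      config$n_bears + config$n_rocks + config$n_ephemeral,
      poly, min_sep_m = config$min_sep_m)
    sizes <- 1L + rbinom(config$n_bears, 1L, config$mean_group_size - 1)
    eph_date <- if (config$n_ephemeral > 0)
      sample(c("target", "reference"), config$n_ephemeral, replace = TRUE)
    else character(0)
    list(all = all_pts, sizes = sizes, eph_date = eph_date)
  })

  i_bear <- seq_len(config$n_bears)
  i_rock <- seq_len(config$n_rocks) + config$n_bears
  i_eph <- seq_len(config$n_ephemeral) + config$n_bears + config$n_rocks

  bears <- data.frame(id = i_bear,
                      x = pts$all[i_bear, 1], y = pts$all[i_bear, 2],
                      group_size = pts$sizes)
  rocks <- data.frame(id = seq_len(config$n_rocks),
                      x = pts$all[i_rock, 1], y = pts$all[i_rock, 2])
  ephemeral <- data.frame(id = seq_len(config$n_ephemeral),
                          x = pts$all[i_eph, 1], y = pts$all[i_eph, 2],
                          date = pts$eph_date)

  transects <- make_transects(poly, config$transect_spacing_km)

  structure(list(island = poly, area_km2 = polygon_area_m2(poly) / 1e6,
                 bears = bears, rocks = rocks, ephemeral = ephemeral,
                 transects = transects, config = config),
            class = "pc_scene")
}

# Vertical transects (perpendicular to the long axis, which lies along x),
# at `spacing_km` intervals, centred so the grid covers the island; each
# transect is the chord of the island at its x position.
make_transects <- function(poly, spacing_km) {
  sp <- km_to_m(spacing_km)
  bx <- range(poly[, 1])
  # islands narrower than the spacing get a single central transect
  xs <- if (bx[1] + sp / 2 > bx[2]) mean(bx)
        else seq(bx[1] + sp / 2, bx[2], by = sp)
  rows <- list()
  tid <- 0L
  for (x0 in xs) {
    ch <- vertical_chords(poly, x0)
    for (k in seq_len(nrow(ch))) {
      tid <- tid + 1L
      rows[[tid]] <- data.frame(transect_id = tid, x_m = x0,
                                y0_m = ch[k, 1], y1_m = ch[k, 2],
                                length_km = m_to_km(ch[k, 2] - ch[k, 1]))
    }
  }
  if (length(rows) == 0)
    return(data.frame(transect_id = integer(0), x_m = numeric(0),
                      y0_m = numeric(0), y1_m = numeric(0),
                      length_km = numeric(0)))
  do.call(rbind, rows)
}

#' @export
print.pc_scene <- function(x, ...) {
  cat("Synthetic survey scene\n")
  cat(sprintf("  island %.0f km2; %d bear groups (%d bears), %d rocks, %d ephemeral\n",
              x$area_km2, nrow(x$bears), sum(x$bears$group_size),
              nrow(x$rocks), nrow(x$ephemeral)))
  cat(sprintf("  %d transects, total length %.1f km\n",
              nrow(x$transects), sum(x$transects$length_km)))
  invisible(x)
}
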