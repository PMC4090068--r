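# Flat-file schemas. All tables are UTF-8 CSV with a header row; coordinates
# are meters of a declared planar CRS. Validation reports the offending row
# so third-party data can be debugged without reading the source.

VIS_LEVELS <- c("poor/fair", "excellent")
LIGHT_LEVELS <- c("overcast", "mostly cloudy", "partly cloudy/clear")

check_columns <- function(d, cols, what) {
  miss <- setdiff(cols, names(d))
  if (length(miss) > 0)
    fail_input(what, ": missing columns ", paste(miss, collapse = ", "))
}

#' Read and validate survey tables
#'
#' `read_sightings` reads a distance-sampling sighting table
#' (`transect_id, stratum, perp_distance_m, group_size, vis, light`),
#' rejecting negative distances, group sizes below 1 and categories outside
#' the documented levels (visibility: poor/fair, excellent; light: overcast,
#' mostly cloudy, partly cloudy/clear), naming the first offending row.
#' `read_transects` reads `transect_id, stratum, length_km` (lengths > 0).
#' `read_observer_points` reads `point_id, observer, x_m, y_m` with
#' observer in {A, B} and unique point ids. The matching `write_*`
#' functions emit the same schemas; a write-then-read round trip is the
#' identity.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_sightings <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  validate_sightings(d)
}

#' @rdname read_sightings
#' @param d data.frame to validate in memory.
#' @export
validate_sightings <- function(d) {
  check_columns(d, c("transect_id", "stratum", "perp_distance_m",
                     "group_size", "vis", "light"), "sightings")
  bad <- which(!is.finite(d$perp_distance_m) | d$perp_distance_m < 0)
  if (length(bad) > 0)
    fail_input("sightings row ", bad[1], ": perp_distance_m must be >= 0")
  bad <- which(d$group_size < 1 | d$group_size != round(d$group_size))
  if (length(bad) > 0)
    fail_input("sightings row ", bad[1], ": group_size must be an integer >= 1")
  bad <- which(!(d$vis %in% VIS_LEVELS))
  if (length(bad) > 0)
    fail_input("sightings row ", bad[1], ": vis '", d$vis[bad[1]],
               "' not in {", paste(VIS_LEVELS, collapse = ", "), "}")
  bad <- which(!(d$light %in% LIGHT_LEVELS))
  if (length(bad) > 0)
    fail_input("sightings row ", bad[1], ": light '", d$light[bad[1]],
               "' not in {", paste(LIGHT_LEVELS, collapse = ", "), "}")
  d
}

#' @rdname read_sightings
#' @export
read_transects <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(d, c("transect_id", "stratum", "length_km"), "transects")
  bad <- which(!is.finite(d$length_km) | d$length_km <= 0)
  if (length(bad) > 0)
    fail_input("transects row ", bad[1], ": length_km must be > 0")
  d
}

#' @rdname read_sightings
#' @export
read_observer_points <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(d, c("point_id", "observer", "x_m", "y_m"), "observer points")
  bad <- which(!(d$observer %in% c("A", "B")))
  if (length(bad) > 0)
    fail_input("observer points row ", bad[1], ": observer must be A or B")
  if (anyDuplicated(d$point_id))
    fail_input("observer points: duplicate point_id")
  d
}

#' @rdname read_sightings
#' @export
write_sightings <- function(d, path) {
  validate_sightings(d)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_sightings
#' @export
write_transects <- function(d, path) {
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_sightings
#' @export
write_observer_points <- function(d, path) {
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write scene geometry as GeoJSON
#'
#' Emits a FeatureCollection with the island polygon, bear / rock /
#' ephemeral points and transect LineStrings, coordinates in meters of the
#' scene's planar CRS.
#'
#' @param scene a [generate_scene()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scene_geojson <- function(scene, path) {
  stopifnot(inherits(scene, "pc_scene"))
  feat <- list()
  ring <- rbind(scene$island, scene$island[1, ])
  feat[[1]] <- list(type = "Feature",
                    properties = list(kind = "island"),
                    geometry = list(type = "Polygon",
                                    coordinates = list(unname(
                                      lapply(seq_len(nrow(ring)),
                                             function(i) ring[i, ])))))
  add_points <- function(df, kind, extra = NULL) {
    lapply(seq_len(nrow(df)), function(i) {
      props <- c(list(kind = kind, id = df$id[i]),
                 if (!is.null(extra)) df[i, extra, drop = FALSE])
      list(type = "Feature", properties = props,
           geometry = list(type = "Point",
                           coordinates = c(df$x[i], df$y[i])))
    })
  }
  feat <- c(feat, add_points(scene$bears, "bear", "group_size"),
            add_points(scene$rocks, "rock"),
            add_points(scene$ephemeral, "ephemeral", "date"))
  feat <- c(feat, lapply(seq_len(nrow(scene$transects)), function(i) {
    t <- scene$transects[i, ]
    list(type = "Feature",
         properties = list(kind = "transect", id = t$transect_id,
                           length_km = t$length_km),
         geometry = list(type = "LineString",
                         coordinates = list(c(t$x_m, t$y0_m),
                                            c(t$x_m, t$y1_m))))
  }))
  jsonlite::write_json(list(type = "FeatureCollection", features = feat),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Nested list of every pipeline parameter with defaults, serialisable to
#' YAML and back without loss; a run is reproducible from its config and
#' seed alone.
#'
#' @param seed master seed.
#' @param ... overrides of the default entries (named, possibly nested
#'   lists merged shallowly per section).
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    scene = list(island_area_km2 = 1100, island_aspect = 2.6, n_bears = 94,
                 n_rocks = 200, n_ephemeral = 50, mean_group_size = 1.03,
                 min_sep_m = 30),
    satellite = list(obs_probs = c(0.96, 0.42), jitter_max_m = 5,
                     match_radius_m = 30),
    aerial = list(sigma_m = 800, truncation_m = 2300,
                  transect_spacing_km = 7, huggins_p_front = 0.95,
                  huggins_p_rear = 0.85, aicc_cutoff = 3),
    imagery = list(pixel_m = 0.5, noise_sd = 0.01, threshold_contrast = 0.2,
                   min_area_m2 = 1, max_area_m2 = 12, match_radius_m = 3))
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && nm %in% names(cfg)) {
      for (k in names(dots[[nm]])) cfg[[nm]][[k]] <- dots[[nm]][[k]]
    } else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, c(list(seed = cfg$seed),
                        cfg[setdiff(names(cfg), "seed")]))
}

#' Write a report as machine-readable key-value text
#'
#' Flattens a report list into `key = value` lines (nested names joined with
#' dots), diffable and parseable without R.
#'
#' @param report named list (any pipeline report).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_kv <- function(report, path) {
  flatten <- function(x, prefix = "") {
    out <- character(0)
    for (nm in names(x)) {
      key <- if (prefix == "") nm else paste0(prefix, ".", nm)
      v <- x[[nm]]
      if (is.list(v) && !is.null(names(v))) {
        out <- c(out, flatten(v, key))
      } else if (is.data.frame(v)) {
        next
      } else {
        out <- c(out, paste0(key, " = ",
                             paste(format(v, digits = 10, trim = TRUE),
                                   collapse = ", ")))
      }
    }
    out
  }
  writeLines(flatten(unclass(report)), path)
  invisible(path)
}
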