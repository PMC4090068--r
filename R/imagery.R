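#' Acquisition metadata for top-of-atmosphere reflectance
#'
#' Per-band radiometric calibration and solar geometry of one image
#' acquisition: radiance is `L = gain * DN + offset` and reflectance
#' \eqn{\rho = \pi L d^2 / (ESUN \sin\theta_s)} where `d` is the earth-sun
#' distance (AU) and \eqn{\theta_s} the sun elevation.
#'
#' @param gain radiometric gain (> 0).
#' @param offset radiometric offset.
#' @param esun band mean exo-atmospheric solar irradiance (W m-2 um-1).
#' @param earth_sun_distance_au earth-sun distance in AU, in [0.98, 1.02].
#' @param sun_elevation_deg sun elevation angle, degrees, in (0, 90].
#' @param acquisition_date date string.
#' @return object of class `scene_metadata`.
#' @export
scene_metadata <- function(gain, offset = 0, esun,
                           earth_sun_distance_au = 1,
                           sun_elevation_deg, acquisition_date = NA) {
  if (gain <= 0) fail_input("gain must be > 0")
  if (sun_elevation_deg <= 0 || sun_elevation_deg > 90)
    fail_input("sun_elevation_deg must lie in (0, 90]")
  if (earth_sun_distance_au < 0.98 || earth_sun_distance_au > 1.02)
    fail_input("earth_sun_distance_au must lie in [0.98, 1.02]")
  structure(list(gain = gain, offset = offset, esun = esun,
                 earth_sun_distance_au = earth_sun_distance_au,
                 sun_elevation_deg = sun_elevation_deg,
                 acquisition_date = acquisition_date),
            class = "scene_metadata")
}

#' Convert digital numbers to top-of-atmosphere reflectance
#'
#' Applies the standard DN-to-reflectance conversion so that target and
#' reference images acquired under different exposure settings and solar
#' geometry are directly comparable. Output is clipped to `[0, 1.5]`.
#'
#' @param dn a [pc_raster()] (or plain matrix) of digital numbers.
#' @param metadata a [scene_metadata()].
#' @return raster (or matrix) of reflectance, same grid.
#' @examples
#' md <- scene_metadata(gain = 0.01, esun = pi * 100, sun_elevation_deg = 90)
#' toa_reflectance(matrix(100, 2, 2), md)
#' @export
toa_reflectance <- function(dn, metadata) {
  stopifnot(inherits(metadata, "scene_metadata"))
  v <- if (inherits(dn, "pc_raster")) dn$values else dn
  L <- metadata$gain * v + metadata$offset
  rho <- pi * L * metadata$earth_sun_distance_au^2 /
    (metadata$esun * sin(metadata$sun_elevation_deg * pi / 180))
  rho <- pmin(pmax(rho, 0), 1.5)
  if (inherits(dn, "pc_raster")) {
    dn$values <- rho
    dn
  } else rho
}

#' Linear percentile stretch
#'
#' Maps the `[P_lo, P_hi]` percentile range linearly onto `[0, 1]` with
#' clipping, brightening dark non-ice areas for visual comparison. The same
#' anchors must be applied to both images of a pair; pass `anchors` computed
#' from one image to stretch the other identically.
#'
#' A constant raster returns all 0.5 with a warning. If the raster is not
#' constant but the two percentile anchors coincide (e.g. a flat background
#' with a handful of bright pixels), the full min-max range is used instead,
#' with a warning.
#'
#' @param r a [pc_raster()] or matrix.
#' @param lo_pct,hi_pct percentile anchors (defaults 2 and 98).
#' @param anchors optional precomputed `c(lo, hi)` values overriding the
#'   percentiles (for pair-identical stretching).
#' @return object of the same kind, values in `[0, 1]`, with attribute-free
#'   `anchors` retrievable via `attr(, "anchors")` on the value matrix.
#' @export
percentile_stretch <- function(r, lo_pct = 2, hi_pct = 98, anchors = NULL) {
  if (lo_pct >= hi_pct) fail_input("lo_pct must be < hi_pct")
  v <- if (inherits(r, "pc_raster")) r$values else r
  if (is.null(anchors)) {
    anchors <- unname(quantile(v, c(lo_pct, hi_pct) / 100))
    if (anchors[1] == anchors[2]) {
      rng <- range(v)
      if (rng[1] == rng[2]) {
        warning("constant raster: returning 0.5 everywhere")
        out <- matrix(0.5, nrow(v), ncol(v))
        attr(out, "anchors") <- anchors
        if (inherits(r, "pc_raster")) { r$values <- out; return(r) }
        return(out)
      }
      warning("degenerate percentile anchors: falling back to min-max stretch")
      anchors <- rng
    }
  }
  out <- (v - anchors[1]) / (anchors[2] - anchors[1])
  out <- pmin(pmax(out, 0), 1)
  attr(out, "anchors") <- anchors
  if (inherits(r, "pc_raster")) { r$values <- out; r } else out
}

#' Extract candidate bright spots
#'
#' Thresholds pixels whose value exceeds the local background by
#' `threshold_contrast`, labels connected components (8-connectivity), and
#' keeps components whose area falls inside a gate bracketing a ~2-m object.
#' Background is the median inside a square window (default 25 m), robust to
#' smooth gradients; `background = "global"` uses the raster median instead.
#'
#' @param r a stretched [pc_raster()].
#' @param threshold_contrast minimum contrast over background.
#' @param min_area_m2,max_area_m2 component area gate, m2.
#' @param background `"local"` (median filter) or `"global"`.
#' @param bg_window_m local background window width, m.
#' @param cloud_mask optional logical matrix (same grid) of pixels excluded
#'   from the candidate search.
#' @return data.frame of spot candidates: `id, x, y, area_m2,
#'   mean_reflectance, contrast` (centroids in map coordinates).
#' @export
detect_bright_spots <- function(r, threshold_contrast = 0.2,
                                min_area_m2 = 1, max_area_m2 = 12,
                                background = c("local", "global"),
                                bg_window_m = 25, cloud_mask = NULL) {
  stopifnot(inherits(r, "pc_raster"))
  background <- match.arg(background)
  v <- r$values
  if (background == "local") {
    rad <- max(1L, as.integer(round(bg_window_m / (2 * r$pixel_m))))
    vin <- pmin(pmax(v, 0), 1)
    bg <- EBImage::medianFilter(vin, size = rad)
  } else {
    bg <- median(v)
  }
  contrast <- v - bg
  mask <- contrast > threshold_contrast
  if (!is.null(cloud_mask)) mask <- mask & !cloud_mask
  lab <- EBImage::bwlabel(mask * 1)
  nlab <- max(lab)
  empty <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      area_m2 = numeric(0), mean_reflectance = numeric(0),
                      contrast = numeric(0))
  if (nlab == 0) return(empty)
  idx <- which(lab > 0)
  li <- lab[idx]
  rows <- (idx - 1) %% nrow(v) + 1
  cols <- (idx - 1) %/% nrow(v) + 1
  px_area <- r$pixel_m^2
  area <- tabulate(li, nlab) * px_area
  cx <- tapply(cols, li, mean); cy <- tapply(rows, li, mean)
  mval <- tapply(v[idx], li, mean)
  mcon <- tapply(contrast[idx], li, mean)
  keep <- which(area >= min_area_m2 & area <= max_area_m2)
  if (length(keep) == 0) return(empty)
  xy <- raster_xy(r, as.numeric(cy[keep]), as.numeric(cx[keep]))
  data.frame(id = seq_along(keep), x = xy[, "x"], y = xy[, "y"],
             area_m2 = unname(area[keep]),
             mean_reflectance = as.numeric(mval[keep]),
             contrast = as.numeric(mcon[keep]), row.names = NULL)
}

#' Label target-date candidates against the reference image
#'
#' A candidate is a persistent confuser (`both_dates`) if the reference image
#' shows a bright spot within `match_radius_m` of it; otherwise it is a
#' presumed animal (`target_only`). Candidates falling in a cloud-masked
#' region of the reference cannot be checked and default to `target_only`
#' with `low_confidence = TRUE`.
#'
#' @param target_candidates data.frame from [detect_bright_spots()] on the
#'   target image.
#' @param reference_raster stretched reference [pc_raster()], co-registered
#'   with the target grid.
#' @param target_raster the target [pc_raster()] (used only to verify the
#'   grids match).
#' @param match_radius_m matching radius, m.
#' @param threshold_contrast,min_area_m2,max_area_m2,background,bg_window_m
#'   detector settings applied to the reference image (defaults as in
#'   [detect_bright_spots()]).
#' @param cloud_mask optional logical matrix marking cloud-obscured reference
#'   pixels.
#' @return `target_candidates` with `persistence_label` in
#'   `{"target_only","both_dates"}` and logical `low_confidence` appended.
#' @export
cross_date_filter <- function(target_candidates, reference_raster,
                              target_raster = NULL, match_radius_m = 3,
                              threshold_contrast = 0.2, min_area_m2 = 1,
                              max_area_m2 = 12,
                              background = c("local", "global"),
                              bg_window_m = 25, cloud_mask = NULL) {
  stopifnot(inherits(reference_raster, "pc_raster"))
  if (!is.null(target_raster) && !same_grid(target_raster, reference_raster))
    fail_input("target and reference rasters are not on the same grid")
  background <- match.arg(background)
  ref <- detect_bright_spots(reference_raster, threshold_contrast,
                             min_area_m2, max_area_m2, background,
                             bg_window_m, cloud_mask)
  n <- nrow(target_candidates)
  label <- rep("target_only", n)
  lowconf <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (!is.null(cloud_mask)) {
      row <- round((reference_raster$ymax - target_candidates$y[i]) /
                     reference_raster$pixel_m + 0.5)
      col <- round((target_candidates$x[i] - reference_raster$xmin) /
                     reference_raster$pixel_m + 0.5)
      if (row >= 1 && row <= nrow(cloud_mask) &&
          col >= 1 && col <= ncol(cloud_mask) && cloud_mask[row, col]) {
        lowconf[i] <- TRUE
        next
      }
    }
    if (nrow(ref) > 0) {
      d2 <- (ref$x - target_candidates$x[i])^2 +
        (ref$y - target_candidates$y[i])^2
      if (min(d2) <= match_radius_m^2) label[i] <- "both_dates"
    }
  }
  target_candidates$persistence_label <- label
  target_candidates$low_confidence <- lowconf
  target_candidates
}
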