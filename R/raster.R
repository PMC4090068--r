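#' Lightweight single-band raster
#'
#' An in-memory grid with an affine geotransform: row-major storage with the
#' top-left pixel first, pixel-is-area convention, half-open extent
#' `[xmin, xmin + ncol * pixel) x (ymax - nrow * pixel, ymax]`. `values` is a
#' numeric matrix with `nrow` rows (north to south) and `ncol` columns (west
#' to east).
#'
#' @param values numeric matrix.
#' @param xmin west edge of the west-most pixel, m.
#' @param ymax north edge of the north-most pixel, m.
#' @param pixel_m pixel size, m (> 0).
#' @return object of class `pc_raster`.
#' @export
pc_raster <- function(values, xmin, ymax, pixel_m) {
  if (pixel_m <= 0) fail_input("pixel size must be > 0")
  stopifnot(is.matrix(values))
  structure(list(values = values, xmin = xmin, ymax = ymax,
                 pixel_m = pixel_m), class = "pc_raster")
}

#' @export
print.pc_raster <- function(x, ...) {
  cat(sprintf("pc_raster: %d x %d pixels, %.2f m, origin (%.1f, %.1f)\n",
              nrow(x$values), ncol(x$values), x$pixel_m, x$xmin, x$ymax))
  cat(sprintf("  values in [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$xmin, a$ymax, a$pixel_m),
                     c(b$xmin, b$ymax, b$pixel_m)))
}

# map coordinates (m) of pixel centres
raster_xy <- function(r, rows, cols) {
  cbind(x = r$xmin + (cols - 0.5) * r$pixel_m,
        y = r$ymax - (rows - 0.5) * r$pixel_m)
}

# draw filled discs of constant value onto a matrix (in place semantics via
# return); centres in map coordinates
draw_discs <- function(r, cx, cy, radius_m, value) {
  v <- r$values
  nr <- nrow(v); nc <- ncol(v)
  for (i in seq_along(cx)) {
    col0 <- (cx[i] - r$xmin) / r$pixel_m
    row0 <- (r$ymax - cy[i]) / r$pixel_m
    rad <- radius_m / r$pixel_m
    cs <- max(1L, floor(col0 - rad)):min(nc, ceiling(col0 + rad) + 1L)
    rs <- max(1L, floor(row0 - rad)):min(nr, ceiling(row0 + rad) + 1L)
    if (length(cs) == 0 || length(rs) == 0) next
    cc <- cs - 0.5; rr <- rs - 0.5
    d2 <- outer((rr - row0)^2, (cc - col0)^2, "+")
    sel <- d2 <= rad^2
    v[rs, cs][sel] <- value
  }
  r$values <- v
  r
}

#' Render a co-registered target/reference raster pair for a scene
#'
#' Bears (~2-m bright objects) are drawn only on the target date; rocks on
#' both dates; ephemeral confusers only on their assigned date. Background is
#' constant reflectance plus optional Gaussian pixel noise. Rerunning with
#' the same scene and seed reproduces identical rasters.
#'
#' @param scene a [generate_scene()] result.
#' @param pixel_m pixel size, m; defaults to the scene configuration.
#' @param window optional `c(xmin, xmax, ymin, ymax)` in m; defaults to the
#'   island bounding box plus a 50 m margin.
#' @param bear_reflectance,rock_reflectance,ephemeral_reflectance apparent
#'   top-of-atmosphere reflectance of drawn objects.
#' @param object_diameter_m drawn object diameter, m (~2 m white objects).
#' @param noise_sd Gaussian pixel noise SD; defaults to the scene
#'   configuration (`0` for noise-free pairs).
#' @param seed optional seed override.
#' @return list with `target` and `reference` [pc_raster()] objects.
#' @export
render_image_pair <- function(scene, pixel_m = NULL, window = NULL,
                              bear_reflectance = 0.9,
                              rock_reflectance = 0.85,
                              ephemeral_reflectance = 0.8,
                              object_diameter_m = 2,
                              noise_sd = NULL, seed = NULL) {
  stopifnot(inherits(scene, "pc_scene"))
  cfg <- scene$config
  if (is.null(pixel_m)) pixel_m <- cfg$pixel_m
  if (pixel_m <= 0) fail_input("pixel size must be > 0")
  if (is.null(noise_sd)) noise_sd <- cfg$noise_sd
  if (is.null(seed)) seed <- derive_seed(cfg$seed, 4)
  if (is.null(window)) {
    bx <- range(scene$island[, 1]); by <- range(scene$island[, 2])
    window <- c(bx[1] - 50, bx[2] + 50, by[1] - 50, by[2] + 50)
  }
  nc <- ceiling((window[2] - window[1]) / pixel_m)
  nr <- ceiling((window[4] - window[3]) / pixel_m)
  base <- matrix(cfg$background_reflectance, nr, nc)

  rad <- object_diameter_m / 2
  build <- function(noise, which_date) {
    r <- pc_raster(base + noise, window[1], window[4], pixel_m)
    if (nrow(scene$rocks) > 0)
      r <- draw_discs(r, scene$rocks$x, scene$rocks$y, rad, rock_reflectance)
    eph <- scene$ephemeral[scene$ephemeral$date == which_date, , drop = FALSE]
    if (nrow(eph) > 0)
      r <- draw_discs(r, eph$x, eph$y, rad, ephemeral_reflectance)
    if (which_date == "target" && nrow(scene$bears) > 0)
      r <- draw_discs(r, scene$bears$x, scene$bears$y, rad, bear_reflectance)
    r
  }

  with_seed(seed, {
    noise_t <- if (noise_sd > 0) matrix(rnorm(nr * nc, 0, noise_sd), nr, nc) else 0
    noise_r <- if (noise_sd > 0) matrix(rnorm(nr * nc, 0, noise_sd), nr, nc) else 0
    list(target = build(noise_t, "target"),
         reference = build(noise_r, "reference"))
  })
}

#' Write / read a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format carrying the affine geotransform in its
#' header (`ncols, nrows, xllcorner, yllcorner, cellsize`); round-trips a
#' [pc_raster()] exactly up to numeric formatting.
#'
#' @param r a [pc_raster()].
#' @param path file path.
#' @return `write_ascii_grid` returns `path` invisibly; `read_ascii_grid`
#'   returns a [pc_raster()].
#' @export
write_ascii_grid <- function(r, path) {
  stopifnot(inherits(r, "pc_raster"))
  nr <- nrow(r$values); nc <- ncol(r$values)
  hdr <- c(sprintf("ncols %d", nc), sprintf("nrows %d", nr),
           sprintf("xllcorner %.6f", r$xmin),
           sprintf("yllcorner %.6f", r$ymax - nr * r$pixel_m),
           sprintf("cellsize %.6f", r$pixel_m),
           "NODATA_value -9999")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(format(r$values, digits = 10, trim = TRUE, scientific = FALSE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(hdr, "\\s+")
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  names(vals) <- tolower(vapply(kv, `[`, "", 1))
  m <- as.matrix(read.table(path, skip = 6))
  dimnames(m) <- NULL
  pc_raster(m, vals[["xllcorner"]],
            vals[["yllcorner"]] + vals[["nrows"]] * vals[["cellsize"]],
            vals[["cellsize"]])
}
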