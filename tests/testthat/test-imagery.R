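small_scene <- function(n_bears, n_rocks, n_eph = 0, seed = 1,
                        noise_sd = 0, area = 2) {
  generate_scene(sim_config(island_area_km2 = area, n_bears = n_bears,
                            n_rocks = n_rocks, n_ephemeral = n_eph,
                            noise_sd = noise_sd, pixel_m = 1,
                            min_sep_m = 30, seed = seed))
}

test_that("TOA reflectance follows the radiometric formula", {
  md <- scene_metadata(gain = 0.01, offset = 0, esun = pi * 100,
                       sun_elevation_deg = 90)
  # hand oracle: rho = pi * (0.01 * 100) * 1 / (pi * 100 * sin 90) = 0.01
  expect_equal(toa_reflectance(matrix(100, 2, 2), md),
               matrix(0.01, 2, 2))
  expect_equal(toa_reflectance(matrix(0, 2, 2), md), matrix(0, 2, 2))
  # d^2 scaling within the physical range of earth-sun distances
  md_far <- scene_metadata(gain = 0.01, esun = pi * 100,
                           earth_sun_distance_au = 1.02,
                           sun_elevation_deg = 90)
  expect_equal(toa_reflectance(matrix(100, 1, 1), md_far)[1] /
                 toa_reflectance(matrix(100, 1, 1), md)[1], 1.02^2)
  # monotone in DN for positive gain
  dn <- matrix(seq(0, 2000, length.out = 50), 1)
  expect_true(all(diff(toa_reflectance(dn, md)[1, ]) >= 0))
  # clipping to [0, 1.5]
  expect_equal(max(toa_reflectance(matrix(1e6, 1, 1), md)), 1.5)
  expect_error(scene_metadata(gain = 0.01, esun = 1,
                              sun_elevation_deg = 0), "sun_elevation")
  expect_error(scene_metadata(gain = -1, esun = 1, sun_elevation_deg = 45),
               "gain")
})

test_that("percentile stretch anchors match order statistics and preserve rank", {
  ramp <- matrix(seq(0, 1, length.out = 100), 10)
  st <- percentile_stretch(ramp)
  expect_equal(attr(st, "anchors"),
               unname(quantile(ramp, c(0.02, 0.98))))
  # identity up to clipping when anchors are 0 and 1
  st2 <- percentile_stretch(ramp, anchors = c(0, 1))
  expect_equal(as.vector(st2), as.vector(ramp))
  expect_warning(stc <- percentile_stretch(matrix(0.3, 5, 5)), "constant")
  expect_true(all(stc == 0.5))
  # rank invariance
  set.seed(1)
  v <- matrix(rnorm(400), 20)
  sv <- percentile_stretch(v)
  mid <- v > quantile(v, 0.02) & v < quantile(v, 0.98)
  expect_equal(order(v[mid]), order(sv[mid]))
})

test_that("image pairs show bears only on the target date", {
  sc <- small_scene(1, 0, seed = 2)
  pair <- render_image_pair(sc)
  diff <- pair$target$values - pair$reference$values
  expect_equal(flood_fill_components(diff > 0.2), 1)
  # a single rock is persistent: noise-free difference is identically zero
  sc2 <- small_scene(1, 1, seed = 3)
  sc2$bears <- sc2$bears[0, ]
  pair2 <- render_image_pair(sc2)
  expect_true(all(pair2$target$values == pair2$reference$values))
})

test_that("rendering is bytewise reproducible under a fixed seed", {
  sc <- small_scene(10, 20, seed = 4, noise_sd = 0.01)
  a <- render_image_pair(sc)
  b <- render_image_pair(sc)
  expect_identical(a$target$values, b$target$values)
  expect_identical(a$reference$values, b$reference$values)
  expect_error(render_image_pair(sc, pixel_m = 0), "pixel")
})

test_that("bright-spot extraction matches a flood-fill oracle", {
  sc <- small_scene(30, 0, seed = 5)
  pair <- render_image_pair(sc)
  cand <- detect_bright_spots(pair$target)
  oracle <- flood_fill_components(pair$target$values >
                                    sc$config$background_reflectance + 0.2)
  expect_equal(nrow(cand), oracle)
  expect_equal(nrow(cand), 30)
  # centroids within one pixel of the planted coordinates
  d <- vapply(seq_len(nrow(cand)), function(i)
    min(sqrt((sc$bears$x - cand$x[i])^2 + (sc$bears$y - cand$y[i])^2)), 0)
  expect_lte(max(d), sc$config$pixel_m)
})

test_that("area gate drops objects outside the 2-m bracket", {
  sc <- small_scene(5, 0, seed = 6)
  pair <- render_image_pair(sc, object_diameter_m = 5)  # ~20 m2 floes
  cand <- detect_bright_spots(pair$target)
  expect_equal(nrow(cand), 0)
  wide <- detect_bright_spots(pair$target, max_area_m2 = 40)
  expect_equal(nrow(wide), 5)
})

test_that("cross-date filtering separates bears from rocks exactly", {
  sc <- small_scene(25, 40, seed = 7, area = 4)
  pair <- render_image_pair(sc)
  cand <- detect_bright_spots(pair$target)
  lab <- cross_date_filter(cand, pair$reference, pair$target)
  expect_equal(sum(lab$persistence_label == "target_only"), 25)
  expect_equal(sum(lab$persistence_label == "both_dates"), 40)
  # labels agree with ground truth: every target_only centroid is a bear
  to <- lab[lab$persistence_label == "target_only", ]
  d <- vapply(seq_len(nrow(to)), function(i)
    min(sqrt((sc$bears$x - to$x[i])^2 + (sc$bears$y - to$y[i])^2)), 0)
  expect_lte(max(d), 2)
})

test_that("grid mismatch and cloud masks are handled", {
  sc <- small_scene(3, 3, seed = 8)
  pair <- render_image_pair(sc)
  shifted <- pair$reference
  shifted$xmin <- shifted$xmin + 10
  cand <- detect_bright_spots(pair$target)
  expect_error(cross_date_filter(cand, shifted, pair$target), "same grid")
  # full cloud mask on the reference: everything defaults to low-confidence
  # target_only
  mask <- matrix(TRUE, nrow(pair$reference$values),
                 ncol(pair$reference$values))
  lab <- cross_date_filter(cand, pair$reference, pair$target,
                           cloud_mask = mask)
  expect_true(all(lab$persistence_label == "target_only"))
  expect_true(all(lab$low_confidence))
})

test_that("ephemeral confusers appear only on their assigned date", {
  sc <- small_scene(1, 0, n_eph = 12, seed = 9, area = 4)
  sc$bears <- sc$bears[0, ]
  pair <- render_image_pair(sc)
  cand_t <- detect_bright_spots(pair$target)
  cand_r <- detect_bright_spots(pair$reference)
  expect_equal(nrow(cand_t), sum(sc$ephemeral$date == "target"))
  expect_equal(nrow(cand_r), sum(sc$ephemeral$date == "reference"))
})
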