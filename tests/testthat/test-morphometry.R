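# Histology mask generation and morphometric quantification.

test_that("the mask generator is deterministic, hits the collagen target
           exactly, and records component truth", {
  cfg <- mask_sim_config(seed = 4)
  a <- sim_histology_masks(cfg)
  b <- sim_histology_masks(cfg)
  expect_identical(a$capillary, b$capillary)
  expect_identical(a$collagen, b$collagen)
  expect_equal(a$truth$collagen_fraction, 0.196, tolerance = 0.005)
  expect_equal(max(a$capillary), cfg$n_capillaries)
  # placement failure raises an error
  crowded <- mask_sim_config(size = 110, n_capillaries = 150,
                             radius_range = c(6, 8), min_gap = 6,
                             max_tries = 40)
  expect_error(sim_histology_masks(crowded), "could not place")
  expect_error(sim_histology_masks(mask_sim_config(size = 40)), "too small")
})

test_that("simple geometry: disks, annuli and elongated ellipses are
           measured and classified correctly", {
  # filled disk r = 10: area within 1% of pi r^2, transverse, no lumen
  size <- 64
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  disk <- ((rows - 32)^2 + (cols - 32)^2 <= 100) * 1L
  cd <- extract_components(disk, pixel_size = 1)
  expect_equal(nrow(cd), 1)
  expect_equal(cd$area_px, pi * 100, tolerance = 0.01)
  expect_equal(cd$orientation_class, "transverse")
  expect_false(cd$lumen_present)

  # annulus outer 20 inner 10: lumen detected from the enclosed hole
  ann <- (((rows - 32)^2 + (cols - 32)^2 <= 400) &
            ((rows - 32)^2 + (cols - 32)^2 > 100)) * 1L
  ca <- extract_components(ann, pixel_size = 1)
  expect_true(ca$lumen_present)
  expect_equal(ca$lumen_area_um2, pi * 100, tolerance = 0.02)
  expect_lt(ca$lumen_area_um2, ca$area_um2)

  # ellipse 40 x 10 px (AR 4): longitudinal, area within 2% of pi a b
  ell <- ((((cols - 32) / 20)^2 + ((rows - 32) / 5)^2) <= 1) * 1L
  ce <- extract_components(ell, pixel_size = 1)
  expect_equal(ce$orientation_class, "longitudinal")
  expect_equal(ce$area_px, pi * 20 * 5, tolerance = 0.02)
  expect_equal(ce$aspect_ratio, 4, tolerance = 0.1)

  # empty mask: empty table, not an error
  expect_equal(nrow(extract_components(matrix(0L, 8, 8))), 0)
  expect_error(extract_components(matrix(0.5, 4, 4)), "binary")
})

test_that("two disks 30 px apart have mean nearest edge distance 20 px and
           summary ratios follow the formulas", {
  m <- two_disk_mask()
  comp <- extract_components(m, pixel_size = 1)
  expect_equal(nrow(comp), 2)
  s <- summarize_architecture(comp, tissue_area_um2 = 6400)
  expect_equal(s$mean_nearest_distance_um, 20, tolerance = 1)
  expect_equal(s$wall_area_fraction, 100 * sum(comp$area_px) / 6400)
  expect_equal(s$pct_longitudinal + s$pct_oblique + s$pct_transverse, 100,
               tolerance = 1e-6)
  # wall area of 100 px^2 in 1000 px^2 of tissue is 10%
  expect_equal(summarize_architecture(comp, sum(comp$area_um2) * 10)$wall_area_fraction,
               10, tolerance = 1e-9)
  # a single oblique/transverse component leaves the distance undefined
  one <- extract_components(two_disk_mask(centres = list(c(25, 25))), pixel_size = 1)
  expect_warning(s1 <- summarize_architecture(one, 6400), "fewer than 2")
  expect_true(is.na(s1$mean_nearest_distance_um))
})

test_that("generated masks are recovered: counts, classes and distances
           match the ground truth", {
  sim <- sim_histology_masks(mask_sim_config(seed = 4))
  comp <- extract_components(sim$capillary, sim$lumen, pixel_size = 0.5)
  truth <- sim$truth$components
  expect_equal(nrow(comp), nrow(truth))
  expect_equal(table(comp$orientation_class)[names(table(truth$class))],
               table(truth$class))
  s <- summarize_architecture(comp, tissue_area_um2 = sum(sim$capillary == 0) * 0.25)
  class_truth <- sapply(c("longitudinal", "oblique", "transverse"), function(cl)
    100 * sum(truth$wall_px[truth$class == cl]) / sum(truth$wall_px))
  expect_equal(c(s$pct_longitudinal, s$pct_oblique, s$pct_transverse),
               unname(class_truth), tolerance = 1)
  expect_equal(s$mean_nearest_distance_um,
               mean(sim$truth$nearest_distances$nearest_px) * 0.5,
               tolerance = 0.5)
})

test_that("areas scale as pixel_size^2 and distances as pixel_size; the
           summary is invariant under rotation and translation", {
  m <- two_disk_mask()
  c1 <- extract_components(m, pixel_size = 1)
  c2 <- extract_components(m, pixel_size = 2.5)
  expect_equal(c2$area_um2, c1$area_um2 * 2.5^2)
  s1 <- summarize_architecture(c1, 6400)
  s2 <- summarize_architecture(c2, 6400 * 2.5^2)
  expect_equal(s2$mean_nearest_distance_um, s1$mean_nearest_distance_um * 2.5)
  expect_equal(s2$wall_area_fraction, s1$wall_area_fraction)

  # 90-degree rotation and translation leave the summary unchanged
  rot <- t(m)[ncol(m):1, ]
  sr <- summarize_architecture(extract_components(rot, pixel_size = 1), 6400)
  expect_equal(sr$mean_nearest_distance_um, s1$mean_nearest_distance_um,
               tolerance = 1)
  expect_equal(sr$wall_area_fraction, s1$wall_area_fraction)
  shifted <- matrix(0L, 80, 80)
  shifted[6:80, 1:70] <- m[1:75, 11:80]
  ss <- summarize_architecture(extract_components(shifted, pixel_size = 1), 6400)
  expect_equal(ss$mean_nearest_distance_um, s1$mean_nearest_distance_um,
               tolerance = 1)
})

test_that("collagen fraction follows the pixel-count formula", {
  col <- matrix(FALSE, 10, 10); col[1:5, 1:5] <- TRUE   # 25 px
  myo <- matrix(TRUE, 10, 10); myo[col] <- FALSE        # 75 px
  expect_equal(collagen_fraction(col, myo)$collagen_percent, 25)
  expect_equal(collagen_fraction(matrix(FALSE, 4, 4),
                                 matrix(TRUE, 4, 4))$collagen_percent, 0)
  expect_error(collagen_fraction(col, col), "overlap")
  expect_warning(r <- collagen_fraction(matrix(FALSE, 2, 2),
                                        matrix(FALSE, 2, 2)), "empty")
  expect_true(is.na(r$collagen_percent))
  # generator target recovered within half a point
  sim <- sim_histology_masks(mask_sim_config(seed = 12))
  cf <- collagen_fraction(sim$collagen, sim$myocardium)
  expect_equal(cf$collagen_percent, 19.6, tolerance = 0.5)
})

test_that("8-connectivity joins diagonally touching pixels", {
  m <- matrix(0L, 6, 6)
  m[2, 2] <- 1L; m[3, 3] <- 1L; m[4, 2] <- 1L
  comp <- extract_components(m, pixel_size = 1)
  expect_equal(nrow(comp), 1)
  expect_equal(comp$area_px, 3)
})
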