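test_that("body mask excludes the CT table and matches ground truth", {
  ph <- generate_phantom(small_spec(seed = 1))  # table on by default
  bm <- make_body_mask(ph$slice)
  expect_true(bm$table_removed)
  tr <- ph$truth$body_mask
  dice <- 2 * sum(bm$mask & tr) / (sum(bm$mask) + sum(tr))
  expect_gte(dice, 0.99)
  # table rows must not be in the mask
  table_px <- ph$truth$labels == 1L
  expect_equal(sum(bm$mask & table_px), 0)

  # noise-free, no table: equal up to a 1-pixel boundary band
  ph0 <- generate_phantom(small_spec(seed = 2, hu_noise_sd = 0,
                                     include_table = FALSE))
  bm0 <- make_body_mask(ph0$slice)
  band <- ph0$truth$body_mask & !adipoct:::erode_by(ph0$truth$body_mask, 1.5)
  mismatch <- xor(bm0$mask, ph0$truth$body_mask)
  expect_true(all(mismatch[!band] == FALSE))
})

test_that("an all-air image is a segmentation failure", {
  air <- ct_slice(matrix(-1000, 64, 64), c(1, 1))
  expect_error(make_body_mask(air), class = "adipoct_segmentation_failure")
})

test_that("anisotropic diffusion smooths noise but keeps edges and mean", {
  ph <- generate_phantom(small_spec(seed = 3, hu_noise_sd = 15))
  # n_iter = 0 is the identity
  expect_identical(denoise(ph$slice, n_iter = 0)$hu, ph$slice$hu)
  # constant image unchanged
  const <- ct_slice(matrix(10, 32, 32), c(1, 1))
  expect_equal(denoise(const)$hu, const$hu, tolerance = 1e-12)

  den <- denoise(ph$slice)
  sat <- adipoct:::erode_by(generate_phantom(small_spec(seed = 3,
    hu_noise_sd = 0))$truth$sat_mask, 2)  # interior, away from edges
  sd_before <- sd(ph$slice$hu[sat])
  sd_after <- sd(den$hu[sat])
  expect_lt(sd_after, 10)
  expect_lt(sd_after, 0.7 * sd_before)   # >= 30% reduction
  expect_lt(abs(mean(den$hu) - mean(ph$slice$hu)), 0.5)

  expect_error(denoise(ph$slice, dt = 0), class = "adipoct_parameter_error")
})

test_that("adipose band threshold is a closed interval at [-274, -49] HU", {
  hu <- matrix(c(-275, -274, -150, -49, -48, 0), 1)
  slice <- ct_slice(hu, c(1, 1))
  lab <- label_adipose(slice, matrix(TRUE, 1, 6))
  expect_equal(as.vector(lab), c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))
})

test_that("noise-free phantom adipose labels equal the painted fat masks", {
  ph <- generate_phantom(small_spec(seed = 4, hu_noise_sd = 0))
  bm <- make_body_mask(ph$slice)
  lab <- label_adipose(ph$slice, bm)
  expect_identical(unclass(lab) & TRUE, ph$truth$sat_mask | ph$truth$vat_mask)
})

test_that("contours on a disk phantom are circles at the analytic radii", {
  ph <- generate_phantom(disk_spec(r = 120, sat = 20, img = 300L))
  bm <- make_body_mask(ph$slice)
  cp <- fit_contours(ph$slice, bm)
  r_ext <- sqrt(sum(cp$external_mask) / pi)
  r_int <- sqrt(sum(cp$internal_mask) / pi)
  expect_lt(abs(r_ext - 120), 1)
  expect_lt(abs(r_int - 100), 1)  # disk radius minus the 20 mm SAT ring
  expect_true(all(cp$internal_mask[!cp$external_mask] == FALSE))
})

test_that("contours capture >= 95% of ground-truth SAT and VAT", {
  for (s in c(5, 6)) {
    ph <- generate_phantom(small_spec(seed = s))
    den <- denoise(ph$slice)
    bm <- make_body_mask(ph$slice)
    cp <- fit_contours(den, bm)
    sat_between <- ph$truth$sat_mask & cp$external_mask & !cp$internal_mask
    vat_inside <- ph$truth$vat_mask & cp$internal_mask
    expect_gte(sum(sat_between) / sum(ph$truth$sat_mask), 0.95)
    expect_gte(sum(vat_inside) / sum(ph$truth$vat_mask), 0.95)
  }
})

test_that("a degenerate body mask fails contour fitting", {
  ph <- generate_phantom(small_spec(seed = 7))
  tiny <- matrix(FALSE, nrow(ph$slice$hu), ncol(ph$slice$hu))
  tiny[80:82, 80:83] <- TRUE
  expect_error(fit_contours(ph$slice, tiny),
               class = "adipoct_segmentation_failure")
})

test_that("quantification reproduces the worked VSR examples", {
  m1 <- adipose_measures(sat_area_mm2 = 18730, vat_area_mm2 = 19860)
  expect_equal(m1$sat_area_cm2, 187.3)
  expect_equal(m1$vat_area_cm2, 198.6)
  expect_equal(round(m1$vsr, 2), 1.06)
  m2 <- adipose_measures(sat_area_mm2 = 7150, vat_area_mm2 = 2340)
  expect_equal(round(m2$vsr, 2), 0.33)
})

test_that("an empty label map yields zero areas and an undefined VSR", {
  ph <- generate_phantom(small_spec(seed = 8, sat_ring_thickness = 0,
                                    visceral_fat_fraction = 0,
                                    hu_noise_sd = 0))
  bm <- make_body_mask(ph$slice)
  lab <- label_adipose(ph$slice, bm)
  cp <- fit_contours(ph$slice, bm)
  m <- quantify(lab, cp, ph$slice$pixel_spacing)
  expect_equal(m$sat_area_mm2, 0)
  expect_equal(m$vat_area_mm2, 0)
  expect_false(m$vsr_defined)
  expect_true(is.na(m$vsr))
})

test_that("areas scale with the pixel-area factor and VSR is scale-free", {
  ph <- generate_phantom(small_spec(seed = 9))
  bm <- make_body_mask(ph$slice)
  lab <- label_adipose(denoise(ph$slice), bm)
  cp <- fit_contours(denoise(ph$slice), bm)
  m1 <- quantify(lab, cp, c(2.2, 2.2))
  m2 <- quantify(lab, cp, c(4.4, 4.4))
  expect_equal(m2$sat_area_mm2, 4 * m1$sat_area_mm2)
  expect_equal(m2$vat_area_mm2, 4 * m1$vat_area_mm2)
  expect_equal(m2$vsr, m1$vsr)
})

test_that("full segmentation recovers phantom areas within 5%", {
  ph <- generate_phantom(small_spec(seed = 10))
  res <- segment_slice(ph$slice)
  expect_equal(res$status, "ok")
  expect_lte(abs(res$measures$sat_area_mm2 - ph$truth$sat_area_mm2) /
               ph$truth$sat_area_mm2, 0.05)
  expect_lte(abs(res$measures$vat_area_mm2 - ph$truth$vat_area_mm2) /
               ph$truth$vat_area_mm2, 0.05)
  # determinism
  res2 <- segment_slice(ph$slice)
  expect_identical(res$measures[c("sat_area_mm2", "vat_area_mm2", "vsr")],
                   res2$measures[c("sat_area_mm2", "vat_area_mm2", "vsr")])
})

test_that("SAT and VAT are disjoint subsets of the adipose map", {
  ph <- generate_phantom(small_spec(seed = 12))
  res <- segment_slice(ph$slice)
  lab <- unclass(res$labels)
  sat_px <- lab & res$contours$external_mask & !res$contours$internal_mask
  vat_px <- lab & res$contours$internal_mask
  expect_equal(sum(sat_px & vat_px), 0)
  expect_true(all(lab[sat_px | vat_px]))
  expect_lte(res$measures$sat_area_mm2 + res$measures$vat_area_mm2,
             sum(lab) * prod(ph$slice$pixel_spacing) + 1e-9)
})

test_that("a SAT-only phantom yields near-zero VAT", {
  ph <- generate_phantom(small_spec(seed = 13, visceral_fat_fraction = 0))
  res <- segment_slice(ph$slice)
  expect_lt(res$measures$vat_area_mm2, 0.02 * res$measures$sat_area_mm2)
})

test_that("segmentation failure propagates as a tool-failure result", {
  air <- ct_slice(matrix(-1000 + rnorm(64^2), 64, 64), c(1, 1))
  res <- segment_slice(air)
  expect_equal(res$status, "tool_failure")
  expect_equal(res$failed_stage, "body_mask")
})

test_that("QA rendering paints VAT gold pixel-for-pixel and writes a file", {
  ph <- generate_phantom(small_spec(seed = 14))
  res <- segment_slice(ph$slice)
  f <- withr::local_tempfile(fileext = ".png")
  render_qa(ph$slice, res$labels, res$contours, res$measures, f)
  expect_true(file.exists(f))
  img <- png::readPNG(f)
  gold <- img[, , 1] == 1 & abs(img[, , 2] - 0.84) < 0.01 & img[, , 3] == 0
  vat_px <- unclass(res$labels) & res$contours$internal_mask
  expect_equal(sum(gold), sum(vat_px))
  blue <- abs(img[, , 1] - 0.12) < 0.01 & abs(img[, , 2] - 0.35) < 0.01
  sat_px <- unclass(res$labels) & res$contours$external_mask &
    !res$contours$internal_mask
  expect_equal(sum(blue), sum(sat_px))
})

test_that("QA rendering of an empty segmentation has no overlay pixels", {
  ph <- generate_phantom(small_spec(seed = 15, sat_ring_thickness = 0,
                                    visceral_fat_fraction = 0,
                                    hu_noise_sd = 0))
  res <- segment_slice(ph$slice)
  f <- withr::local_tempfile(fileext = ".png")
  render_qa(ph$slice, res$labels, res$contours, res$measures, f)
  img <- png::readPNG(f)
  gold <- img[, , 1] == 1 & abs(img[, , 2] - 0.84) < 0.01 & img[, , 3] == 0
  expect_equal(sum(gold), 0)
})
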