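test_that("a noiseless binary disk at an exact pixel centre is found to sub-pixel accuracy", {
  img <- disk_image(64, 64, 32, 32, 20)
  circ <- detect_phantom(img)
  expect_lt(abs(circ$center_row - 32), 0.1)
  expect_lt(abs(circ$center_col - 32), 0.1)
  expect_lt(abs(circ$radius - 20), 1)
})

test_that("detection recovers simulated centres and radii to sub-pixel accuracy", {
  set.seed(42)
  for (i in 1:5) {
    cr <- runif(1, 110, 150); cc <- runif(1, 110, 150); rad <- runif(1, 70, 95)
    cfg <- qa_scenario("se", center_px = c(cr, cc), radius_px = rad,
                       noise_sigma = 2, shading_depth = 0, ghost_fraction = 0,
                       seed = i)
    circ <- detect_phantom(get_slice(simulate_se(cfg)))
    expect_lt(abs(circ$center_row - cr), 0.5)
    expect_lt(abs(circ$center_col - cc), 0.5)
    expect_lt(abs(circ$radius - rad), 1)
  }
})

test_that("detection is rotation-consistent", {
  cfg <- qa_scenario("se", matrix = c(128, 128), center_px = c(55, 70),
                     radius_px = 35, noise_sigma = 2, seed = 9)
  img <- get_slice(simulate_se(cfg))
  c0 <- detect_phantom(img)
  c90 <- detect_phantom(t(img[nrow(img):1, ]))  # 90 degree rotation
  expect_lt(abs(c90$center_row - c0$center_col), 0.5)
  expect_lt(abs(c90$center_col - (nrow(img) + 1 - c0$center_row)), 0.5)
  expect_lt(abs(c90$radius - c0$radius), 0.5)
})

test_that("degenerate images raise the documented detection errors", {
  expect_error(detect_phantom(matrix(0, 32, 32)), "phantom not found")
  tiny <- matrix(0, 64, 64); tiny[30:31, 30:31] <- 100  # < 1% of the area
  expect_error(detect_phantom(tiny), "phantom not found")
  full <- matrix(100, 32, 32); full[16, 16] <- 0  # foreground on all borders
  expect_error(detect_phantom(full), "not separable")
})

test_that("large-ROI area and square ROI match their geometric definitions", {
  img <- disk_image(256, 256, 128, 128, 100)
  circ <- detect_phantom(img)
  roi <- build_structural_rois(circ, img, c(0.9766, 0.9766), pe_axis = "row")
  expected <- pi * (0.8 * circ$radius)^2
  expect_lt(abs(sum(roi$large_circle_mask) - expected) / expected, 0.02)
  expect_equal(sum(roi$square_roi_mask), 225)
  sq <- which(roi$square_roi_mask, arr.ind = TRUE)
  expect_equal(range(sq[, 1]), round(circ$center_row) + c(-7, 7))
  expect_equal(range(sq[, 2]), round(circ$center_col) + c(-7, 7))
})

test_that("small ROIs lie inside the large ROI and backgrounds clear the dilated phantom", {
  se <- simulate_se(qa_scenario("se", seed = 2))
  img <- get_slice(se)
  circ <- detect_phantom(img)
  roi <- build_structural_rois(circ, img, se$pixel_spacing_mm, pe_axis = "row")
  expect_true(all(roi$large_circle_mask[roi$min_roi_mask]))
  expect_true(all(roi$large_circle_mask[roi$max_roi_mask]))
  # ~1 cm^2 and ~10 cm^2 achieved areas
  expect_lt(abs(roi$small_roi_area_mm2 - 100) / 100, 0.05)
  expect_true(all(abs(roi$bg_area_mm2 - 1000) / 1000 < 0.05))
  # phantom mask dilated by 2 px must be disjoint from every rectangle
  dil <- circle_mask_for_test(dim(img), circ$center_row, circ$center_col,
                              circ$radius + 2)
  for (bg in list(roi$bg_fe1, roi$bg_fe2, roi$bg_pe1, roi$bg_pe2)) {
    expect_gt(sum(bg), 0)
    expect_false(any(bg & dil))
  }
})

test_that("swapping the phase-encode axis swaps the FE and PE rectangle pairs exactly", {
  img <- disk_image(256, 256, 128, 128, 90)
  circ <- detect_phantom(img)
  a <- build_structural_rois(circ, img, c(1, 1), pe_axis = "row")
  b <- build_structural_rois(circ, img, c(1, 1), pe_axis = "col")
  expect_identical(a$bg_pe1, b$bg_fe1)
  expect_identical(a$bg_pe2, b$bg_fe2)
  expect_identical(a$bg_fe1, b$bg_pe1)
  expect_identical(a$bg_fe2, b$bg_pe2)
})

test_that("an oversized phantom leaves no room for background rectangles", {
  img <- disk_image(128, 128, 64, 64, 55)
  circ <- detect_phantom(img)
  expect_error(build_structural_rois(circ, img, c(1, 1), pe_axis = "row"),
               "insufficient background margin")
})

test_that("extreme-ROI search matches the brute-force scan exactly on small images", {
  set.seed(7)
  for (i in 1:3) {
    img <- matrix(runif(48 * 48, 50, 150), 48, 48)
    mask <- circle_mask_for_test(c(48, 48), 24, 24, 18)
    got <- locate_extreme_rois(img, mask, c(1, 1), roi_area_mm2 = 20)
    want <- brute_extreme_rois(img, mask, c(1, 1), area_mm2 = 20)
    expect_identical(got$min_center, want$min_center)
    expect_identical(got$max_center, want$max_center)
    expect_equal(got$s_min, want$s_min, tolerance = 1e-12)
    expect_equal(got$s_max, want$s_max, tolerance = 1e-12)
  }
})

test_that("a dark notch attracts the minimal ROI and a shading ramp separates the extremes", {
  img <- disk_image(96, 96, 48, 48, 35, value = 100)
  img[40:56, 60:70] <- 20  # dark notch inside the phantom
  mask <- circle_mask_for_test(c(96, 96), 48, 48, 28)
  got <- locate_extreme_rois(img, mask, c(1, 1), roi_area_mm2 = 30)
  expect_true(got$min_center[1] %in% 40:56 && got$min_center[2] %in% 58:72)
  expect_lt(got$s_min, 60)

  ramp <- outer(seq_len(96), rep(1, 96)) + 100  # linear shading along rows
  got2 <- locate_extreme_rois(ramp, mask, c(1, 1), roi_area_mm2 = 30)
  want2 <- brute_extreme_rois(ramp, mask, c(1, 1), area_mm2 = 30)
  expect_identical(got2$min_center, want2$min_center)
  expect_identical(got2$max_center, want2$max_center)
  # opposite ends of the ramp along its gradient (rows), same column
  expect_lt(got2$min_center[1], 48 - 15)
  expect_gt(got2$max_center[1], 48 + 15)
  expect_equal(got2$min_center[2], got2$max_center[2])
})

test_that("a perfectly uniform disk gives equal extreme means", {
  img <- disk_image(64, 64, 32, 32, 25, value = 80)
  mask <- circle_mask_for_test(c(64, 64), 32, 32, 18)
  got <- locate_extreme_rois(img, mask, c(1, 1), roi_area_mm2 = 20)
  expect_equal(got$s_min, 80)
  expect_equal(got$s_max, 80)
})

test_that("kernel larger than the signal ROI is rejected", {
  img <- matrix(1, 32, 32)
  mask <- circle_mask_for_test(c(32, 32), 16, 16, 3)
  expect_error(locate_extreme_rois(img, mask, c(1, 1), roi_area_mm2 = 200),
               "signal ROI too small")
})

test_that("masks are pure functions of their inputs", {
  se <- simulate_se(qa_scenario("se", seed = 4, matrix = c(128, 128),
                                radius_px = 40))
  img <- get_slice(se)
  circ <- detect_phantom(img)
  a <- build_structural_rois(circ, img, se$pixel_spacing_mm, pe_axis = "row")
  b <- build_structural_rois(circ, img, se$pixel_spacing_mm, pe_axis = "row")
  expect_identical(a, b)
})
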