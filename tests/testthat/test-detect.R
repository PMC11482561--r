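test_that("blank and constant rasters yield no detections", {
  cfg <- detector_config(radius_min_px = 2, radius_max_px = 6)
  expect_identical(nrow(detect_circles(matrix(100, 64, 64), cfg)), 0L)
  noisy <- matrix(rnorm(64 * 64, 100, 5), 64, 64)
  expect_identical(nrow(detect_circles(noisy, cfg)), 0L)
})

test_that("radius range larger than the image is rejected by name", {
  expect_error(detect_circles(matrix(0, 20, 20),
                              detector_config(radius_min_px = 2, radius_max_px = 12)),
               "radius range")
})

test_that("a single high-contrast disc is recovered within 1 px", {
  img <- disc_raster(100, 100, cx = 40, cy = 60, radius = 6, amp = 1000)
  det <- detect_circles(img, detector_config(radius_min_px = 2, radius_max_px = 9))
  expect_identical(nrow(det), 1L)
  expect_lt(abs(det$x - 40), 1)
  expect_lt(abs(det$y - 60), 1)
  expect_lt(abs(det$radius_px - 6), 1)
})

test_that("detection is deterministic and translation-equivariant", {
  img <- disc_raster(80, 80, cx = 30, cy = 35, radius = 5, amp = 800)
  cfg <- detector_config()
  expect_identical(detect_circles(img, cfg), detect_circles(img, cfg))
  # shift by (7, 4) px using an embedding that keeps the disc interior
  img2 <- disc_raster(80, 80, cx = 37, cy = 39, radius = 5, amp = 800)
  d1 <- detect_circles(img, cfg); d2 <- detect_circles(img2, cfg)
  expect_identical(nrow(d1), 1L)
  expect_identical(d2$x, d1$x + 7)
  expect_identical(d2$y, d1$y + 4)
  expect_equal(d2$radius_px, d1$radius_px, tolerance = 1e-9)
})

test_that("detections agree with an exhaustive brute-force circle search", {
  for (case in list(c(20, 25, 5), c(31, 18, 7), c(24, 40, 4))) {
    img <- disc_raster(64, 64, cx = case[1], cy = case[2], radius = case[3],
                       amp = 900)
    det <- detect_circles(img, detector_config(radius_min_px = 3, radius_max_px = 9))
    bf <- circle_bruteforce(img, edge_threshold = 60, r_range = c(3, 9))
    expect_identical(nrow(det), 1L)
    expect_lte(abs(det$x[1] - bf$x), 1)
    expect_lte(abs(det$y[1] - bf$y), 1)
  }
})

test_that("rendered fields are recovered with high recall and no duplicates", {
  sp <- field_spec(wbc_conc = 800, rbc_conc = 500, artifact_rate = 0, seed = 123)
  out <- render_field(sp)
  det <- detect_field(out$image)
  m <- match_detections(det, out$truth, tol = 2)
  expect_gte(m$recall, 29 / 30)
  expect_identical(m$precision, 1)
})

test_that("size filtering keeps exactly the in-interval radii in order", {
  det <- data.frame(x = 1:3, y = 1:3, radius_px = c(1.0, 3.5, 6.0), score = 1)
  expect_identical(nrow(filter_by_size(det[0, ], c(2.5, 7), 1)), 0L)
  kept <- filter_by_size(det, c(2.5, 7), 1)
  expect_equal(kept$radius_px, c(3.5, 6.0))
  expect_identical(filter_by_size(det, c(0, Inf), 1), det)
  # closed interval: boundary radii survive
  expect_equal(filter_by_size(det, c(3.5, 6.0), 1)$radius_px, c(3.5, 6.0))
  expect_error(filter_by_size(det, c(7, 2.5), 1), "non-empty")
  expect_error(filter_by_size(det, c(2.5, 7), 0), "pixel_size_um")
  # micrometre conversion: 2 um/px doubles the physical radius
  expect_equal(filter_by_size(det, c(6, 13), 2)$radius_px, c(3.5, 6.0))
})

test_that("disc intensity is disc mean minus annulus median, exactly on flat input", {
  img <- disc_raster(60, 60, cx = 30, cy = 30, radius = 5, amp = 0, background = 50)
  # paint an exact hard disc of value 700 on background 50
  for (i in 1:60) for (j in 1:60)
    if (sqrt((j - 1 - 30)^2 + (i - 1 - 30)^2) <= 5) img[i, j] <- 700
  det <- data.frame(x = 30, y = 30, radius_px = 5, score = 2)
  out <- measure_intensities(det, img, matrix(50, 60, 60))
  expect_equal(out$gf_intensity, 700 - 50)
  expect_equal(out$cf_intensity, 0)
  expect_false(out$edge)
})

test_that("synthetic WBC intensities match generator amplitudes", {
  sp <- field_spec(wbc_conc = 400, seed = 21)
  out <- render_field(sp)
  det <- detect_field(out$image)
  tr <- out$truth
  expect_gt(nrow(det), 0)
  for (i in seq_len(nrow(det))) {
    j <- which.min((tr$x - det$x[i])^2 + (tr$y - det$y[i])^2)
    # soft edge lowers the disc mean slightly below the peak amplitude
    expect_gt(det$gf_intensity[i], 0.6 * tr$gf_amp[j])
    expect_lt(det$gf_intensity[i], 1.1 * tr$gf_amp[j])
    expect_lt(abs(det$cf_intensity[i]), 60)
  }
})

test_that("annulus exclusion keeps neighbor cells out of the background", {
  iso <- disc_raster(80, 80, cx = 30, cy = 40, radius = 5, amp = 1000)
  det1 <- data.frame(x = 30, y = 40, radius_px = 5, score = 2)
  v_iso <- measure_intensities(det1, iso, iso * 0 + 100)$gf_intensity
  # neighbor disc whose body overlaps the first disc's annulus
  pair <- disc_raster(80, 80, cx = 43, cy = 40, radius = 5, amp = 1000)
  pair <- pair + iso - 100
  det2 <- data.frame(x = c(30, 43), y = c(40, 40), radius_px = c(5, 5), score = 2)
  v_pair <- measure_intensities(det2, pair, pair * 0 + 100)$gf_intensity[1]
  expect_lt(abs(v_pair - v_iso) / v_iso, 0.05)
})

test_that("discs clipped by the raster border are flagged edge", {
  img <- disc_raster(60, 60, cx = 3, cy = 30, radius = 5, amp = 500)
  det <- data.frame(x = 3, y = 30, radius_px = 5, score = 2)
  out <- measure_intensities(det, img, img)
  expect_true(out$edge)
  expect_true(is.finite(out$gf_intensity))
})
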