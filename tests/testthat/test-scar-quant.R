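ph <- make_lv_phantom(small_phantom_config())
geom_mid <- ph$ground_truth$geometry[[3]]
geom_apex <- ph$ground_truth$geometry[[5]]

test_that("basal/mid slices get 6 segments, apical 4, on the annulus only", {
  sm6 <- build_segment_map(geom_mid)
  sm4 <- build_segment_map(geom_apex)
  expect_equal(sm6$n_segments, 6L)
  expect_equal(sm4$n_segments, 4L)
  expect_setequal(setdiff(unique(as.vector(sm6$labels)), 0L), 1:6)
  expect_setequal(setdiff(unique(as.vector(sm4$labels)), 0L), 1:4)
  expect_true(all((sm6$labels > 0) == sm6$annulus))
})

test_that("equal sectors have equal pixel counts up to discretization", {
  sm <- build_segment_map(geom_mid)
  counts <- tabulate(sm$labels[sm$labels > 0], nbins = 6)
  perimeter_px <- 2 * pi * (geom_mid$pixel_spacing * 0 + 25 / 1.65)
  expect_lt(max(counts) - min(counts), perimeter_px)
})

test_that("intersecting contours and inside reference points are rejected", {
  big <- circle_contour_for_tests(32.5, 12)
  small <- circle_contour_for_tests(32.5, 6)
  expect_error(lv_geometry(big, small, c(60, 32.5), image_dim = c(64, 64)),
               "intersect")
  expect_error(lv_geometry(small, big, c(32.5, 32.5), image_dim = c(64, 64)),
               "outside")
})

test_that("subsegment accounting gives 28 per patient and 644 for 23 patients", {
  std <- c("basal", "basal", "mid", "mid", "apical")
  expect_equal(subsegment_count(std), 28L)
  expect_equal(subsegment_count("apical"), 4L)
  expect_equal(23L * subsegment_count(std), 644L)
  expect_error(subsegment_count(character(0)), "nonempty")
  expect_error(subsegment_count("septal"), "basal")
})

test_that("reference ROI statistics match a two-pass oracle and enforce size", {
  img <- matrix(10, 30, 30)
  roi <- matrix(FALSE, 30, 30)
  roi[1:10, 1:15] <- TRUE  # 150 px
  rs <- reference_roi_stats(img, roi)
  expect_equal(rs$mean, 10)
  expect_equal(rs$sd, 0)
  expect_equal(rs$npixels, 150L)

  set.seed(21)
  img[] <- rnorm(900)
  roi2 <- matrix(FALSE, 30, 30)
  roi2[1:20, 1:20] <- TRUE  # 400 px
  rs2 <- reference_roi_stats(img, roi2)
  vals <- img[which(roi2)]
  # two-pass oracle
  m <- sum(vals) / length(vals)
  s <- sqrt(sum((vals - m)^2) / (length(vals) - 1))
  expect_equal(rs2$mean, m, tolerance = 1e-12)
  expect_equal(rs2$sd, s, tolerance = 1e-12)

  roi99 <- matrix(FALSE, 30, 30)
  roi99[1:9, 1:11] <- TRUE  # 99 px
  expect_error(reference_roi_stats(img, roi99), "99 pixels.*100")
})

test_that("an image at the ROI mean yields an empty scar mask", {
  sm <- build_segment_map(geom_mid)
  img <- matrix(10, 64, 64)
  rs <- reference_roi_stats(img, sm$annulus)
  res <- segment_scar(img, sm, rs)
  expect_equal(res$scar_pixels, 0L)
  expect_true(all(!res$scar_mask))
  # sd = 0 with constant image: empty mask, no error
  expect_equal(res$threshold, 10)
})

test_that("a supra-threshold wedge is recovered pixel-exactly", {
  cfg <- small_phantom_config(scar_specs = list(scar_spec(3, 40, 65, 0.55)))
  ph2 <- make_lv_phantom(cfg)
  gt <- ph2$ground_truth
  img <- noisy_esge_image_noiseless(ph2, 3)
  sm <- build_segment_map(gt$geometry[[3]])
  roi <- gt$annulus[[3]] & !gt$scar_mask[[3]]
  rs <- reference_roi_stats(img, roi)
  res <- segment_scar(img, sm, rs)
  expect_equal(res$scar_pixels, sum(gt$scar_mask[[3]]))
  expect_equal(res$scar_mask, gt$scar_mask[[3]])
})

test_that("recovered mass is within 5% of ground truth at 10-sigma contrast", {
  cfg <- small_phantom_config(scar_specs = list(scar_spec(3, 20, 70, 0.6)))
  ph2 <- make_lv_phantom(cfg)
  truth <- ph2$ground_truth$scar_mass_g[3]
  # scar-vs-myocardium contrast at the nulled TI, noise at a tenth of it
  contrast <- abs(ir_signal(cfg$t1_scar, 350) - ir_signal(cfg$t1_myocardium, 350))
  sigma <- contrast / 10
  set.seed(100)
  errs <- vapply(1:100, function(i) {
    img <- noisy_esge_image(ph2, 3, sigma)
    q <- quantify_scar(list(img), list(ph2$ground_truth$geometry[[3]]))
    abs(q$total_mass_g - truth) / truth
  }, numeric(1))
  expect_lt(max(errs), 0.05)
})

test_that("raising the threshold never adds scar pixels (5SD within 4SD)", {
  cfg <- small_phantom_config(scar_specs = list(scar_spec(2, 110, 55, 0.5)))
  ph2 <- make_lv_phantom(cfg)
  set.seed(8)
  img <- noisy_esge_image(ph2, 2, 0.02)
  sm <- build_segment_map(ph2$ground_truth$geometry[[2]])
  roi <- ph2$ground_truth$annulus[[2]] & !ph2$ground_truth$scar_mask[[2]]
  rs <- reference_roi_stats(img, roi)
  m5 <- segment_scar(img, sm, rs, n_sd = 5)$scar_mask
  m4 <- segment_scar(img, sm, rs, n_sd = 4)$scar_mask
  expect_true(all(m4[m5]))  # 5-SD mask is a subset of the 4-SD mask
})

test_that("mass arithmetic is dimensionally correct, linear, and additive", {
  expect_equal(mass_from_pixels(0), 0)
  # unit-analysis oracle: mm^2 * mm -> mm^3, /1000 -> ml, * g/ml
  expect_equal(mass_from_pixels(1000, 1.65, 8, 1.05),
               1000 * (1.65^2 * 8 / 1000) * 1.05)
  expect_equal(round(mass_from_pixels(1000, 1.65, 8, 1.05), 2), 22.87)
  expect_equal(mass_from_pixels(500, 1.65, 16, 1.05),
               2 * mass_from_pixels(500, 1.65, 8, 1.05))

  cfg <- small_phantom_config(scar_specs = list(scar_spec(3, 20, 70, 0.6),
                                                scar_spec(3, 200, 40, 0.4)))
  ph2 <- make_lv_phantom(cfg)
  img <- noisy_esge_image_noiseless(ph2, 3)
  q <- quantify_scar(list(img), list(ph2$ground_truth$geometry[[3]]))
  expect_equal(sum(q$subsegments$mass_g), q$slices$scar_mass_g[1])
  expect_equal(q$slices$scar_mass_g[1],
               mass_from_pixels(q$slices$scar_pixels[1]))
})

test_that("subsegment calls follow geometric containment", {
  sm <- build_segment_map(geom_mid)
  roi_img <- matrix(0, 64, 64)
  rs <- structure(list(mean = 0, sd = 0.01, npixels = 200), class = "roi_stats")

  # empty mask: all calls false
  res0 <- segment_scar(roi_img, sm, rs)
  expect_true(all(!call_subsegments(res0)))

  # wedge confined to segment 2 (60-90 degrees): only that call true
  cfg <- small_phantom_config(scar_specs = list(scar_spec(3, 65, 20, 0.5)))
  gt <- make_lv_phantom(cfg)$ground_truth
  img <- roi_img
  img[gt$scar_mask[[3]]] <- 1
  res1 <- segment_scar(img, sm, rs)
  expect_equal(which(call_subsegments(res1)), 2L)

  # wedge spanning the segment 1/2 boundary: both adjacent calls true
  cfg2 <- small_phantom_config(scar_specs = list(scar_spec(3, 45, 30, 0.5)))
  gt2 <- make_lv_phantom(cfg2)$ground_truth
  img2 <- roi_img
  img2[gt2$scar_mask[[3]]] <- 1
  expect_equal(which(call_subsegments(segment_scar(img2, sm, rs))), c(1L, 2L))

  # call consistency: positive iff per-segment pixel count > 0
  expect_equal(call_subsegments(res1), res1$segments$pixels > 0)
})

test_that("the island filter removes only sub-threshold-size components", {
  mask <- matrix(FALSE, 10, 10)
  mask[2:4, 2:4] <- TRUE   # 9 px component
  mask[8, 8] <- TRUE       # 1 px component
  out <- synthlge:::drop_small_islands(mask, 2L)
  expect_equal(sum(out), 9L)
  expect_false(out[8, 8])
})
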