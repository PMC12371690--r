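test_that("fiber_spec validates its invariants", {
  expect_error(fiber_spec(5, fiber_intensity = 0.3, background_intensity = 0.5),
               "brighter")
  expect_error(fiber_spec(5, width_modes = data.frame(mean = 2, sd = 0, weight = 1)),
               ">= 3 px")
  expect_error(fiber_spec(5, width_modes = data.frame(mean = c(5, 9), sd = c(1, 1),
                                                      weight = c(0.5, 0.6))),
               "sum to 1")
  expect_error(fiber_spec(1, width_modes = data.frame(mean = 61, sd = 0, weight = 1),
                          image_shape = c(64, 64)),
               "too small")
})

test_that("n_fibers = 0 yields pure background texture and empty truth", {
  sp <- fiber_spec(0, image_shape = c(64, 64), seed = 2,
                   texture = list(noise_sd = 0.05, corr_len = 1.5))
  out <- generate_fiber_image(sp)
  expect_equal(sum(out$truth$fiber_mask), 0)
  expect_equal(nrow(centerline_truth(out$truth)), 0)
  expect_gt(sd(out$image), 0)   # texture present
})

test_that("a straight horizontal fiber of width 11 rasterizes as an 11-row ribbon", {
  out <- generate_fiber_image(ribbon_spec(11))
  m <- out$truth$fiber_mask
  expect_equal(unique(colSums(m)), 11)
  occupied <- which(rowSums(m) > 0)
  expect_equal(length(occupied), 11)
  ct <- centerline_truth(out$truth)
  expect_true(all(ct$width == 11))
  # every centerline point lies inside the mask
  expect_true(all(m[cbind(ct$row + 1, ct$col + 1)] == 1))
})

test_that("identical (spec, seed) pairs reproduce bit-identical images", {
  sp <- quick_spec("a")
  a <- generate_fiber_image(sp)
  b <- generate_fiber_image(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$fiber_mask, b$truth$fiber_mask)
  sp2 <- sp; sp2$seed <- sp$seed + 1L
  expect_false(identical(unclass(generate_fiber_image(sp2)$image), unclass(a$image)))
})

test_that("sampled width mixture matches a standalone mixture sampler", {
  modes <- data.frame(mean = c(5, 20, 60), sd = c(1, 1, 1),
                      weight = c(1, 1, 1) / 3)
  sp <- fiber_spec(30, width_modes = modes, image_shape = c(512, 512),
                   seed = 11, texture = list(noise_sd = 0, corr_len = 0))
  out <- generate_fiber_image(sp)
  w <- vapply(out$truth$fibers, function(f) f$width, numeric(1))
  # standalone oracle: the same mixture drawn directly, large n
  set.seed(99)
  mode_i <- sample.int(3, 30000, replace = TRUE, prob = modes$weight)
  oracle <- round_odd_ref <- 2 * round((rnorm(30000, modes$mean[mode_i],
                                              modes$sd[mode_i]) - 1) / 2) + 1
  oracle <- pmax(oracle, 3)
  for (target in c(5, 20, 60)) {
    got <- w[abs(w - target) < 7]
    ref <- oracle[abs(oracle - target) < 7]
    expect_gt(length(got), 0)
    tol <- 2 * sd(ref) / sqrt(length(got))
    expect_lt(abs(mean(got) - mean(ref)), max(tol, 1))
  }
})

test_that("ground truth is geometrically consistent with the rasterized mask", {
  for (seed in 1:3) {
    sp <- fiber_spec(5, data.frame(mean = c(7, 15), sd = c(1, 1), weight = c(.5, .5)),
                     curvature = 300, image_shape = c(256, 256), seed = seed,
                     texture = list(noise_sd = 0, corr_len = 0))
    out <- generate_fiber_image(sp)
    m <- out$truth$fiber_mask
    ct <- centerline_truth(out$truth)
    # centerline points inside the mask (mask dilated by 1 px always contains them)
    expect_true(all(m[cbind(ct$row + 1, ct$col + 1)] == 1))
    # perpendicular chord at interior points equals width_truth within +/- 1 px;
    # fiber crossings can only inflate the chord, so require no short chords
    # and bulk agreement
    for (f in seq_along(out$truth$fibers)) {
      fb <- out$truth$fibers[[f]]
      np <- nrow(fb$points)
      if (np < 21) next
      ks <- round(seq(11, np - 10, length.out = 40))
      # keep points far enough from the frame that the chord stays inside
      margin <- fb$width + 2
      ks <- ks[fb$points[ks, 1] >= margin & fb$points[ks, 1] <= 255 - margin &
               fb$points[ks, 2] >= margin & fb$points[ks, 2] <= 255 - margin]
      if (length(ks) < 5) next
      chords <- vapply(ks, function(k) {
        dir <- fb$points[k + 9, ] - fb$points[k - 9, ]
        perp_chord(m, fb$points[k, ] + 1, as.numeric(dir))
      }, numeric(1))
      expect_true(all(chords >= fb$width - 1 - 1e-9))
      # crossings with other fibers can only inflate chords: judge by median.
      # tolerance: staircase quantization of oblique bands contributes up to
      # half a pixel per side and the marching oracle another quarter pixel
      expect_lte(abs(median(chords) - fb$width), 1.5 + 1e-9)
    }
  }
})

test_that("class datasets are labeled, deterministic and validated", {
  specs <- list(A = quick_spec("A", 0.8), B = quick_spec("B", 0.5))
  ds <- generate_class_dataset(specs, 4, seed = 3)
  expect_length(ds$images, 8)
  expect_equal(table(ds$labels), table(rep(c("A", "B"), each = 4)))
  ds2 <- generate_class_dataset(specs, 4, seed = 3)
  expect_identical(ds$images, ds2$images)
  # intensity gap close to the designed 0.3 difference
  mean_by <- tapply(vapply(ds$images, mean, numeric(1)), ds$labels, mean)
  gap_designed <- 0.3 * mean(ds$truths[[1]]$fiber_mask > -1) # fibers cover part only
  expect_gt(mean_by["A"] - mean_by["B"], 0.05)
  # validation
  expect_error(generate_class_dataset(specs["A"], 2), "two classes")
  expect_error(generate_class_dataset(list(A = specs$A, B = specs$A), 2),
               "identical generator parameters")
  expect_error(generate_class_dataset(setNames(specs, c("A", "A")), 2),
               "duplicate")
})

test_that("hybrid images carry exact-fraction region labels", {
  specs <- demo_class_specs(c(512, 512))
  h <- generate_hybrid_image(specs$APO, specs$PHY, 0.5, seed = 7)
  expect_equal(mean(h$truth$region_labels == 2L), 0.5, tolerance = 0.001)
  expect_error(generate_hybrid_image(specs$APO, specs$PHY, 0), "0, 1")
  expect_error(generate_hybrid_image(specs$APO, specs$PHY, 1.2), "0, 1")
  expect_error(generate_hybrid_image(specs$PHY, specs$APO, 0.5), "brighter")
  # af_region_fraction = 1: uniformly AF-dominated
  h1 <- generate_hybrid_image(specs$APO, specs$PHY, 1, seed = 7)
  tl <- region_tile_labels(h1$truth$region_labels, 224, 112)
  expect_true(all(tl$label == "APO"))
  # matrix-only: uniformly matrix class
  h0 <- generate_hybrid_image(NULL, specs$PHY, seed = 7)
  tl0 <- region_tile_labels(h0$truth$region_labels, 224, 112)
  expect_true(all(tl0$label == "PHY"))
})

test_that("half/half hybrids have AF-dominant tile fraction near 0.5", {
  specs <- demo_class_specs(c(1024, 1024))
  h <- generate_hybrid_image(specs$APO, specs$PHY, 0.5, seed = 13)
  tl <- region_tile_labels(h$truth$region_labels, 224, 112)
  expect_lt(abs(mean(tl$label == "APO") - 0.5), 0.1)
})
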