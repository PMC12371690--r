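test_that("otsu segmentation matches the exhaustive between-class-variance scan", {
  out <- generate_fiber_image(ribbon_spec(11))
  px <- unclass(out$image); attributes(px) <- list(dim = dim(px))
  mask <- segment_fibers(out$image, "otsu")
  t_oracle <- brute_force_otsu(px)
  expect_equal(unclass(mask)[, ], (px > t_oracle) * 1L,
               ignore_attr = TRUE)
  # fixed threshold between the two levels gives the identical mask
  mask_f <- segment_fibers(out$image, "fixed", threshold = 0.5)
  expect_equal(as.vector(mask_f), as.vector(mask))
  expect_equal(attr(mask_f, "method"), "fixed")
})

test_that("constant images yield an empty mask with a warning", {
  img <- grayscale_image(matrix(0.3, 16, 16))
  expect_warning(mask <- segment_fibers(img), "constant")
  expect_equal(sum(mask), 0)
})

test_that("distance transform matches brute force on structured masks", {
  # isolated pixel
  m <- matrix(0L, 9, 9); m[5, 5] <- 1L
  d <- distance_transform(m)
  expect_equal(d[5, 5], 1)
  expect_equal(sum(d > 0), 1)
  # filled disk of radius 10: max distance 10 +/- 0.5 at the center
  n <- 25
  disk <- outer(1:n, 1:n, function(i, j) ((i - 13)^2 + (j - 13)^2 <= 100) * 1L)
  dd <- distance_transform(disk)
  expect_equal(max(dd), 10, tolerance = 0.05)
  expect_equal(which.max(dd), (13 - 1) * 25 + 13)
  expect_equal(unclass(dd), brute_force_edt(disk), ignore_attr = TRUE)
  # empty mask
  expect_true(all(distance_transform(matrix(0L, 8, 8)) == 0))
  # all-foreground mask: border acts as background
  d1 <- distance_transform(matrix(1L, 7, 7))
  expect_equal(d1[4, 4], 4)
  expect_equal(d1[1, 1], 1)
})

test_that("distance map is 0 on background, positive on foreground, Lipschitz", {
  set.seed(42)
  for (i in 1:5) {
    m <- matrix(rbinom(48 * 48, 1, 0.6), 48, 48)
    d <- unclass(distance_transform(m))
    expect_true(all(d[m == 0] == 0))
    expect_true(all(d[m == 1] > 0))
    # neighbor difference bounded by sqrt(2)
    dh <- abs(d[, -1] - d[, -48]); dv <- abs(d[-1, ] - d[-48, ])
    expect_lte(max(dh, dv), sqrt(2) + 1e-9)
  }
})

test_that("skeleton of a ribbon is its middle row; single pixels survive", {
  out <- generate_fiber_image(ribbon_spec(11, row = 31))
  sk <- skeletonize(out$truth$fiber_mask)
  pts <- which(sk == 1L, arr.ind = TRUE)
  expect_gt(nrow(pts), 100)                     # spans most of the length
  expect_true(all(abs(pts[, 1] - 32) <= 1))     # within 1 px of the middle row
  nbr <- table(factor(pts[, 1]))
  # one pixel wide: each column contributes one skeleton pixel (off ends)
  expect_lte(max(tabulate(pts[, 2])), 2)
  # single pixel
  m <- matrix(0L, 7, 7); m[4, 4] <- 1L
  expect_equal(which(skeletonize(m) == 1L), 25L)
  # empty mask
  expect_equal(sum(skeletonize(matrix(0L, 8, 8))), 0)
})

test_that("plus-shaped mask skeletonizes to a junction with >2 neighbors", {
  m <- matrix(0L, 41, 41)
  m[19:23, ] <- 1L
  m[, 19:23] <- 1L
  sk <- skeletonize(m)
  nbr <- fibrilmap:::neighbor_count(unclass(sk))
  expect_gte(sum(sk == 1L & nbr > 2), 1)
})

test_that("refinement prunes short spurs, keeps long ones, and is idempotent", {
  # horizontal line with a 3-px vertical spur
  m <- matrix(0L, 21, 41)
  m[11, 5:35] <- 1L
  spur <- matrix(0L, 21, 41); spur[8:10, 20] <- 1L
  withspur <- structure(pmax(m, spur), class = c("centerline", "matrix", "array"))
  ref <- refine_centerline(withspur, spur_length = 5)
  expect_equal(sum(ref[8:10, 20]), 0)           # spur gone
  expect_equal(sum(ref[11, 5:35] == 1), 31)     # main line intact
  # 10-px spur with spur_length 5 is retained
  spur10 <- matrix(0L, 21, 41); spur10[1:10, 20] <- 1L
  withlong <- structure(pmax(m, spur10), class = c("centerline", "matrix", "array"))
  ref2 <- refine_centerline(withlong, spur_length = 5)
  expect_gt(sum(ref2[1:10, 20]), 5)
  # idempotence: refining a refined centerline changes nothing
  expect_identical(refine_centerline(ref, spur_length = 5), ref)
  ref3 <- refine_centerline(ref2, spur_length = 5)
  expect_identical(refine_centerline(ref3, spur_length = 5), ref3)
})

test_that("local width on a ribbon is exact and matches the chord oracle", {
  out <- generate_fiber_image(ribbon_spec(11))
  m <- out$truth$fiber_mask
  d <- distance_transform(m)
  cl <- refine_centerline(skeletonize(m), 5, mask = m)
  wm <- measure_local_width(d, cl)
  interior <- wm[!wm$border, ]
  expect_true(all(abs(interior$width_px - 11) <= 1))
  # oracle: perpendicular chord at each centerline pixel
  chords <- vapply(seq_len(nrow(interior)), function(i)
    chord_width(m, interior$row[i] + 1, interior$col[i] + 1), numeric(1))
  expect_true(all(abs(interior$width_px - chords) <= 1 + 1e-9))
  # nm conversion
  wm_nm <- measure_local_width(d, cl, pixel_size = 2)
  expect_equal(wm_nm$width_nm, wm_nm$width_px * 2)
  expect_equal(wm_nm$width_nm[abs(wm_nm$width_px - 11) < 1e-9][1], 22)
  # 2d convention
  wm2 <- measure_local_width(d, cl, convention = "2d")
  expect_equal(wm2$width_px, wm$width_px + 1)
  # empty centerline
  empty <- measure_local_width(d, matrix(0L, nrow(m), ncol(m)))
  expect_equal(nrow(empty), 0)
})

test_that("centerline pixels off the foreground are skipped and counted", {
  m <- matrix(0L, 9, 9); m[4:6, 2:8] <- 1L
  d <- distance_transform(m)
  cl <- matrix(0L, 9, 9); cl[5, 3:7] <- 1L; cl[1, 1] <- 1L  # one off-mask pixel
  wm <- measure_local_width(d, cl)
  expect_equal(attr(wm, "skipped"), 1)
  expect_equal(nrow(wm), 5)
})

test_that("cluster_widths is exact on separated triples and names them in order", {
  wm <- structure(data.frame(row = 0:8, col = 0:8,
                             width_px = rep(c(5, 20, 60), each = 3),
                             width_nm = NA_real_, junction = FALSE,
                             border = FALSE),
                  pixel_size = NULL, class = c("width_map", "data.frame"))
  cw <- cluster_widths(wm, k = 3)
  expect_equal(cw$stats$name, c("thin", "medium", "thick"))
  expect_equal(cw$stats$mean, c(5, 20, 60))
  expect_equal(cw$stats$sd, c(0, 0, 0))
  expect_equal(sum(cw$stats$count), nrow(wm))
  expect_true(all(diff(cw$stats$mean) > 0))
  expect_equal(as.vector(table(cw$labels)), c(3, 3, 3))
})

test_that("cluster_widths recovers three-mode samples like optimal DP k-means", {
  set.seed(5)
  vals <- c(rnorm(300, 5, 1), rnorm(300, 20, 1), rnorm(300, 60, 1))
  wm <- structure(data.frame(row = seq_along(vals), col = 0,
                             width_px = vals, width_nm = NA_real_,
                             junction = FALSE, border = FALSE),
                  pixel_size = NULL, class = c("width_map", "data.frame"))
  cw <- cluster_widths(wm, k = 3)
  oracle <- dp_kmeans_1d(vals, 3)
  expect_equal(cw$stats$mean, oracle$means, tolerance = 1e-6)
  expect_true(all(abs(cw$stats$mean - c(5, 20, 60)) < 0.5))
})

test_that("cluster_widths rejects fewer than k distinct widths", {
  wm <- structure(data.frame(row = 0:3, col = 0, width_px = c(5, 5, 9, 9),
                             width_nm = NA_real_, junction = FALSE, border = FALSE),
                  pixel_size = NULL, class = c("width_map", "data.frame"))
  expect_error(cluster_widths(wm, k = 3), "distinct")
})

test_that("width summaries are formatted as mean +/- sd in the unit measured", {
  expect_equal(fibrilmap:::format_mean_sd(20.4, 2.3, "nm"), "20 ± 2 nm")
  expect_equal(fibrilmap:::format_mean_sd(17.04, 0.52, "nm"), "17.0 ± 0.5 nm")
  expect_equal(fibrilmap:::format_mean_sd(21, 1.8, "px"), "21 ± 2 px")
})

test_that("width histogram conserves counts and validates bin width", {
  wm <- structure(data.frame(row = 0:8, col = 0,
                             width_px = c(10, 25, 40, 80, 120, 160, 12, 15, 60),
                             width_nm = NA_real_, junction = FALSE, border = FALSE),
                  pixel_size = NULL, class = c("width_map", "data.frame"))
  h <- width_histogram(wm, bin_width = 10)
  expect_equal(sum(h$count), 9)
  expect_lte(min(h$bin_lo), 10)
  expect_gte(max(h$bin_hi), 160)
  expect_error(width_histogram(wm, bin_width = 0), "positive")
  # single repeated value: one nonzero bin
  wm1 <- wm; wm1$width_px <- rep(7, 9)
  h1 <- width_histogram(wm1, 2)
  expect_equal(sum(h1$count > 0), 1)
})

test_that("width colormap clips at the 1st-99th percentile and colors clusters", {
  out <- generate_fiber_image(ribbon_spec(11))
  m <- out$truth$fiber_mask
  wm <- measure_local_width(distance_transform(m),
                            refine_centerline(skeletonize(m), 5, mask = m))
  ov <- render_width_colormap(out$image, wm)
  expect_equal(dim(ov), c(64, 128, 3))
  expect_equal(attr(ov, "limits"),
               unname(quantile(wm$width_px, c(0.01, 0.99))) + c(-0.5, 0.5))
  # constant width: the painted overlay uses a single color
  painted <- unique(apply(cbind(wm$row + 1, wm$col + 1), 1,
                          function(rc) paste(ov[rc[1], rc[2], ], collapse = ",")))
  expect_length(painted, 1)
  # three clusters give exactly three distinct colors at entry pixels
  wm3 <- structure(data.frame(row = rep(c(10, 30, 50), each = 3),
                              col = rep(c(10, 40, 70), 3),
                              width_px = rep(c(5, 20, 60), each = 3),
                              width_nm = NA_real_, junction = FALSE,
                              border = FALSE),
                   pixel_size = NULL, class = c("width_map", "data.frame"))
  cw <- cluster_widths(wm3, 3)
  ov3 <- render_width_colormap(out$image, wm3, clusters = cw, dot_radius = 0)
  cols <- unique(apply(cbind(wm3$row + 1, wm3$col + 1), 1,
                       function(rc) paste(ov3[rc[1], rc[2], ], collapse = ",")))
  expect_length(cols, 3)
})
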