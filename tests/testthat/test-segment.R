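test_that("HSI conversion matches the classical formulas", {
  gray <- rgb_to_hsi(array(77, c(1, 1, 3)))
  expect_equal(gray[1, 1, 2], 0)
  red <- rgb_to_hsi(array(c(255, 0, 0), c(1, 1, 3)))
  expect_equal(red[1, 1, 2], 1)
  px <- rgb_to_hsi(array(c(100, 200, 50), c(1, 1, 3)))
  expect_equal(px[1, 1, 3], 350 / 3, tolerance = 1e-9)
  expect_equal(px[1, 1, 2], 1 - 150 / 350, tolerance = 1e-9)
})

test_that("contrast stretch is a clipped linear percentile map", {
  full <- matrix(c(0, 255, 100, 30), 2, 2)
  expect_equal(adjust_contrast(full, 0, 100), full)
  ramp <- matrix(seq(50, 100, length.out = 51), ncol = 1)
  out <- adjust_contrast(ramp, 0, 100)
  expect_equal(out[1], 0)
  expect_equal(out[51], 255)
  expect_equal(out[26], 127.5)   # 75 sits halfway
  expect_true(all(diff(out[, 1]) >= 0))
  # non-constant inputs always reach the full range
  set.seed(3)
  x <- matrix(runif(100, 20, 90), 10, 10)
  y <- adjust_contrast(x, 0, 100)
  expect_equal(range(y), c(0, 255))
  # constant image returned unchanged
  cst <- matrix(42, 4, 4)
  expect_equal(adjust_contrast(cst), cst)
})

test_that("global threshold maximises between-class variance (Otsu)", {
  img <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  bw <- global_threshold(img)
  expect_true(all(bw[img == 200] == 1L))
  expect_true(all(bw[img == 10] == 0L))
  expect_warning(z <- global_threshold(matrix(0, 5, 5)), "constant")
  expect_true(all(z == 0L))
  # agreement with the brute-force criterion, and polarity symmetry
  set.seed(21)
  for (i in 1:5) {
    x <- matrix(sample(0:255, 400, replace = TRUE,
                       prob = dnorm(0:255, sample(c(60, 180), 1), 30)),
                20, 20)
    bw <- suppressWarnings(global_threshold(x))
    expect_identical(attr(bw, "threshold"), oracle_otsu(x))
    # inverting intensities and polarity yields the complementary mask
    inv <- suppressWarnings(global_threshold(255 - x))
    expect_identical(inv > 0, !(bw > 0))
  }
})

draw_disc <- function(mask, r0, c0, radius) {
  for (r in seq_len(nrow(mask))) {
    for (c in seq_len(ncol(mask))) {
      if ((r - r0)^2 + (c - c0)^2 <= radius^2) mask[r, c] <- 1L
    }
  }
  mask
}

test_that("marker-controlled watershed splits touching discs", {
  one <- draw_disc(matrix(0L, 40, 40), 20, 20, 10)
  lab1 <- split_touching_nuclei(one)
  expect_equal(max(lab1), 1L)
  expect_identical(lab1 > 0, one > 0)

  two <- draw_disc(matrix(0L, 50, 60), 25, 22, 10)
  two <- draw_disc(two, 25, 37, 10)   # centers 15 px apart, overlapping
  lab2 <- split_touching_nuclei(two)
  expect_equal(max(lab2), 2L)
  # partition contract: every foreground pixel gets exactly one label
  expect_identical(lab2 > 0, two > 0)
  # empty input
  expect_equal(max(split_touching_nuclei(matrix(0L, 10, 10))), 0L)
})

test_that("mask cleanup removes small objects and smooths boundaries", {
  tiny <- matrix(0L, 20, 20); tiny[5, 5:6] <- 1L
  ns <- clean_mask(tiny, min_area = 30)
  expect_equal(nrow(ns$centroids), 0L)
  expect_equal(nrow(clean_mask(matrix(0L, 8, 8))$centroids), 0L)

  # disc with one-pixel protrusion: opening removes the protrusion,
  # matching an independent erosion-then-dilation composition
  disc <- draw_disc(matrix(0L, 30, 30), 15, 15, 8)
  spiky <- disc; spiky[15, 24] <- 1L  # protrusion off the boundary
  ns2 <- clean_mask(spiky, min_area = 10, se_radius = 2)
  ref <- nucleiclust:::binary_dilate(
    nucleiclust:::binary_erode(
      nucleiclust:::binary_erode(
        nucleiclust:::binary_dilate(spiky, 2), 2), 2), 2)
  expect_identical(ns2$mask > 0, ref > 0)
  # centroid is the pixel-coordinate mean (0-based)
  idx <- which(ns2$mask == 1L)
  expect_equal(ns2$centroids$row, mean((idx - 1) %% 30))
  expect_equal(ns2$centroids$col, mean((idx - 1) %/% 30))
})

test_that("full segmentation recovers synthetic ground truth", {
  blank <- array(255, dim = c(64, 64, 3))
  expect_equal(nrow(segment_nuclei(blank)$centroids), 0L)

  sp <- patch_spec(size = 256, n_clusters = 5, nuclei_per_cluster = 8,
                   cluster_spread = 14, cluster_sep = 60, seed = 31)
  p <- generate_patch(sp)
  ns <- segment_nuclei(p$image)
  expect_true(abs(nrow(ns$centroids) - 40) <= 4)  # within 10 %
  mr <- match_rate(as.matrix(p$centroids[, c("row", "col")]),
                   as.matrix(ns$centroids[, c("row", "col")]), radius = 5)
  expect_gte(mr["recall"], 0.9)
  expect_gte(mr["precision"], 0.9)
  # centroid localisation better than 3 px on matched nuclei
  d2 <- outer(rowSums(as.matrix(p$centroids[, c("row", "col")])^2),
              rep(1, nrow(ns$centroids))) +
    outer(rep(1, nrow(p$centroids)),
          rowSums(as.matrix(ns$centroids[, c("row", "col")])^2)) -
    2 * as.matrix(p$centroids[, c("row", "col")]) %*%
      t(as.matrix(ns$centroids[, c("row", "col")]))
  expect_lt(mean(sqrt(pmax(apply(d2, 1, min), 0))), 3)

  # determinism: identical masks across runs
  ns2 <- segment_nuclei(p$image)
  expect_identical(ns$mask, ns2$mask)
  # label partition: labels disjoint and cover their foreground
  expect_setequal(unique(as.integer(ns$mask[ns$mask > 0])),
                  ns$centroids$label)
})
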