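test_that("LAB channel statistics behave like per-pixel moments", {
  # constant image: zero spread in every channel
  gray <- array(128, dim = c(8, 8, 3))
  s <- compute_lab_stats(gray)
  expect_equal(c(s$sd_l, s$sd_a, s$sd_b), c(0, 0, 0))

  # permutation invariance: an image and its mirror share all stats
  img <- array(runif(10 * 12 * 3, 0, 255), dim = c(10, 12, 3))
  mir <- img[, ncol(img[, , 1]):1, , drop = FALSE]
  expect_equal(as.data.frame(compute_lab_stats(img)),
               as.data.frame(compute_lab_stats(mir)))

  # two-tone image vs brute-force accumulation over the LAB pixels
  two <- array(0, dim = c(4, 4, 3))
  two[1:2, , ] <- 60; two[3:4, , ] <- 200
  s2 <- compute_lab_stats(two)
  lab <- nucleiclust:::rgb_to_lab(two)
  for (ch in 1:3) {
    o <- oracle_channel_stats(lab[, , ch])
    expect_equal(c(s2$mean_l, s2$mean_a, s2$mean_b)[ch], unname(o["mean"]))
    expect_equal(c(s2$sd_l, s2$sd_a, s2$sd_b)[ch], unname(o["sd"]),
                 tolerance = 1e-10)
  }
})

test_that("the modified channel transfer map matches its closed form", {
  # worked example: (50-40)*(20/10) + (50+60)/2 = 75
  expect_equal(nucleiclust:::channel_transfer(50, 40, 10, 60, 20), 75)
  # the source mean is a fixed point when target stats equal source stats
  expect_equal(nucleiclust:::channel_transfer(40, 40, 10, 40, 10), 40)
  # analytic expectation: E[out] = (mean_src + mean_tar)/2 by linearity
  x <- rnorm(5000, mean = 55, sd = 7)
  out <- nucleiclust:::channel_transfer(x, mean(x), sd(x), 20, 14)
  expect_equal(mean(out), (mean(x) + 20) / 2, tolerance = 1e-9)
})

test_that("normalize_stain transfers statistics and stays in gamut", {
  set.seed(42)
  src <- array(runif(16 * 16 * 3, 40, 220), dim = c(16, 16, 3))
  ref <- array(runif(16 * 16 * 3, 80, 160), dim = c(16, 16, 3))
  out <- normalize_stain(src, ref)
  expect_equal(dim(out), dim(src))
  expect_true(all(out >= 0 & out <= 255))
  # pre-clipping LAB mean of the output channel is (mean_src + mean_tar)/2
  ss <- compute_lab_stats(src); tt <- compute_lab_stats(ref)
  lab <- nucleiclust:::px_mat(nucleiclust:::rgb_to_lab(src))
  mapped <- nucleiclust:::channel_transfer(lab[, 1], ss$mean_l, ss$sd_l,
                                           tt$mean_l, tt$sd_l)
  expect_equal(mean(mapped), (ss$mean_l + tt$mean_l) / 2, tolerance = 1e-9)
  # degenerate source raises
  expect_error(normalize_stain(array(10, dim = c(4, 4, 3)), ref),
               "degenerate")
})

test_that("optical density transform follows the base-10 convention", {
  expect_identical(rgb_to_od(array(255, c(1, 1, 3)))[1], 0)
  expect_equal(rgb_to_od(array(25.5, c(1, 1, 3)))[1], 1)
  expect_equal(rgb_to_od(array(0, c(1, 1, 3)))[1], -log10(1 / 255))
  # strict monotone decrease on [1, 255]
  ii <- seq(1, 255, by = 0.5)
  od <- rgb_to_od(array(rep(ii, 3), dim = c(length(ii), 1, 3)))[, 1, 1]
  expect_true(all(diff(od) < 0))
})

test_that("stain deconvolution is the least-squares projection", {
  m <- default_stain_matrix()
  expect_equal(sqrt(rowSums(m^2)), c(hematoxylin = 1, eosin = 1),
               tolerance = 0.02)
  mk_od <- function(v) array(rep(v, each = 1), dim = c(1, 1, 3))
  z <- deconvolve_stains(mk_od(c(0, 0, 0)))
  expect_equal(c(z$h[1], z$e[1]), c(0, 0))
  s1 <- deconvolve_stains(mk_od(2 * m[1, ]))
  expect_equal(c(s1$h[1], s1$e[1]), c(2, 0), tolerance = 1e-12)
  s2 <- deconvolve_stains(mk_od(m[1, ] + m[2, ]))
  expect_equal(c(s2$h[1], s2$e[1]), c(1, 1), tolerance = 1e-12)
  # in-span OD reconstructs to itself; cross-check against qr least squares
  set.seed(7)
  for (i in 1:20) {
    conc <- runif(2, 0, 1.5)
    od_vec <- conc[1] * m[1, ] + conc[2] * m[2, ]
    got <- deconvolve_stains(mk_od(od_vec))
    expect_equal(c(got$h[1], got$e[1]), conc, tolerance = 1e-9)
    expect_equal(c(got$h[1], got$e[1]),
                 as.numeric(qr.solve(t(m), od_vec)), tolerance = 1e-9)
  }
  bad <- rbind(m[1, ], 2 * m[1, ])
  expect_error(deconvolve_stains(mk_od(m[1, ]), bad), "collinear")
})

test_that("stain image reconstruction closes the round trip", {
  m <- default_stain_matrix()
  white <- reconstruct_stain_image(matrix(0, 2, 2), m[1, ])
  expect_true(all(white == 255))
  one <- reconstruct_stain_image(matrix(1, 1, 1), m[1, ])
  expect_equal(as.numeric(one[1, 1, ]), unname(255 * 10^(-m[1, ])),
               tolerance = 1e-9)
  # negative concentrations are clipped to zero (white)
  neg <- reconstruct_stain_image(matrix(-3, 1, 1), m[1, ])
  expect_true(all(neg == 255))
  # single-stain pixels survive rgb -> od -> deconvolve -> reconstruct
  set.seed(11)
  for (i in 1:25) {
    c_h <- runif(1, 0, 1.8)
    px <- array(255 * 10^(-c_h * m[1, ]), dim = c(1, 1, 3))
    conc <- deconvolve_stains(rgb_to_od(px))
    back <- reconstruct_stain_image(conc$h, m[1, ])
    expect_true(all(abs(back - px) <= 1))
  }
})
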