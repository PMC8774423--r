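test_that("euclidean_distance is the plane metric", {
  expect_equal(euclidean_distance(c(0, 0), c(0, 0)), 0)
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  set.seed(1)
  for (i in 1:10) {
    a <- runif(2, -50, 50); b <- runif(2, -50, 50)
    expect_equal(euclidean_distance(a, b), euclidean_distance(b, a))
  }
})

test_that("build_mst grows the minimum spanning tree", {
  expect_equal(nrow(build_mst(cbind(1, 1))$edges), 0L)
  expect_equal(nrow(build_mst(matrix(numeric(0), 0, 2))$edges), 0L)

  collinear <- cbind(c(0, 3, 7), c(0, 0, 0))
  g <- build_mst(collinear)
  expect_equal(nrow(g$edges), 2L)
  expect_equal(sort(g$edges$weight), c(3, 4))
  expect_equal(sum(g$edges$weight), 7)

  square <- cbind(c(0, 0, 1, 1), c(0, 1, 0, 1))
  expect_equal(sum(build_mst(square)$edges$weight), 3)
  expect_equal(sum(build_mst(square)$edges$weight),
               oracle_exhaustive_mst(square))

  # duplicated points contribute zero-weight edges, K-1 edges always
  dup <- cbind(c(0, 0, 5), c(2, 2, 2))
  gd <- build_mst(dup)
  expect_equal(nrow(gd$edges), 2L)
  expect_equal(min(gd$edges$weight), 0)
})

test_that("MST optimality holds against enumeration and igraph", {
  skip_if_not_installed("igraph")
  set.seed(99)
  for (i in 1:25) {
    n <- sample(2:7, 1)
    xy <- matrix(runif(2 * n, 0, 100), n, 2)
    got <- sum(build_mst(xy)$edges$weight)
    expect_equal(got, oracle_exhaustive_mst(xy), tolerance = 1e-9)
    d <- as.matrix(stats::dist(xy))
    ig <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                              weighted = TRUE)
    expect_equal(got, sum(igraph::E(igraph::mst(ig))$weight),
                 tolerance = 1e-9)
  }
})

test_that("edge cutting partitions the tree as specified", {
  set.seed(5)
  xy <- matrix(runif(60, 0, 300), 30, 2)
  g <- build_mst(xy)

  # removing k edges from a tree gives exactly k+1 components
  for (k in c(0, 1, 4, 9, 20)) {
    cs <- cut_edges(g, mode = "top_k", value = k)
    expect_equal(length(cs$clusters), k + 1L)
    expect_equal(nrow(cs$cut_edges), k)
    # clusters partition the vertex set
    expect_setequal(unlist(cs$clusters), seq_len(30))
    expect_equal(sum(lengths(cs$clusters)), 30L)
  }
  # k >= |edges|: all singletons
  allcut <- cut_edges(g, mode = "top_k", value = 50)
  expect_equal(length(allcut$clusters), 30L)

  # threshold mode extremes
  expect_equal(length(cut_edges(g, "threshold",
                                max(g$edges$weight))$clusters), 1L)
  expect_equal(length(cut_edges(g, "threshold",
                                min(g$edges$weight) - 1)$clusters), 30L)

  # threshold consistency: every retained intra-MST edge <= threshold
  cs <- cut_edges(g, "threshold", 40)
  intra <- intra_cluster_summary(cs)
  expect_true(all(intra$mst_max <= 40))
})

test_that("intra-cluster summaries match hand enumeration", {
  cs1 <- cut_edges(build_mst(cbind(5, 5)), "threshold", 10)
  s1 <- intra_cluster_summary(cs1)
  expect_equal(as.numeric(s1[1, c("pair_min", "pair_max", "pair_total",
                                  "pair_avg", "mst_min", "mst_max",
                                  "mst_total", "hull_area")]),
               rep(0, 8))
  expect_error(nucleiclust:::cluster_stats(matrix(numeric(0), 0, 2)),
               "empty")

  xy <- cbind(c(0, 3, 7), c(0, 0, 0))
  s <- intra_cluster_summary(cut_edges(build_mst(xy), "threshold", 100))
  expect_equal(s$pair_min, 3); expect_equal(s$pair_max, 7)
  expect_equal(s$pair_total, 14); expect_equal(s$pair_avg, 14 / 3)
  expect_equal(s$mst_min, 3); expect_equal(s$mst_max, 4)
  expect_equal(s$mst_total, 7)
  expect_equal(s$hull_area, 0)  # collinear

  sq <- cbind(c(0, 0, 1, 1), c(0, 1, 0, 1))
  ssq <- intra_cluster_summary(cut_edges(build_mst(sq), "threshold", 100))
  expect_equal(ssq$hull_area, 1)
  expect_equal(ssq$hull_area, oracle_hull_area(sq))
})

test_that("inter-cluster summaries use cluster means", {
  # two clusters with means (0,0) and (6,8): centroid distance 10
  xy <- rbind(cbind(c(-1, 1), c(0, 0)), cbind(c(5, 7), c(8, 8)))
  cs <- cut_edges(build_mst(xy), "threshold", 3)
  expect_equal(length(cs$clusters), 2L)
  s <- inter_cluster_summary(cs)
  expect_equal(s$c2c_min, 10)
  expect_equal(s$mst_total, 10)

  one <- cut_edges(build_mst(xy), "threshold", 1000)
  s1 <- inter_cluster_summary(one)
  expect_equal(as.numeric(s1[1, -1]), rep(0, 8))

  # three centroids (0,0),(10,0),(0,10): brute-force values
  xy3 <- rbind(c(0, 0), c(10, 0), c(0, 10))
  cs3 <- cut_edges(build_mst(xy3), "threshold", 1)
  s3 <- inter_cluster_summary(cs3)
  expect_equal(s3$c2c_total, 20 + sqrt(200), tolerance = 1e-12)
  expect_equal(s3$mst_total, 20)
  expect_equal(s3$mst_min, 10); expect_equal(s3$mst_max, 10)
})

test_that("distance features are scale-equivariant and consistent", {
  set.seed(17)
  xy <- matrix(runif(40, 0, 200), 20, 2)
  cs <- cut_edges(build_mst(xy), "threshold", 50)
  intra <- intra_cluster_summary(cs)
  inter <- inter_cluster_summary(cs)
  s <- 2.5
  cs_s <- cut_edges(build_mst(xy * s), "threshold", 50 * s)
  intra_s <- intra_cluster_summary(cs_s)
  inter_s <- inter_cluster_summary(cs_s)
  expect_equal(length(cs_s$clusters), length(cs$clusters))
  dist_cols <- c("pair_min", "pair_max", "pair_total", "pair_avg",
                 "mst_min", "mst_max", "mst_total")
  expect_equal(as.matrix(intra_s[dist_cols]),
               as.matrix(intra[dist_cols]) * s, tolerance = 1e-9)
  expect_equal(intra_s$hull_area, intra$hull_area * s^2, tolerance = 1e-9)
  expect_equal(as.numeric(inter_s[1, -1]), as.numeric(inter[1, -1]) * s,
               tolerance = 1e-9)
  # intra-MST total never exceeds the pairwise total
  expect_true(all(intra$mst_total <= intra$pair_total + 1e-12))
})
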