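test_that("standardization is the population z-score with safe inverses", {
  tab <- data.frame(a = c(1, 2, 3), b = c(5, 5, 5))
  sc <- standardize(tab)
  expect_equal(sc$a, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(sc$a, c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(sc$b, c(0, 0, 0))
  # defining property on random data
  set.seed(8)
  X <- as.data.frame(matrix(rnorm(200, 5, 3), 50, 4))
  Z <- standardize(X)
  expect_equal(unname(colMeans(as.matrix(Z))), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(as.matrix(Z), 2,
                            function(x) sqrt(mean(x^2)))),
               rep(1, 4), tolerance = 1e-12)
  # round trip restores inputs
  expect_equal(as.data.frame(unstandardize(Z)), X, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(fit_scaler(X[1, , drop = FALSE]), "2 rows")
})

test_that("metric formulas match the worked confusion matrix", {
  cm <- matrix(c(9, 1, 2, 8), 2, 2, byrow = TRUE,
               dimnames = list(c("pos", "neg"), c("pos", "neg")))
  m <- compute_metrics(cm)
  expect_equal(m$accuracy, 85)
  expect_equal(m$recall, 90)
  expect_equal(m$precision, 900 / 11, tolerance = 1e-9)   # 81.82 %
  expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
  expect_equal(m$f1, 85.71, tolerance = 1e-3)

  # perfect and all-wrong classifiers
  expect_equal(compute_metrics(diag(c(5, 5, 5)))$accuracy, 100)
  expect_equal(compute_metrics(diag(c(5, 5, 5)))$f1, 100)
  wrong <- matrix(c(0, 5, 5, 0), 2, 2)
  expect_equal(compute_metrics(wrong)$accuracy, 0)

  # per class, F1 lies between precision and recall
  set.seed(2)
  for (i in 1:10) {
    cm3 <- matrix(rpois(9, 5), 3, 3)
    for (cl in 1:3) {
      two <- matrix(c(cm3[cl, cl], sum(cm3[cl, -cl]),
                      sum(cm3[-cl, cl]), sum(cm3[-cl, -cl])),
                    2, 2, byrow = TRUE)
      mm <- compute_metrics(two, positive = 1)
      expect_gte(mm$f1, min(mm$precision, mm$recall) - 1e-9)
      expect_lte(mm$f1, max(mm$precision, mm$recall) + 1e-9)
    }
  }
  never_pred <- matrix(c(3, 0, 2, 0), 2, 2, byrow = TRUE)  # col 2 empty
  expect_gte(compute_metrics(never_pred, positive = 2)$n_undefined, 1L)
})

test_that("confusion_matrix aligns truth rows with prediction columns", {
  cm <- confusion_matrix(c("a", "a", "b"), c("a", "b", "b"))
  expect_equal(as.numeric(cm), c(1, 0, 1, 1))
  expect_equal(sum(cm), 3)
})

test_that("the stacking ensemble separates well-separated Gaussians", {
  set.seed(31)
  n <- 100
  X <- rbind(matrix(rnorm(2 * n), n, 2),
             matrix(rnorm(2 * n, mean = 5), n, 2))  # 5 sigma apart
  colnames(X) <- c("f1", "f2")
  y <- factor(rep(c("lo", "hi"), each = n), levels = c("lo", "hi"))
  tr <- c(1:80, 101:180); te <- setdiff(seq_len(2 * n), tr)
  fit <- fit_stacked_ensemble(X[tr, ], y[tr], seed = 3L,
                              rf_trees = 60L, boost_rounds = 30L)
  acc <- mean(predict(fit, X[te, ]) == y[te])
  expect_gte(acc, 0.95)
  # architecture contract: meta features = 4 learners x n_classes
  expect_length(fit$meta_feature_names, 4L * 2L)
  expect_equal(ncol(nucleiclust:::meta_features(fit, X[te, ])), 8L)
  # determinism
  fit2 <- fit_stacked_ensemble(X[tr, ], y[tr], seed = 3L,
                               rf_trees = 60L, boost_rounds = 30L)
  expect_identical(predict(fit, X[te, ]), predict(fit2, X[te, ]))
  # single-class input is rejected
  expect_error(fit_stacked_ensemble(X[1:50, ], y[1:50], seed = 1),
               "2 classes")
  # broom-style accessors
  expect_true(all(c("class", "term", "estimate") %in%
                    names(tidy(fit))))
  expect_equal(glance(fit)$n_base_learners, 4L)
})

test_that("the ensemble is no worse than its weakest base learner", {
  set.seed(77)
  n <- 60
  X <- rbind(matrix(rnorm(2 * n), n, 2),
             matrix(rnorm(2 * n, mean = 3), n, 2))  # 3 sigma apart
  colnames(X) <- c("f1", "f2")
  y <- factor(rep(c("lo", "hi"), each = n))
  tr <- c(1:45, 61:105); te <- setdiff(seq_len(2 * n), tr)
  fit <- fit_stacked_ensemble(X[tr, ], y[tr], seed = 5L,
                              rf_trees = 60L, boost_rounds = 30L)
  ens_acc <- mean(predict(fit, X[te, ]) == y[te])
  base_accs <- vapply(fit$base_fits, function(b)
    mean(predict(b, X[te, ], type = "class") == y[te]), numeric(1))
  expect_gte(ens_acc, min(base_accs))
})

test_that("k-medoids matches the exhaustive medoid search on two blobs", {
  set.seed(12)
  X <- rbind(matrix(rnorm(30, 0, 0.5), 15, 2),
             matrix(rnorm(30, 6, 0.5), 15, 2))
  a <- kmedoids_classify(X, k = 2, seed = 1)
  expect_equal(length(unique(a[1:15])), 1L)
  expect_equal(length(unique(a[16:30])), 1L)
  expect_true(a[1] != a[16])
  # exhaustive search over all medoid pairs
  d <- as.matrix(stats::dist(X))
  best <- Inf
  for (i in 1:29) for (j in (i + 1):30) {
    cost <- sum(pmin(d[, i], d[, j]))
    if (cost < best) best <- cost
  }
  expect_equal(attr(a, "cost"), best, tolerance = 1e-9)

  # degenerate k = n: every point its own medoid, zero cost
  an <- kmedoids_classify(X[1:6, ], k = 6, seed = 1)
  expect_equal(attr(an, "cost"), 0)
  expect_error(kmedoids_classify(X, k = 31, seed = 1), "exceeds")
  # determinism
  expect_identical(as.integer(kmedoids_classify(X, 2, seed = 7)),
                   as.integer(kmedoids_classify(X, 2, seed = 8)))
})

test_that("cluster-to-label mapping maximises accuracy over permutations", {
  y <- factor(rep(c("g3", "g4", "g5"), each = 4))
  relabelled <- c(rep(2L, 4), rep(3L, 4), rep(1L, 4))
  mp <- map_clusters_to_labels(relabelled, y)
  expect_equal(mp$accuracy, 100)
  expect_equal(unname(mp$mapping[c("2", "3", "1")]),
               c("g3", "g4", "g5"))

  # the better of the two binary permutations is always chosen
  set.seed(5)
  yb <- factor(rep(c("A", "B"), each = 10))
  ab <- sample(1:2, 20, replace = TRUE)
  mp2 <- map_clusters_to_labels(ab, yb)
  acc1 <- mean(c("A", "B")[ab] == as.character(yb)) * 100
  acc2 <- mean(c("B", "A")[ab] == as.character(yb)) * 100
  expect_equal(mp2$accuracy, max(acc1, acc2))
  expect_gte(mp2$accuracy, 50)
  expect_error(map_clusters_to_labels(1:3, yb), "length mismatch")
})

test_that("five-fold evaluation emits the split table contract", {
  tab <- generate_feature_table(20, separation = 4, seed = 13)
  res <- five_fold_evaluate(tab, "grade", model = "kmedoids",
                            n_splits = 5, seed = 2)
  expect_equal(nrow(res), 6L)
  expect_equal(res$split[6], "Average Split")
  expect_equal(res$accuracy[6], mean(res$accuracy[1:5]), tolerance = 1e-12)
  expect_equal(sum(res$n[1:5]), 60L)
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 100))
  # a class smaller than n_splits is rejected
  small <- tab[c(1:3, 21:23, 41:43), ]
  expect_error(five_fold_evaluate(small, "grade", model = "kmedoids"),
               "n_splits")
})

test_that("split_test scheme trains once and scores disjoint test splits", {
  tab <- generate_feature_table(25, separation = 4, seed = 19)
  res <- five_fold_evaluate(tab, "grade", model = "stacked",
                            n_splits = 5, seed = 3,
                            rf_trees = 40L, boost_rounds = 20L)
  expect_equal(nrow(res), 6L)
  # 20 % of 75 = 15 test rows split five ways
  expect_equal(sum(res$n[1:5]), 15L)
  expect_gte(res$accuracy[6], 90)   # 4-sigma world is easy
  # a test set too small for the split protocol is rejected
  tiny <- generate_feature_table(20, separation = 4, seed = 20)
  expect_error(five_fold_evaluate(tiny, "grade", model = "stacked",
                                  n_splits = 5, seed = 1),
               "test set")
})
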