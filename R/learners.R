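# Base learners for the stacking ensemble and the wrapper feature
# selectors. All four expose the same surface: fit_*(X, y, ...) returning
# an object whose predict() yields a class-probability matrix with one
# column per factor level.

as_label_factor <- function(y) {
  if (!is.factor(y)) y <- factor(y)
  droplevels(y)
}

#' Random forest classifier
#'
#' Bagged CART ensemble: each tree is grown on a bootstrap sample with
#' `mtry` features tried per split (default `floor(sqrt(p))`), Gini
#' criterion, and class-proportion leaves; forest probabilities average
#' the tree leaf proportions. Feature importance is the mean decrease in
#' Gini impurity accumulated over trees.
#'
#' @param X Numeric feature matrix.
#' @param y Class labels (factor or coercible).
#' @param n_trees Number of trees (default 150).
#' @param mtry Features tried per split.
#' @param max_depth,min_node Tree size controls.
#' @param seed Integer seed; fixed seed gives identical forests.
#' @return Object of class `nc_rf` with an `importance` vector.
#' @export
fit_rf <- function(X, y, n_trees = 150L, mtry = NULL, max_depth = 20L,
                   min_node = 1L, seed = 1L) {
  X <- as.matrix(X)
  y <- as_label_factor(y)
  K <- nlevels(y)
  yi <- as.integer(y)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  trees <- with_seed(seed, lapply(seq_len(n_trees), function(b) {
    idx <- sample.int(nrow(X), replace = TRUE)
    fit_cart(X[idx, , drop = FALSE], y = yi[idx], objective = "class",
             n_classes = K, max_depth = max_depth, min_node = min_node,
             mtry = mtry)
  }))
  imp <- Reduce(`+`, lapply(trees, `[[`, "importance")) / n_trees
  names(imp) <- colnames(X)
  structure(list(trees = trees, levels = levels(y), importance = imp,
                 n_features = ncol(X)),
            class = "nc_rf")
}

#' @export
predict.nc_rf <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  pr <- Reduce(`+`, lapply(object$trees, function(tr) predict_cart(tr, X))) /
    length(object$trees)
  colnames(pr) <- object$levels
  if (type == "prob") pr else
    factor(object$levels[max.col(pr, ties.method = "first")],
           levels = object$levels)
}

# shared multinomial softmax boosting loop; flavour "gbm" fits
# squared-error trees to the residual (first-order), flavour "xgb" uses
# second-order gain with L2 leaf regularisation and row/column subsampling
fit_boost <- function(X, y, flavour = c("gbm", "xgb"), n_rounds = 100L,
                      depth = 2L, shrinkage = 0.1, lambda = 1,
                      subsample = 0.8, colsample = 0.8, seed = 1L) {
  flavour <- match.arg(flavour)
  X <- as.matrix(X)
  y <- as_label_factor(y)
  K <- nlevels(y)
  n <- nrow(X)
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), as.integer(y))] <- 1
  F_mat <- matrix(0, n, K)
  trees <- vector("list", n_rounds)
  with_seed(seed, {
    for (m in seq_len(n_rounds)) {
      P <- exp(F_mat - apply(F_mat, 1, max))
      P <- P / rowSums(P)
      round_trees <- vector("list", K)
      for (k in seq_len(K)) {
        gk <- P[, k] - Y[, k]          # gradient of multinomial deviance
        hk <- pmax(P[, k] * (1 - P[, k]), 1e-6)
        if (flavour == "xgb") {
          ridx <- sort(sample.int(n, max(2L, floor(subsample * n))))
          cidx <- sort(sample.int(ncol(X),
                                  max(1L, floor(colsample * ncol(X)))))
          tr <- fit_cart(X[ridx, cidx, drop = FALSE],
                         g = gk[ridx], h = hk[ridx], objective = "xgb",
                         max_depth = depth, min_node = 2L,
                         lambda = lambda)
          tr$cols <- cidx
        } else {
          tr <- fit_cart(X, y = -gk, g = gk, h = hk, objective = "reg",
                         max_depth = depth, min_node = 2L)
          tr$cols <- seq_len(ncol(X))
        }
        round_trees[[k]] <- tr
        F_mat[, k] <- F_mat[, k] + shrinkage *
          predict_cart(tr, X[, tr$cols, drop = FALSE])
      }
      trees[[m]] <- round_trees
    }
  })
  structure(list(trees = trees, levels = levels(y), shrinkage = shrinkage,
                 flavour = flavour, n_features = ncol(X)),
            class = "nc_boost")
}

#' Gradient boosting classifier (multinomial deviance)
#'
#' Stagewise boosting of shallow regression trees on the softmax
#' residuals with Newton leaf values.
#'
#' @inheritParams fit_rf
#' @param n_rounds Boosting rounds (default 100).
#' @param depth Tree depth (default 2).
#' @param shrinkage Learning rate (default 0.1).
#' @return Object of class `nc_boost`.
#' @export
fit_gbm <- function(X, y, n_rounds = 100L, depth = 2L, shrinkage = 0.1,
                    seed = 1L) {
  fit_boost(X, y, flavour = "gbm", n_rounds = n_rounds, depth = depth,
            shrinkage = shrinkage, seed = seed)
}

#' Regularised second-order boosting classifier
#'
#' Extreme-gradient-boosting flavour: split gain and leaf weights use the
#' gradient/hessian pair with an L2 penalty `lambda`, plus row and column
#' subsampling per tree.
#'
#' @inheritParams fit_gbm
#' @param lambda L2 regularisation on leaf weights (default 1).
#' @param subsample,colsample Row/column subsampling rates (default 0.8).
#' @return Object of class `nc_boost`.
#' @export
fit_xgb <- function(X, y, n_rounds = 100L, depth = 2L, shrinkage = 0.1,
                    lambda = 1, subsample = 0.8, colsample = 0.8,
                    seed = 1L) {
  fit_boost(X, y, flavour = "xgb", n_rounds = n_rounds, depth = depth,
            shrinkage = shrinkage, lambda = lambda, subsample = subsample,
            colsample = colsample, seed = seed)
}

#' @export
predict.nc_boost <- function(object, newdata, type = c("prob", "class"),
                             ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  K <- length(object$levels)
  F_mat <- matrix(0, nrow(X), K)
  for (round_trees in object$trees) {
    for (k in seq_len(K)) {
      tr <- round_trees[[k]]
      F_mat[, k] <- F_mat[, k] + object$shrinkage *
        predict_cart(tr, X[, tr$cols, drop = FALSE])
    }
  }
  P <- exp(F_mat - apply(F_mat, 1, max))
  P <- P / rowSums(P)
  colnames(P) <- object$levels
  if (type == "prob") P else
    factor(object$levels[max.col(P, ties.method = "first")],
           levels = object$levels)
}

#' k-nearest-neighbour classifier
#'
#' Thin wrapper over FNN's exact neighbour search; probabilities are the
#' class frequencies among the `k` nearest training rows.
#'
#' @inheritParams fit_rf
#' @param k Number of neighbours (default 5).
#' @return Object of class `nc_knn`.
#' @export
fit_knn <- function(X, y, k = 5L) {
  X <- as.matrix(X)
  y <- as_label_factor(y)
  structure(list(X = X, y = y, k = min(k, nrow(X)), levels = levels(y)),
            class = "nc_knn")
}

#' @export
predict.nc_knn <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  nn <- FNN::get.knnx(object$X, X, k = object$k)$nn.index
  K <- length(object$levels)
  pr <- matrix(0, nrow(X), K, dimnames = list(NULL, object$levels))
  yi <- as.integer(object$y)
  for (j in seq_len(ncol(nn))) {
    pr[cbind(seq_len(nrow(X)), yi[nn[, j]])] <-
      pr[cbind(seq_len(nrow(X)), yi[nn[, j]])] + 1
  }
  pr <- pr / object$k
  if (type == "prob") pr else
    factor(object$levels[max.col(pr, ties.method = "first")],
           levels = object$levels)
}
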