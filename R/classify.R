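# Supervised (stacking ensemble) and unsupervised (k-medoids) grade
# classification, with z-score standardization, the five-fold evaluation
# protocol, and the accuracy/precision/recall/F1 metrics (in percent).

#' Fit per-feature standardization parameters
#'
#' @param table Numeric feature data frame or matrix.
#' @return A `scaler_params` tibble: `feature`, `mean`, `sd` (population
#'   standard deviation).
#' @export
fit_scaler <- function(table) {
  X <- as.matrix(table)
  if (nrow(X) < 2L) stop("need at least 2 rows to fit a scaler",
                         call. = FALSE)
  mu <- colMeans(X)
  sdv <- sqrt(colMeans(X^2) - mu^2)
  sdv[sdv < 0] <- 0
  out <- tibble::tibble(feature = colnames(X), mean = mu, sd = sdv)
  class(out) <- c("scaler_params", class(out))
  out
}

#' Standardize a feature table (z-score)
#'
#' Subtracts the per-feature mean and divides by the population standard
#' deviation. Parameters are fitted on `table` unless `params` is given
#' (fit on training data, reuse on test data). Zero-variance features map
#' to 0.
#'
#' @param table Numeric feature data frame or matrix.
#' @param params Optional `scaler_params` from [fit_scaler()].
#' @return Scaled tibble with the fitted `scaler_params` as the
#'   `"scaler"` attribute.
#' @export
standardize <- function(table, params = NULL) {
  if (is.null(params)) params <- fit_scaler(table)
  X <- as.matrix(table)
  stopifnot(identical(colnames(X), params$feature))
  sdv <- ifelse(params$sd > 0, params$sd, 1)
  Xs <- sweep(sweep(X, 2, params$mean), 2, sdv, "/")
  Xs[, params$sd == 0] <- 0
  out <- tibble::as_tibble(as.data.frame(Xs))
  attr(out, "scaler") <- params
  out
}

#' Invert a standardization
#'
#' @param scaled Tibble from [standardize()].
#' @param params `scaler_params`; defaults to the `"scaler"` attribute.
#' @return Tibble on the original scale.
#' @export
unstandardize <- function(scaled, params = attr(scaled, "scaler")) {
  X <- as.matrix(scaled)
  sdv <- ifelse(params$sd > 0, params$sd, 1)
  tibble::as_tibble(as.data.frame(
    sweep(sweep(X, 2, sdv, "*"), 2, params$mean, "+")))
}

stratified_folds <- function(y, k, seed) {
  y <- as_label_factor(y)
  fold <- integer(length(y))
  with_seed(seed, {
    for (lv in levels(y)) {
      idx <- sample(which(y == lv))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Fit the stacking ensemble classifier
#'
#' Two-level ensemble: four base learners (k-NN, random forest, gradient
#' boosting, regularised second-order boosting) and a logistic-regression
#' meta learner. The meta learner is trained on out-of-fold predicted
#' class probabilities of the base learners (5 inner stratified folds), so
#' the meta-feature matrix has `4 x n_classes` columns; the base learners
#' are then refitted on the full training data for prediction. All
#' randomness derives from `seed`.
#'
#' @param table Numeric feature table (standardize first; see
#'   [standardize()]).
#' @param labels Class labels (>= 2 classes).
#' @param seed Integer seed.
#' @param n_inner_folds Inner folds for the out-of-fold meta features
#'   (default 5).
#' @param rf_trees,boost_rounds Base-learner sizes.
#' @param knn_k Neighbours for the k-NN base learner.
#' @return Object of class `stacked_ensemble`.
#' @export
fit_stacked_ensemble <- function(table, labels, seed = 1L,
                                 n_inner_folds = 5L, rf_trees = 150L,
                                 boost_rounds = 80L, knn_k = 5L) {
  X <- as.matrix(table)
  y <- as_label_factor(labels)
  if (nlevels(y) < 2L) stop("need at least 2 classes", call. = FALSE)
  K <- nlevels(y)
  fitters <- list(
    knn = function(X, y, s) fit_knn(X, y, k = knn_k),
    rf = function(X, y, s) fit_rf(X, y, n_trees = rf_trees, seed = s),
    gbm = function(X, y, s) fit_gbm(X, y, n_rounds = boost_rounds,
                                    seed = s),
    xgb = function(X, y, s) fit_xgb(X, y, n_rounds = boost_rounds,
                                    seed = s))
  fold <- stratified_folds(y, n_inner_folds, derive_seed(seed, 1L))
  meta_X <- matrix(NA_real_, nrow(X), 4L * K)
  for (f in seq_len(n_inner_folds)) {
    tr <- fold != f; te <- fold == f
    if (!any(te)) next
    for (b in seq_along(fitters)) {
      fit <- fitters[[b]](X[tr, , drop = FALSE], y[tr],
                          derive_seed(seed, 10L * f + b))
      meta_X[te, ((b - 1L) * K + 1L):(b * K)] <-
        predict(fit, X[te, , drop = FALSE], type = "prob")
    }
  }
  colnames(meta_X) <- as.vector(outer(levels(y), names(fitters),
                                      function(l, b) paste(b, l, sep = "_")))
  meta_fit <- glmnet::glmnet(meta_X, y, family = "multinomial",
                             alpha = 0, lambda = 1e-3)
  base_fits <- lapply(seq_along(fitters), function(b)
    fitters[[b]](X, y, derive_seed(seed, 1000L + b)))
  names(base_fits) <- names(fitters)
  oof_pred <- predict(meta_fit, meta_X, type = "class")
  structure(list(base_fits = base_fits, meta_fit = meta_fit,
                 levels = levels(y), n_classes = K,
                 meta_feature_names = colnames(meta_X),
                 oof_accuracy = mean(oof_pred == as.character(y)) * 100,
                 seed = seed),
            class = "stacked_ensemble")
}

meta_features <- function(object, X) {
  K <- object$n_classes
  mx <- matrix(NA_real_, nrow(X), 4L * K)
  for (b in seq_along(object$base_fits)) {
    mx[, ((b - 1L) * K + 1L):(b * K)] <-
      predict(object$base_fits[[b]], X, type = "prob")
  }
  colnames(mx) <- object$meta_feature_names
  mx
}

#' @export
predict.stacked_ensemble <- function(object, newdata,
                                     type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  mx <- meta_features(object, X)
  if (type == "class") {
    cls <- predict(object$meta_fit, mx, type = "class")
    factor(as.character(cls), levels = object$levels)
  } else {
    pr <- predict(object$meta_fit, mx, type = "response")[, , 1]
    if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1,
                                       dimnames = list(NULL, object$levels))
    pr
  }
}

#' @export
print.stacked_ensemble <- function(x, ...) {
  cat(sprintf(
    "<stacked_ensemble> %d base learners (%s) + logistic meta learner\n",
    length(x$base_fits), paste(names(x$base_fits), collapse = ", ")))
  cat(sprintf("  classes: %s; out-of-fold accuracy %.1f%%\n",
              paste(x$levels, collapse = ", "), x$oof_accuracy))
  invisible(x)
}

#' @export
tidy.stacked_ensemble <- function(x, ...) {
  coefs <- stats::coef(x$meta_fit)
  purrr::map_dfr(names(coefs), function(cl) {
    m <- as.matrix(coefs[[cl]])
    tibble::tibble(class = cl, term = rownames(m), estimate = m[, 1])
  })
}

#' @export
glance.stacked_ensemble <- function(x, ...) {
  tibble::tibble(n_base_learners = length(x$base_fits),
                 n_classes = x$n_classes,
                 oof_accuracy = x$oof_accuracy,
                 seed = x$seed)
}

#' k-medoids (PAM) clustering of a feature table
#'
#' Partitioning around medoids with Euclidean dissimilarity: the BUILD
#' phase greedily seeds `k` medoids, then SWAP exchanges medoid/non-medoid
#' pairs until no swap reduces the total dissimilarity. Medoids are data
#' rows. PAM is deterministic for a given table, so `seed` only guards the
#' contract that repeated calls agree.
#'
#' @param table Numeric feature table (standardized recommended).
#' @param k Number of clusters, `1 <= k <= n`.
#' @param seed Unused beyond determinism bookkeeping; kept for interface
#'   symmetry.
#' @return Integer cluster assignments (1..k) with the medoid row indices
#'   as attribute `medoids` and the total dissimilarity as attribute
#'   `cost`.
#' @export
kmedoids_classify <- function(table, k, seed = 1L) {
  X <- as.matrix(table)
  if (k > nrow(X)) stop("k exceeds the number of rows", call. = FALSE)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k == nrow(X)) {
    # degenerate: every row is its own medoid at zero cost
    out <- seq_len(nrow(X))
    attr(out, "medoids") <- out
    attr(out, "cost") <- 0
    return(out)
  }
  fit <- cluster::pam(X, k = k, metric = "euclidean", do.swap = TRUE,
                      keep.diss = FALSE, keep.data = FALSE)
  out <- as.integer(fit$clustering)
  attr(out, "medoids") <- as.integer(fit$id.med)
  d <- sqrt(rowSums((X - X[fit$id.med[out], , drop = FALSE])^2))
  attr(out, "cost") <- sum(d)
  out
}

permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

#' Map unsupervised clusters to class labels
#'
#' Finds the one-to-one cluster-to-label mapping that maximises accuracy,
#' by exhaustive search over label permutations (cluster ids `1..k`,
#' `k` at most the number of label values).
#'
#' @param assignments Integer cluster assignments.
#' @param true_labels Class labels, same length.
#' @return List: `mapping` (named character vector cluster -> label),
#'   `mapped` (factor of mapped labels), `accuracy` (percent).
#' @export
map_clusters_to_labels <- function(assignments, true_labels) {
  if (length(assignments) != length(true_labels)) {
    stop("length mismatch", call. = FALSE)
  }
  y <- as_label_factor(true_labels)
  ks <- sort(unique(assignments))
  if (length(ks) > nlevels(y)) {
    stop("more clusters than label values", call. = FALSE)
  }
  best <- NULL; best_acc <- -1
  for (perm in permutations(levels(y))) {
    lab <- perm[match(assignments, ks)]
    acc <- mean(lab == as.character(y))
    if (acc > best_acc) {
      best_acc <- acc
      best <- perm[seq_along(ks)]
    }
  }
  names(best) <- as.character(ks)
  mapped <- factor(best[match(assignments, ks)], levels = levels(y))
  list(mapping = best, mapped = mapped, accuracy = best_acc * 100)
}

#' Confusion matrix
#'
#' @param truth True labels (rows).
#' @param pred Predicted labels (columns); coerced to the union of levels.
#' @return Square integer matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(truth, pred) {
  lv <- union(levels(as_label_factor(truth)), levels(as_label_factor(pred)))
  t1 <- factor(as.character(truth), levels = lv)
  t2 <- factor(as.character(pred), levels = lv)
  as.matrix(table(truth = t1, predicted = t2))
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, precision, recall and F1, all in percent:
#' accuracy = (TP + TN) / total x 100, precision = TP / (TP + FP) x 100,
#' recall = TP / (TP + FN) x 100, F1 = 2 PR / (P + R). For two classes the
#' metrics are computed for the positive class (by default the first row);
#' for more classes they are per-class one-vs-rest, macro-averaged. A
#' zero denominator reports that quantity as 0 and increments
#' `n_undefined`.
#'
#' @param cm Square count matrix, rows = truth, cols = predicted.
#' @param positive For 2 x 2 matrices, the positive class name or index
#'   (default the first row).
#' @return One-row tibble: `accuracy`, `precision`, `recall`, `f1`
#'   (percent) and `n_undefined`.
#' @export
compute_metrics <- function(cm, positive = 1L) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm), sum(cm) > 0)
  total <- sum(cm)
  acc <- sum(diag(cm)) / total * 100
  n_undef <- 0L
  per_class <- function(i) {
    tp <- cm[i, i]
    fp <- sum(cm[-i, i])
    fn <- sum(cm[i, -i])
    p <- if (tp + fp > 0) tp / (tp + fp) * 100 else {
      n_undef <<- n_undef + 1L; 0
    }
    r <- if (tp + fn > 0) tp / (tp + fn) * 100 else {
      n_undef <<- n_undef + 1L; 0
    }
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(p, r, f)
  }
  if (nrow(cm) == 2L) {
    i <- if (is.character(positive)) match(positive, rownames(cm)) else
      as.integer(positive)
    m <- per_class(i)
  } else {
    m <- rowMeans(vapply(seq_len(nrow(cm)), per_class, numeric(3)))
  }
  tibble::tibble(accuracy = acc, precision = m[1], recall = m[2],
                 f1 = m[3], n_undefined = n_undef)
}

#' Five-fold evaluation of the classifiers
#'
#' Evaluates either the stacking ensemble or k-medoids under the five-fold
#' protocol and emits a metrics table with one row per split plus an
#' `"Average Split"` row (the arithmetic mean of the split rows).
#'
#' Schemes for the ensemble:
#' * `"split_test"` (default): stratified 80/20 train/test split; the
#'   model is trained once on the training part (scaler fitted there and
#'   reused), and the test part is divided into `n_splits` stratified
#'   splits scored separately.
#' * `"cv"`: conventional stratified `n_splits`-fold cross-validation.
#'
#' k-medoids ignores the scheme: the whole table is standardized and
#' clustered once, clusters are mapped to labels by [map_clusters_to_labels()],
#' and the data are divided into `n_splits` stratified splits scored
#' separately.
#'
#' @param table Numeric feature table (raw scale; standardization happens
#'   inside, on training data only where applicable).
#' @param labels Class labels (a vector or the name of a column of
#'   `table`, default `"grade"`).
#' @param model `"stacked"` or `"kmedoids"`.
#' @param n_splits Number of evaluation splits (default 5).
#' @param seed Integer seed controlling splits and model fits.
#' @param scheme Evaluation scheme for the ensemble (see above).
#' @param train_frac Training fraction for `"split_test"` (default 0.8).
#' @param ... Passed on to [fit_stacked_ensemble()].
#' @return Tibble: `split`, `n`, `accuracy`, `precision`, `recall`, `f1`,
#'   `n_undefined`.
#' @export
five_fold_evaluate <- function(table, labels = "grade",
                               model = c("stacked", "kmedoids"),
                               n_splits = 5L, seed = 1L,
                               scheme = c("split_test", "cv"),
                               train_frac = 0.8, ...) {
  model <- match.arg(model)
  scheme <- match.arg(scheme)
  table <- as.data.frame(table)
  if (is.character(labels) && length(labels) == 1L &&
      labels %in% names(table)) {
    y <- table[[labels]]
    table <- table[setdiff(names(table), c(labels, "image_id"))]
  } else {
    y <- labels
    table <- table[setdiff(names(table), "image_id")]
  }
  y <- as_label_factor(y)
  if (min(table(y)) < n_splits) {
    stop("every class needs at least `n_splits` members", call. = FALSE)
  }
  rows <- list()
  add_row <- function(name, truth, pred) {
    cm <- confusion_matrix(truth, pred)
    rows[[length(rows) + 1L]] <<- dplyr::bind_cols(
      tibble::tibble(split = name, n = length(truth)),
      compute_metrics(cm))
  }
  if (model == "stacked" && scheme == "split_test") {
    te_flag <- stratified_folds(y, round(1 / (1 - train_frac)),
                                derive_seed(seed, 5L)) == 1L
    tr_idx <- which(!te_flag); te_idx <- which(te_flag)
    if (min(table(y[te_idx])) < n_splits) {
      stop("every class needs at least `n_splits` members in the test set",
           call. = FALSE)
    }
    scaler <- fit_scaler(table[tr_idx, ])
    Xtr <- standardize(table[tr_idx, ], scaler)
    Xte <- standardize(table[te_idx, ], scaler)
    fit <- fit_stacked_ensemble(Xtr, y[tr_idx], seed = seed, ...)
    pred <- predict(fit, Xte, type = "class")
    sub <- stratified_folds(y[te_idx], n_splits, derive_seed(seed, 6L))
    for (s in seq_len(n_splits)) {
      add_row(paste("Split", s), y[te_idx][sub == s], pred[sub == s])
    }
  } else if (model == "stacked") {
    fold <- stratified_folds(y, n_splits, derive_seed(seed, 5L))
    for (s in seq_len(n_splits)) {
      tr <- fold != s; te <- fold == s
      scaler <- fit_scaler(table[tr, ])
      fit <- fit_stacked_ensemble(standardize(table[tr, ], scaler), y[tr],
                                  seed = derive_seed(seed, s), ...)
      pred <- predict(fit, standardize(table[te, ], scaler),
                      type = "class")
      add_row(paste("Split", s), y[te], pred)
    }
  } else {
    Xs <- standardize(table)
    assign_ <- kmedoids_classify(Xs, k = nlevels(y),
                                 seed = derive_seed(seed, 7L))
    mapped <- map_clusters_to_labels(assign_, y)$mapped
    sub <- stratified_folds(y, n_splits, derive_seed(seed, 8L))
    for (s in seq_len(n_splits)) {
      add_row(paste("Split", s), y[sub == s], mapped[sub == s])
    }
  }
  out <- dplyr::bind_rows(rows)
  avg <- dplyr::summarise(out, split = "Average Split", n = sum(.data$n),
                          dplyr::across(c("accuracy", "precision",
                                          "recall", "f1"), mean),
                          n_undefined = sum(.data$n_undefined))
  dplyr::bind_rows(out, avg)
}
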