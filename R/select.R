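# Majority-voting feature selection: four filter scores (Chi-Square,
# Fisher Score, Information Gain, ANOVA) and three wrapper methods (RFE,
# Permutation Importance, Boruta). Each method marks a boolean vote per
# feature; features with at least `min_votes` votes are selected.

selection_methods <- function() {
  c("chi2", "fisher", "info_gain", "anova", "rfe", "perm_imp", "boruta")
}

minmax_scale <- function(X) {
  apply(X, 2, function(x) {
    r <- range(x)
    if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else rep(0, length(x))
  })
}

# chi-square association of a non-negative feature with the classes:
# per-class sums of the (min-max scaled) feature treated as observed
# frequencies against class-proportion expectations
score_chi2 <- function(X, y) {
  Xs <- minmax_scale(X)
  n_c <- table(y)
  pr <- as.numeric(n_c) / length(y)
  vapply(seq_len(ncol(Xs)), function(j) {
    obs <- tapply(Xs[, j], y, sum)
    exp_ <- sum(Xs[, j]) * pr
    if (all(exp_ == 0)) return(0)
    sum((obs - exp_)^2 / pmax(exp_, 1e-12))
  }, numeric(1))
}

# Fisher score: between-class over within-class variance ratio
score_fisher <- function(X, y) {
  cls <- split(seq_len(nrow(X)), y)
  vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    mu <- mean(x)
    num <- sum(vapply(cls, function(i) length(i) * (mean(x[i]) - mu)^2,
                      numeric(1)))
    den <- sum(vapply(cls, function(i) {
      xi <- x[i]; length(i) * mean((xi - mean(xi))^2)
    }, numeric(1)))
    if (den == 0) {
      if (num == 0) 0 else Inf
    } else num / den
  }, numeric(1))
}

# information gain: mutual information between the feature discretised
# into equal-width bins and the class labels (nats)
score_info_gain <- function(X, y, n_bins = 10L) {
  yf <- factor(y)
  vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    r <- range(x)
    if (r[2] <= r[1]) return(0)
    b <- cut(x, breaks = seq(r[1], r[2], length.out = n_bins + 1L),
             include.lowest = TRUE)
    tab <- table(b, yf)
    p <- tab / sum(tab)
    px <- rowSums(p); py <- colSums(p)
    nz <- p > 0
    sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
  }, numeric(1))
}

# one-way ANOVA F statistic
score_anova <- function(X, y) {
  cls <- split(seq_len(nrow(X)), y)
  k <- length(cls); n <- nrow(X)
  vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    mu <- mean(x)
    ssb <- sum(vapply(cls, function(i) length(i) * (mean(x[i]) - mu)^2,
                      numeric(1)))
    ssw <- sum(vapply(cls, function(i) sum((x[i] - mean(x[i]))^2),
                      numeric(1)))
    if (ssw == 0) {
      if (ssb == 0) 0 else Inf
    } else (ssb / (k - 1)) / (ssw / (n - k))
  }, numeric(1))
}

# recursive feature elimination with the package random forest: drop the
# least important feature until k_select remain
rfe_select <- function(X, y, k_select, seed, n_trees = 120L) {
  active <- seq_len(ncol(X))
  step <- 0L
  while (length(active) > k_select) {
    fit <- fit_rf(X[, active, drop = FALSE], y, n_trees = n_trees,
                  seed = derive_seed(seed, step))
    active <- active[-which.min(fit$importance)]
    step <- step + 1L
  }
  active
}

# permutation importance: accuracy drop on the training rows when one
# column is shuffled, averaged over n_rep permutations
perm_importance <- function(X, y, seed, n_trees = 120L, n_rep = 3L) {
  fit <- fit_rf(X, y, n_trees = n_trees, seed = derive_seed(seed, 1L))
  base_acc <- mean(predict(fit, X, type = "class") == as_label_factor(y))
  y <- as_label_factor(y)
  with_seed(derive_seed(seed, 2L), {
    vapply(seq_len(ncol(X)), function(j) {
      drops <- vapply(seq_len(n_rep), function(r) {
        Xp <- X
        Xp[, j] <- sample(Xp[, j])
        base_acc - mean(predict(fit, Xp, type = "class") == y)
      }, numeric(1))
      mean(drops)
    }, numeric(1))
  })
}

# Boruta-style all-relevant selection: compare each feature's RF
# importance against the best shadow (permuted copy) importance over
# max_runs iterations; confirm by a one-sided binomial test on the hit
# count. Tentative features count as not selected.
boruta_select <- function(X, y, seed, max_runs = 30L, n_trees = 120L,
                          alpha = 0.01) {
  p <- ncol(X)
  hits <- integer(p)
  for (r in seq_len(max_runs)) {
    shadow <- with_seed(derive_seed(seed, 100L + r),
                        apply(X, 2, sample))
    fit <- fit_rf(cbind(X, shadow), y, n_trees = n_trees,
                  seed = derive_seed(seed, 200L + r))
    imp <- fit$importance
    shadow_max <- max(imp[(p + 1L):(2L * p)])
    hits <- hits + as.integer(imp[1:p] > shadow_max)
  }
  pvals <- 1 - pbinom(hits - 1L, max_runs, 0.5)
  pvals < alpha
}

#' Score features with one selection method
#'
#' Applies a single filter or wrapper method and returns its boolean votes.
#' Score-based methods (the four filters plus RFE and permutation
#' importance) mark their top `k_select` features `TRUE`; Boruta marks its
#' confirmed features regardless of `k_select`. Features are min-max
#' scaled to `[0, 1]` before the Chi-Square test (the test is undefined on
#' negatives).
#'
#' @param table Data frame or matrix of numeric features (non-feature
#'   columns such as `image_id`/`grade` must be removed first; see
#'   [select_features()] for the convenience surface).
#' @param labels Class labels, one per row.
#' @param method One of `"chi2"`, `"fisher"`, `"info_gain"`, `"anova"`,
#'   `"rfe"`, `"perm_imp"`, `"boruta"`.
#' @param k_select Number of features the score-based methods keep
#'   (default 16).
#' @param seed Seed for the stochastic wrapper methods.
#' @return Logical vector, one vote per feature.
#' @export
score_method <- function(table, labels, method, k_select = 16L, seed = 1L) {
  X <- as.matrix(table)
  if (!is.numeric(X)) stop("feature table must be numeric", call. = FALSE)
  if (!method %in% selection_methods()) {
    stop(sprintf("unknown method '%s'", method), call. = FALSE)
  }
  if (k_select > ncol(X)) {
    stop("`k_select` exceeds the number of features", call. = FALSE)
  }
  if (method == "boruta") {
    votes <- boruta_select(X, labels, seed = seed)
  } else {
    scores <- switch(method,
                     chi2 = score_chi2(X, labels),
                     fisher = score_fisher(X, labels),
                     info_gain = score_info_gain(X, labels),
                     anova = score_anova(X, labels),
                     rfe = NULL,
                     perm_imp = perm_importance(X, labels, seed = seed))
    if (method == "rfe") {
      votes <- logical(ncol(X))
      votes[rfe_select(X, labels, k_select, seed = seed)] <- TRUE
    } else {
      votes <- logical(ncol(X))
      # top-k by score, deterministic on ties by feature order;
      # zero-variance features can never outrank an informative one
      votes[order(-scores, seq_along(scores))[seq_len(k_select)]] <- TRUE
    }
  }
  names(votes) <- colnames(X)
  votes
}

#' Majority-voting feature selection
#'
#' Runs all seven selection methods and assembles the vote matrix: one row
#' per feature, one boolean column per method, the vote count, and the
#' Select/Reject decision at `min_votes` (default 4, i.e. a feature must
#' be backed by at least four of the seven methods).
#'
#' @param table Feature tibble; columns named in `exclude` (default
#'   `image_id`) are dropped, and `labels` may name a column of `table`.
#' @param labels Class labels: a vector, or the name of a column of
#'   `table` (default `"grade"`).
#' @param k_select Features kept by each score-based method (default 16).
#' @param min_votes Minimum votes to select (default 4).
#' @param seed Seed for the stochastic methods.
#' @param exclude Identifier columns to drop from the feature set.
#' @return A `vote_matrix` tibble: `feature`, seven logical method
#'   columns, `votes`, `decision`.
#' @export
select_features <- function(table, labels = "grade", k_select = 16L,
                            min_votes = 4L, seed = 1L,
                            exclude = "image_id") {
  table <- as.data.frame(table)
  if (is.character(labels) && length(labels) == 1L &&
      labels %in% names(table)) {
    y <- table[[labels]]
    table <- table[setdiff(names(table), labels)]
  } else {
    y <- labels
  }
  table <- table[setdiff(names(table), exclude)]
  y <- as_label_factor(y)
  votes <- lapply(selection_methods(), function(m)
    score_method(table, y, m, k_select = k_select, seed = seed))
  names(votes) <- selection_methods()
  vm <- tibble::as_tibble(votes)
  vm <- dplyr::bind_cols(tibble::tibble(feature = names(table)), vm)
  tally_votes(vm, min_votes = min_votes)
}

#' Tally votes and decide selection
#'
#' Recomputes the `votes` column as the row-wise count of `TRUE` method
#' votes and sets `decision` to `"Select"` where `votes >= min_votes`,
#' `"Reject"` otherwise. Row order is preserved.
#'
#' @param vote_matrix Tibble with a `feature` column and logical method
#'   columns (any pre-existing `votes`/`decision` columns are replaced).
#' @param min_votes Minimum vote count to select (default 4).
#' @return The completed `vote_matrix` tibble with attributes
#'   `selected`/`rejected` holding the feature names in order.
#' @export
tally_votes <- function(vote_matrix, min_votes = 4L) {
  vm <- tibble::as_tibble(vote_matrix)
  method_cols <- names(vm)[vapply(vm, is.logical, logical(1))]
  vm$votes <- rowSums(vm[method_cols])
  vm$decision <- ifelse(vm$votes >= min_votes, "Select", "Reject")
  attr(vm, "min_votes") <- min_votes
  attr(vm, "selected") <- vm$feature[vm$decision == "Select"]
  attr(vm, "rejected") <- vm$feature[vm$decision == "Reject"]
  class(vm) <- c("vote_matrix", class(vm))
  vm
}

#' Names of the selected features
#'
#' @param vote_matrix A tallied `vote_matrix`.
#' @return Character vector of selected feature names, original order.
#' @export
selected_features <- function(vote_matrix) {
  attr(vote_matrix, "selected")
}

#' Reference vote matrix fixture
#'
#' Loads the packaged reference feature-selection vote table for the 26
#' cluster features (7 methods x 26 features with the published
#' True/False votes), used to validate the voting arithmetic.
#'
#' @return A tallied `vote_matrix` tibble.
#' @export
reference_vote_matrix <- function() {
  path <- system.file("extdata", "reference_votes.csv",
                      package = "nucleiclust", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (m in selection_methods()) df[[m]] <- as.logical(df[[m]])
  tally_votes(tibble::as_tibble(df), min_votes = 4L)
}
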