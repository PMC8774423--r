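# CART core shared by the random forest and the two boosting learners.
# No tree package is assumed: split search is vectorised over sorted
# feature values with cumulative-sum statistics.
#
# Objectives:
#   "class" - Gini impurity on integer classes 1..K; leaves store class
#             proportions.
#   "reg"   - squared-error on a numeric response (boosting residuals);
#             leaves store a Newton step -sum(g)/(sum(h)+lambda) when
#             gradients/hessians are supplied, else the mean.
#   "xgb"   - second-order gain with L2 regularisation lambda on the leaf
#             weights (regularised boosting flavour).

fit_cart <- function(X, y = NULL, g = NULL, h = NULL,
                     objective = c("class", "reg", "xgb"),
                     n_classes = NULL, max_depth = 20L, min_node = 1L,
                     mtry = ncol(X), lambda = 0) {
  objective <- match.arg(objective)
  n <- nrow(X); p <- ncol(X)
  if (objective == "class") {
    Y <- matrix(0, n, n_classes)
    Y[cbind(seq_len(n), y)] <- 1
  }
  feat <- integer(0); thr <- numeric(0)
  left <- integer(0); right <- integer(0)
  leaf <- list()
  importance <- numeric(p)

  new_node <- function() {
    feat[length(feat) + 1L] <<- 0L
    thr[length(thr) + 1L] <<- NA_real_
    left[length(left) + 1L] <<- 0L
    right[length(right) + 1L] <<- 0L
    leaf[[length(leaf) + 1L]] <<- NULL
    length(feat)
  }

  leaf_value <- function(idx) {
    if (objective == "class") {
      colSums(Y[idx, , drop = FALSE]) / length(idx)
    } else {
      if (!is.null(g)) -sum(g[idx]) / (sum(h[idx]) + lambda)
      else mean(y[idx])
    }
  }

  node_score <- function(idx) {
    # impurity (class), SSE proxy (reg), or negative xgb score
    if (objective == "class") {
      pr <- colSums(Y[idx, , drop = FALSE]) / length(idx)
      length(idx) * (1 - sum(pr^2))
    } else if (objective == "reg") {
      r <- y[idx]; sum(r^2) - length(idx) * mean(r)^2
    } else {
      -sum(g[idx])^2 / (sum(h[idx]) + lambda)
    }
  }

  best_split <- function(idx, feats) {
    n_i <- length(idx)
    best <- list(score = Inf, feature = 0L)
    for (j in feats) {
      x <- X[idx, j]
      ord <- order(x)
      xs <- x[ord]
      ok <- which(xs[-n_i] < xs[-1])
      ok <- ok[ok >= min_node & (n_i - ok) >= min_node]
      if (!length(ok)) next
      if (objective == "class") {
        cs <- apply(Y[idx[ord], , drop = FALSE], 2, cumsum)
        tot <- cs[n_i, ]
        nl <- seq_len(n_i - 1)
        gl <- nl - rowSums(cs[nl, , drop = FALSE]^2) / nl
        nr <- n_i - nl
        rs <- matrix(tot, n_i - 1, length(tot), byrow = TRUE) -
          cs[nl, , drop = FALSE]
        gr <- nr - rowSums(rs^2) / nr
        sc <- (gl + gr)[ok]
      } else if (objective == "reg") {
        yy <- y[idx[ord]]
        cy <- cumsum(yy); cy2 <- cumsum(yy^2)
        ty <- cy[n_i]; ty2 <- cy2[n_i]
        nl <- seq_len(n_i - 1)
        sse_l <- cy2[nl] - cy[nl]^2 / nl
        sse_r <- (ty2 - cy2[nl]) - (ty - cy[nl])^2 / (n_i - nl)
        sc <- (sse_l + sse_r)[ok]
      } else {
        gg <- g[idx[ord]]; hh <- h[idx[ord]]
        cg <- cumsum(gg); ch <- cumsum(hh)
        tg <- cg[n_i]; th <- ch[n_i]
        nl <- seq_len(n_i - 1)
        sc <- -(cg[nl]^2 / (ch[nl] + lambda) +
                  (tg - cg[nl])^2 / (th - ch[nl] + lambda))
        sc <- sc[ok]
      }
      b <- which.min(sc)
      if (sc[b] < best$score) {
        i0 <- ok[b]
        best <- list(score = sc[b], feature = j,
                     threshold = (xs[i0] + xs[i0 + 1]) / 2)
      }
    }
    best
  }

  grow <- function(idx, depth) {
    id <- new_node()
    parent_score <- node_score(idx)
    stop_here <- depth >= max_depth || length(idx) < 2L * min_node ||
      (objective == "class" && length(unique(y[idx])) == 1L)
    if (!stop_here) {
      feats <- if (mtry < p) sort(sample.int(p, mtry)) else seq_len(p)
      sp <- best_split(idx, feats)
      if (sp$feature > 0L && sp$score < parent_score - 1e-12) {
        go_left <- X[idx, sp$feature] <= sp$threshold
        feat[id] <<- sp$feature
        thr[id] <<- sp$threshold
        importance[sp$feature] <<- importance[sp$feature] +
          (parent_score - sp$score) / n
        l <- grow(idx[go_left], depth + 1L)
        r <- grow(idx[!go_left], depth + 1L)
        left[id] <<- l; right[id] <<- r
        return(id)
      }
    }
    leaf[[id]] <<- leaf_value(idx)
    id
  }

  grow(seq_len(n), 0L)
  structure(list(feature = feat, threshold = thr, left = left,
                 right = right, leaf = leaf, objective = objective,
                 n_classes = n_classes, importance = importance),
            class = "cart_tree")
}

predict_cart <- function(tree, X) {
  n <- nrow(X)
  out <- if (tree$objective == "class")
    matrix(0, n, tree$n_classes) else numeric(n)
  # route row sets down the tree iteratively
  stack <- list(list(node = 1L, idx = seq_len(n)))
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (!length(cur$idx)) next
    nd <- cur$node
    if (tree$feature[nd] == 0L) {
      if (tree$objective == "class") {
        out[cur$idx, ] <- matrix(tree$leaf[[nd]], length(cur$idx),
                                 tree$n_classes, byrow = TRUE)
      } else {
        out[cur$idx] <- tree$leaf[[nd]]
      }
    } else {
      go_left <- X[cur$idx, tree$feature[nd]] <= tree$threshold[nd]
      stack[[length(stack) + 1L]] <- list(node = tree$left[nd],
                                          idx = cur$idx[go_left])
      stack[[length(stack) + 1L]] <- list(node = tree$right[nd],
                                          idx = cur$idx[!go_left])
    }
  }
  out
}
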