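#' Euclidean distance between two points
#'
#' @param p1,p2 Numeric coordinate vectors of equal length.
#' @return Non-negative distance.
#' @export
euclidean_distance <- function(p1, p2) {
  sqrt(sum((as.numeric(p1) - as.numeric(p2))^2))
}

as_coord_matrix <- function(centroids) {
  if (is.matrix(centroids)) {
    stopifnot(ncol(centroids) == 2L)
    m <- centroids
  } else if (is.data.frame(centroids)) {
    stopifnot(all(c("row", "col") %in% names(centroids)))
    m <- cbind(centroids$row, centroids$col)
  } else {
    stop("`centroids` must be a matrix or a data frame with row/col columns",
         call. = FALSE)
  }
  storage.mode(m) <- "double"
  colnames(m) <- c("row", "col")
  m
}

#' Build the Euclidean minimum spanning tree over nucleus centroids
#'
#' Grows the MST with Prim's algorithm over the complete Euclidean graph of
#' the centroids. At each step the vertex with the smallest connecting
#' weight joins the tree; ties are broken by the smallest vertex index so
#' the edge set is deterministic (the total weight of an MST is unique in
#' any case). For `K` vertices the tree has `K - 1` edges.
#'
#' @param centroids A data frame with `row`/`col` columns (e.g.
#'   `nucleus_set$centroids`) or a two-column coordinate matrix.
#' @return An `mst_graph`: list with `vertices` (coordinate tibble) and
#'   `edges` (tibble `i`, `j`, `weight`, 1-based vertex indices, `i < j`).
#' @export
build_mst <- function(centroids) {
  xy <- as_coord_matrix(centroids)
  n <- nrow(xy)
  vertices <- tibble::tibble(row = xy[, 1], col = xy[, 2])
  if (n <= 1L) {
    return(structure(list(vertices = vertices,
                          edges = tibble::tibble(i = integer(), j = integer(),
                                                 weight = numeric())),
                     class = "mst_graph"))
  }
  d <- as.matrix(stats::dist(xy))
  in_tree <- logical(n)
  key <- rep(Inf, n)
  parent <- rep(NA_integer_, n)
  key[1] <- 0
  ei <- integer(n - 1); ej <- integer(n - 1); ew <- numeric(n - 1)
  for (step in seq_len(n)) {
    u <- which(!in_tree)[which.min(key[!in_tree])]  # smallest index on ties
    in_tree[u] <- TRUE
    if (!is.na(parent[u])) {
      a <- min(parent[u], u); b <- max(parent[u], u)
      ei[step - 1L] <- a; ej[step - 1L] <- b; ew[step - 1L] <- d[parent[u], u]
    }
    upd <- !in_tree & d[u, ] < key  # strict: earlier parent wins ties
    key[upd] <- d[u, upd]
    parent[upd] <- u
  }
  structure(list(vertices = vertices,
                 edges = tibble::tibble(i = ei, j = ej, weight = ew)),
            class = "mst_graph")
}

#' @export
print.mst_graph <- function(x, ...) {
  cat(sprintf("<mst_graph> %d vertices, %d edges, total weight %.3f\n",
              nrow(x$vertices), nrow(x$edges), sum(x$edges$weight)))
  invisible(x)
}

# iterative-compression union-find
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Cut inconsistent MST edges into clusters
#'
#' Partitions the nuclei by removing "inconsistent" edges from the MST.
#' In `threshold` mode every edge longer than `value` pixels is removed
#' (the default cut at 10 px); in `top_k` mode the `value` largest-weight
#' edges are removed (ties broken by vertex-index order), so a connected
#' tree always yields exactly `value + 1` clusters. The connected
#' components of the remaining forest are the clusters, numbered by their
#' smallest member vertex.
#'
#' @param mst An [build_mst()] result.
#' @param mode `"threshold"` or `"top_k"`.
#' @param value Threshold in pixels, or the number of edges to remove.
#' @return A `cluster_set`: list with `vertices`, `membership` (integer
#'   cluster id per vertex), `clusters` (list of member index vectors),
#'   `edges` (MST edges with a `kept` flag), `cut_edges`, `mode`, `value`.
#' @export
cut_edges <- function(mst, mode = c("threshold", "top_k"), value = 10) {
  stopifnot(inherits(mst, "mst_graph"))
  mode <- match.arg(mode)
  e <- mst$edges
  n <- nrow(mst$vertices)
  if (mode == "threshold") {
    cut <- e$weight > value
  } else {
    k <- min(as.integer(value), nrow(e))
    cut <- logical(nrow(e))
    if (k > 0) {
      ord <- order(-e$weight, e$i, e$j)
      cut[ord[seq_len(k)]] <- TRUE
    }
  }
  parent <- seq_len(max(n, 1L))
  if (nrow(e)) {
    for (r in which(!cut)) {
      a <- uf_find(parent, e$i[r]); b <- uf_find(parent, e$j[r])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  membership <- match(roots, sort(unique(roots)))
  clusters <- split(seq_len(n), membership)
  names(clusters) <- NULL
  structure(list(vertices = mst$vertices,
                 membership = membership,
                 clusters = clusters,
                 edges = dplyr::mutate(e, kept = !cut),
                 cut_edges = e[cut, , drop = FALSE],
                 mode = mode, value = value),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf(
    "<cluster_set> %d nuclei in %d clusters (%s cut at %s; %d edges removed)\n",
    nrow(x$vertices), length(x$clusters), x$mode, format(x$value),
    nrow(x$cut_edges)))
  invisible(x)
}

# convex-hull area of a point set (shoelace over grDevices::chull);
# 0 for fewer than 3 distinct non-collinear points
hull_area <- function(xy) {
  xy <- unique(xy)
  if (nrow(xy) < 3L) return(0)
  h <- grDevices::chull(xy[, 2], xy[, 1])
  if (length(h) < 3L) return(0)
  x <- xy[h, 2]; y <- xy[h, 1]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# distance summaries for the members of a single cluster
cluster_stats <- function(xy, areas = NULL) {
  n <- nrow(xy)
  if (n == 0L) stop("empty cluster", call. = FALSE)
  if (n == 1L) {
    pw <- c(min = 0, max = 0, total = 0, avg = 0)
    ms <- c(min = 0, max = 0, total = 0)
  } else {
    d <- as.numeric(stats::dist(xy))
    pw <- c(min = min(d), max = max(d), total = sum(d), avg = mean(d))
    w <- build_mst(xy)$edges$weight
    ms <- c(min = min(w), max = max(w), total = sum(w))
  }
  tibble::tibble(
    n = n,
    pair_min = unname(pw["min"]), pair_max = unname(pw["max"]),
    pair_total = unname(pw["total"]), pair_avg = unname(pw["avg"]),
    mst_min = unname(ms["min"]), mst_max = unname(ms["max"]),
    mst_total = unname(ms["total"]),
    hull_area = hull_area(xy),
    nucleus_area = if (is.null(areas)) NA_real_ else sum(areas),
    centroid_row = mean(xy[, 1]), centroid_col = mean(xy[, 2])
  )
}

#' Per-cluster (intra-cluster) distance summaries
#'
#' For every cluster: the set of pairwise Euclidean distances between
#' member nuclei (min/max/total/average), the intra-cluster MST edge
#' weights (min/max/total), the convex-hull area of the member centroids,
#' and the cluster mean position. Singleton clusters report 0 for every
#' distance and area so downstream aggregations stay well-defined.
#'
#' @param cs A `cluster_set` from [cut_edges()].
#' @param areas Optional per-vertex nucleus pixel areas (same order as the
#'   vertices); when given, `nucleus_area` sums them per cluster as an
#'   alternative cluster-area reading.
#' @return Tibble with one row per cluster.
#' @export
intra_cluster_summary <- function(cs, areas = NULL) {
  stopifnot(inherits(cs, "cluster_set"))
  xy <- as_coord_matrix(cs$vertices)
  purrr::map_dfr(seq_along(cs$clusters), function(k) {
    idx <- cs$clusters[[k]]
    dplyr::bind_cols(tibble::tibble(cluster = k),
                     cluster_stats(xy[idx, , drop = FALSE],
                                   if (is.null(areas)) NULL else areas[idx]))
  })
}

#' Inter-cluster distance summaries
#'
#' Cluster positions are the per-cluster coordinate means; the summaries
#' are the pairwise centroid-to-centroid distances over all unordered
#' cluster pairs and the edge weights of the inter-cluster MST built over
#' those centroids. With a single cluster every value is 0.
#'
#' @param cs A `cluster_set`.
#' @return One-row tibble: `n_clusters`, `c2c_min`, `c2c_max`,
#'   `c2c_total`, `c2c_avg`, `mst_min`, `mst_max`, `mst_total`, `mst_avg`.
#' @export
inter_cluster_summary <- function(cs) {
  stopifnot(inherits(cs, "cluster_set"))
  if (!length(cs$clusters)) stop("empty cluster set", call. = FALSE)
  xy <- as_coord_matrix(cs$vertices)
  cents <- t(vapply(cs$clusters, function(idx)
    colMeans(xy[idx, , drop = FALSE]), numeric(2)))
  k <- nrow(cents)
  if (k == 1L) {
    return(tibble::tibble(n_clusters = 1L, c2c_min = 0, c2c_max = 0,
                          c2c_total = 0, c2c_avg = 0, mst_min = 0,
                          mst_max = 0, mst_total = 0, mst_avg = 0))
  }
  d <- as.numeric(stats::dist(cents))
  w <- build_mst(cents)$edges$weight
  tibble::tibble(n_clusters = k,
                 c2c_min = min(d), c2c_max = max(d),
                 c2c_total = sum(d), c2c_avg = mean(d),
                 mst_min = min(w), mst_max = max(w),
                 mst_total = sum(w), mst_avg = mean(w))
}

#' Inter-cluster MST over cluster centroids
#'
#' Convenience accessor for plotting/export: the MST built over the
#' per-cluster mean positions.
#'
#' @param cs A `cluster_set`.
#' @return An `mst_graph` over the cluster centroids.
#' @export
inter_cluster_mst <- function(cs) {
  stopifnot(inherits(cs, "cluster_set"))
  xy <- as_coord_matrix(cs$vertices)
  cents <- t(vapply(cs$clusters, function(idx)
    colMeans(xy[idx, , drop = FALSE]), numeric(2)))
  build_mst(cents)
}

#' Cluster nuclei by MST inconsistent-edge removal
#'
#' One-call wrapper: build the centroid MST and cut it. The default is the
#' 10-pixel weight threshold.
#'
#' @inheritParams build_mst
#' @inheritParams cut_edges
#' @return A `cluster_set`.
#' @export
cluster_nuclei <- function(centroids, mode = c("threshold", "top_k"),
                           value = 10) {
  cut_edges(build_mst(centroids), mode = match.arg(mode), value = value)
}
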