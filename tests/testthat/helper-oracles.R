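# Independent oracles used only by the tests. These deliberately avoid
# the package's code paths: Kruskal instead of Prim, Prufer-sequence
# enumeration instead of greedy growth, monotone-chain hull instead of
# grDevices::chull, plain accumulation loops instead of vectorised
# summaries.

# all pairwise edges of a point set
oracle_edges <- function(xy) {
  n <- nrow(xy)
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      out <- rbind(out, c(i, j, sqrt(sum((xy[i, ] - xy[j, ])^2))))
    }
  }
  out
}

# Kruskal MST total weight (union-find)
oracle_kruskal_edges <- function(xy) {
  n <- nrow(xy)
  if (n <= 1) return(matrix(numeric(0), 0, 3))
  e <- oracle_edges(xy)
  e <- e[order(e[, 3]), , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  keep <- logical(nrow(e))
  for (r in seq_len(nrow(e))) {
    a <- find(e[r, 1]); b <- find(e[r, 2])
    if (a != b) { parent[a] <- b; keep[r] <- TRUE }
  }
  e[keep, , drop = FALSE]
}

oracle_mst_total <- function(xy) sum(oracle_kruskal_edges(xy)[, 3])

# exhaustive minimum spanning-tree weight by enumerating every labelled
# tree on n vertices through its Prufer sequence (n^(n-2) trees)
oracle_exhaustive_mst <- function(xy) {
  n <- nrow(xy)
  if (n <= 1) return(0)
  d <- as.matrix(stats::dist(xy))
  if (n == 2) return(d[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf
  for (s in seq_len(nrow(seqs))) {
    pruf <- seqs[s, ]
    degree <- rep(1L, n)
    for (v in pruf) degree[v] <- degree[v] + 1L
    total <- 0
    avail <- degree
    pr <- pruf
    for (k in seq_len(n - 2)) {
      leaf <- which(avail == 1L)[1]
      total <- total + d[leaf, pr[k]]
      avail[leaf] <- 0L
      avail[pr[k]] <- avail[pr[k]] - 1L
    }
    u <- which(avail == 1L)
    total <- total + d[u[1], u[2]]
    if (total < best) best <- total
  }
  best
}

# Andrew monotone-chain convex hull area
oracle_hull_area <- function(xy) {
  xy <- unique(xy[order(xy[, 1], xy[, 2]), , drop = FALSE])
  n <- nrow(xy)
  if (n < 3) return(0)
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  build <- function(idx) {
    h <- integer(0)
    for (i in idx) {
      while (length(h) >= 2 &&
             cross(xy[h[length(h) - 1], ], xy[h[length(h)], ],
                   xy[i, ]) <= 0) {
        h <- h[-length(h)]
      }
      h <- c(h, i)
    }
    h
  }
  lower <- build(seq_len(n))
  upper <- build(rev(seq_len(n)))
  hull <- c(lower[-length(lower)], upper[-length(upper)])
  if (length(hull) < 3) return(0)
  px <- xy[hull, 1]; py <- xy[hull, 2]
  abs(sum(px * c(py[-1], py[1]) - c(px[-1], px[1]) * py)) / 2
}

# straight-line re-implementation of the full 26-feature vector from a
# list of per-cluster coordinate matrices (row, col)
oracle_features <- function(members) {
  k <- length(members)
  per <- lapply(members, function(xy) {
    n <- nrow(xy)
    if (n == 1) {
      list(pmin = 0, pmax = 0, ptot = 0, pavg = 0,
           mmin = 0, mmax = 0, mtot = 0, area = 0)
    } else {
      dd <- numeric(0)
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        dd <- c(dd, sqrt(sum((xy[i, ] - xy[j, ])^2)))
      }
      me <- oracle_kruskal_edges(xy)[, 3]
      list(pmin = min(dd), pmax = max(dd), ptot = sum(dd),
           pavg = mean(dd), mmin = min(me), mmax = max(me),
           mtot = sum(me), area = oracle_hull_area(xy))
    }
  })
  g <- function(f) vapply(per, `[[`, numeric(1), f)
  cents <- t(vapply(members, colMeans, numeric(2)))
  if (k == 1) {
    inter <- list(cmin = 0, cmax = 0, ctot = 0, cavg = 0,
                  immin = 0, immax = 0, imtot = 0, imavg = 0)
  } else {
    cd <- numeric(0)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      cd <- c(cd, sqrt(sum((cents[i, ] - cents[j, ])^2)))
    }
    ie <- oracle_kruskal_edges(cents)[, 3]
    inter <- list(cmin = min(cd), cmax = max(cd), ctot = sum(cd),
                  cavg = mean(cd), immin = min(ie), immax = max(ie),
                  imtot = sum(ie), imavg = mean(ie))
  }
  c(total_intra_mst_total = sum(g("mtot")),
    total_intra_n2n_max = sum(g("pmax")),
    inter_c2c_total = inter$ctot,
    inter_mst_total = inter$imtot,
    n_clusters = k,
    total_intra_mst_max = sum(g("mmax")),
    avg_intra_n2n_min = mean(g("pmin")),
    avg_intra_n2n_max = mean(g("pmax")),
    avg_intra_mst_max = mean(g("mmax")),
    avg_cluster_area = mean(g("area")),
    total_intra_n2n_total = sum(g("ptot")),
    total_intra_mst_min = sum(g("mmin")),
    total_intra_n2n_min = sum(g("pmin")),
    inter_mst_max = inter$immax,
    avg_intra_mst_total = mean(g("mtot")),
    avg_intra_mst_min = mean(g("mmin")),
    total_cluster_area = sum(g("area")),
    inter_mst_avg = inter$imavg,
    avg_intra_n2n_avg = mean(g("pavg")),
    inter_c2c_avg = inter$cavg,
    min_cluster_area = min(g("area")),
    avg_intra_n2n_total = mean(g("ptot")),
    inter_c2c_min = inter$cmin,
    inter_c2c_max = inter$cmax,
    max_cluster_area = max(g("area")),
    inter_mst_min = inter$immin)
}

# random well-separated cluster geometry; returns the member coordinate
# list plus the matching cluster_set built through the package
random_cluster_world <- function(seed, k_range = 2:5, n_range = 1:7) {
  set.seed(seed)
  k <- sample(k_range, 1)
  centers <- matrix(runif(2 * k, 0, 400), k, 2)
  while (k > 1 && min(stats::dist(centers)) < 120) {
    centers <- matrix(runif(2 * k, 0, 400), k, 2)
  }
  members <- lapply(seq_len(k), function(i) {
    n <- sample(n_range, 1)
    sweep(matrix(runif(2 * n, -15, 15), n, 2), 2, centers[i, ], "+")
  })
  xy <- do.call(rbind, members)
  colnames(xy) <- c("row", "col")
  cs <- cut_edges(build_mst(xy), mode = "threshold", value = 60)
  list(members = members, cs = cs)
}

# brute-force Otsu: maximise between-class variance over all thresholds
oracle_otsu <- function(x) {
  x <- as.integer(round(x))
  best_t <- 0L; best_v <- -Inf
  for (t in 0:255) {
    lo <- x[x <= t]; hi <- x[x > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(x); w1 <- 1 - w0
    v <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (v > best_v) { best_v <- v; best_t <- t }
  }
  best_t
}

# plain per-pixel accumulation of channel mean/sd (population)
oracle_channel_stats <- function(mat) {
  n <- length(mat)
  s <- 0; s2 <- 0
  for (v in as.numeric(mat)) { s <- s + v; s2 <- s2 + v^2 }
  c(mean = s / n, sd = sqrt(s2 / n - (s / n)^2))
}

match_rate <- function(truth_xy, found_xy, radius = 5) {
  if (nrow(found_xy) == 0) return(c(recall = 0, precision = 0))
  d2 <- outer(rowSums(truth_xy^2), rep(1, nrow(found_xy))) +
    outer(rep(1, nrow(truth_xy)), rowSums(found_xy^2)) -
    2 * truth_xy %*% t(found_xy)
  d2 <- pmax(d2, 0)
  c(recall = mean(sqrt(apply(d2, 1, min)) <= radius),
    precision = mean(sqrt(apply(d2, 2, min)) <= radius))
}
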