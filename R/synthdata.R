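# Synthetic H&E-like fixtures: (a) patch images with ground-truth nuclei
# arranged in spatial clusters, rendered through the Beer-Lambert stain
# model so the deconvolution stage is genuinely exercised; (b) feature
# tables with controllable class separation for the classifiers.

#' Specification for a synthetic H&E-like patch
#'
#' Describes a patch containing `n_clusters` spatial clusters of
#' elliptical hematoxylin-dark nuclei on a weak eosin background. Nuclei
#' positions are Gaussian around their cluster center; when
#' `disjoint = TRUE` nuclei are rejection-sampled so that no two overlap.
#' The seed fully determines the output.
#'
#' @param size Patch side length in pixels (default 512, the working
#'   patch size of the pipeline).
#' @param n_clusters Number of nucleus clusters.
#' @param nuclei_per_cluster Nuclei per cluster (fixed count).
#' @param cluster_spread Within-cluster positional SD in pixels; member
#'   offsets are truncated at `2 * cluster_spread` so every cluster has a
#'   bounded footprint.
#' @param cluster_sep Minimum distance between cluster centers (default
#'   `7 * cluster_spread`): together with the offset truncation this
#'   guarantees that members of different clusters are farther apart than
#'   `3 * cluster_spread`, so an MST cut at that threshold recovers the
#'   generated clusters exactly.
#' @param radius_range Nucleus semi-axis range in pixels.
#' @param nucleus_conc Mean hematoxylin concentration of a nucleus
#'   (OD units along the stain vector).
#' @param background_conc Eosin concentration of the background.
#' @param noise_sd Gaussian pixel noise SD (8-bit units).
#' @param disjoint Forbid overlapping nuclei (default TRUE).
#' @param seed Integer seed.
#' @return A list of class `patch_spec`.
#' @export
patch_spec <- function(size = 512L, n_clusters = 6L,
                       nuclei_per_cluster = 8L, cluster_spread = 20,
                       cluster_sep = 7 * cluster_spread,
                       radius_range = c(4, 7), nucleus_conc = 0.9,
                       background_conc = 0.25, noise_sd = 3,
                       disjoint = TRUE, seed = 1L) {
  structure(list(size = as.integer(size), n_clusters = as.integer(n_clusters),
                 nuclei_per_cluster = as.integer(nuclei_per_cluster),
                 cluster_spread = cluster_spread, cluster_sep = cluster_sep,
                 radius_range = radius_range, nucleus_conc = nucleus_conc,
                 background_conc = background_conc, noise_sd = noise_sd,
                 disjoint = disjoint, seed = as.integer(seed)),
            class = "patch_spec")
}

#' Grade-preset patch specifications
#'
#' Qualitative emulation of how nuclear cluster architecture changes with
#' grade: grade 3 has a few loose clusters, grade 4 more and denser
#' clusters, grade 5 many dense sheets. The presets are documentation of
#' the synthetic world, not claims about real tissue.
#'
#' @param grade `"grade3"`, `"grade4"` or `"grade5"`.
#' @param size Patch side length.
#' @param seed Integer seed.
#' @return A `patch_spec`.
#' @export
grade_preset <- function(grade = c("grade3", "grade4", "grade5"),
                         size = 512L, seed = 1L) {
  grade <- match.arg(grade)
  args <- switch(grade,
    grade3 = list(n_clusters = 5L, nuclei_per_cluster = 8L,
                  cluster_spread = 20),
    grade4 = list(n_clusters = 8L, nuclei_per_cluster = 10L,
                  cluster_spread = 16, radius_range = c(4, 6.5)),
    grade5 = list(n_clusters = 12L, nuclei_per_cluster = 10L,
                  cluster_spread = 14, radius_range = c(4, 5.5)))
  do.call(patch_spec, c(args, list(size = size, seed = seed)))
}

#' Generate a synthetic H&E-like patch
#'
#' Renders the spec through the two-stain Beer--Lambert model: each pixel
#' intensity is `255 * 10^-(c_H M_H + c_E M_E)` per RGB channel, with the
#' nucleus hematoxylin concentration inside the elliptical nuclei and the
#' weak eosin background elsewhere, plus Gaussian noise. Ground truth
#' (label mask and centroid/cluster table) is returned alongside.
#'
#' @param spec A [patch_spec()].
#' @return List: `image` (RGB array 0--255), `mask` (integer label
#'   matrix), `centroids` (tibble `label`, `row`, `col`, `cluster`,
#'   `area`; coordinates are the true ellipse centers, 0-based).
#' @export
generate_patch <- function(spec) {
  stopifnot(inherits(spec, "patch_spec"))
  n <- spec$size
  with_seed(spec$seed, {
    margin <- max(2 * spec$cluster_spread, 25)
    centers <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(centers) < spec$n_clusters) {
      cand <- runif(2, margin, n - margin)
      ok <- !nrow(centers) ||
        min(sqrt(rowSums((centers - matrix(cand, nrow(centers), 2,
                                           byrow = TRUE))^2))) >=
        spec$cluster_sep
      if (ok) centers <- rbind(centers, cand)
      tries <- tries + 1L
      if (tries > 20000L) {
        stop("infeasible packing: cannot place cluster centers", call. = FALSE)
      }
    }
    nuclei <- list()
    if (spec$n_clusters > 0L) {
      for (cl in seq_len(spec$n_clusters)) {
        for (i in seq_len(spec$nuclei_per_cluster)) {
          placed <- FALSE
          for (att in seq_len(1000L)) {
            off <- rnorm(2, 0, spec$cluster_spread)
            if (sum(off^2) > (2 * spec$cluster_spread)^2) next
            pos <- centers[cl, ] + off
            a <- runif(1, spec$radius_range[1], spec$radius_range[2])
            b <- runif(1, spec$radius_range[1], spec$radius_range[2])
            rmax <- max(a, b)
            if (any(pos < rmax + 2) || any(pos > n - rmax - 2)) next
            if (spec$disjoint && length(nuclei)) {
              prev <- vapply(nuclei, function(u)
                sqrt(sum((u$pos - pos)^2)) - u$rmax, numeric(1))
              if (any(prev < rmax + 1)) next
            }
            nuclei[[length(nuclei) + 1L]] <-
              list(pos = pos, a = a, b = b,
                   theta = runif(1, 0, pi), cluster = cl, rmax = rmax)
            placed <- TRUE
            break
          }
          if (!placed) {
            stop("infeasible packing: too many nuclei for the area",
                 call. = FALSE)
          }
        }
      }
    }
    mask <- matrix(0L, n, n)
    conc_h <- matrix(0, n, n)
    for (k in seq_along(nuclei)) {
      nu <- nuclei[[k]]
      r0 <- floor(nu$pos[1] - nu$rmax); r1 <- ceiling(nu$pos[1] + nu$rmax)
      c0 <- floor(nu$pos[2] - nu$rmax); c1 <- ceiling(nu$pos[2] + nu$rmax)
      rr <- r0:r1; cc <- c0:c1
      dr <- outer(rr - nu$pos[1], rep(1, length(cc)))
      dc <- outer(rep(1, length(rr)), cc - nu$pos[2])
      u <- dr * cos(nu$theta) + dc * sin(nu$theta)
      v <- -dr * sin(nu$theta) + dc * cos(nu$theta)
      inside <- (u / nu$a)^2 + (v / nu$b)^2 <= 1
      sub_r <- rep(rr, length(cc))[inside]
      sub_c <- rep(cc, each = length(rr))[inside]
      idx <- cbind(sub_r + 1L, sub_c + 1L)
      mask[idx] <- k
      conc_h[idx] <- spec$nucleus_conc * runif(1, 0.85, 1.15)
    }
    m <- default_stain_matrix()
    img <- array(0, dim = c(n, n, 3))
    for (ch in 1:3) {
      od <- conc_h * m[1, ch] + spec$background_conc * m[2, ch]
      img[, , ch] <- 255 * 10^(-od)
    }
    if (spec$noise_sd > 0) {
      img <- img + array(rnorm(length(img), 0, spec$noise_sd), dim = dim(img))
    }
    img <- clamp(img, 0, 255)
    centroids <- if (length(nuclei)) {
      tibble::tibble(
        label = seq_along(nuclei),
        row = vapply(nuclei, function(u) u$pos[1], numeric(1)),
        col = vapply(nuclei, function(u) u$pos[2], numeric(1)),
        cluster = vapply(nuclei, function(u) u$cluster, integer(1)),
        area = as.integer(tabulate(mask[mask > 0], nbins = length(nuclei))))
    } else {
      tibble::tibble(label = integer(), row = numeric(), col = numeric(),
                     cluster = integer(), area = integer())
    }
    list(image = img, mask = mask, centroids = centroids)
  })
}

#' Generate a synthetic 26-feature table with controlled class separation
#'
#' Draws balanced per-class Gaussian feature vectors on the scale of the
#' 26 cluster features. By default the class means of every other feature
#' (13 "signal" features) are shifted by `separation` within-class SDs
#' between adjacent grades; `separation = 0` gives identical classes
#' (chance-level world). Custom `class_means`/`class_sds` matrices
#' (`n_classes x 26`) override the defaults. Distance/area features are
#' clipped at 0 and the cluster count is rounded to a non-negative
#' integer.
#'
#' @param n_per_class Rows per class.
#' @param class_means,class_sds Optional `n_classes x 26` matrices.
#' @param separation Between-adjacent-class mean shift in SD units used
#'   when `class_means` is not supplied (default 3).
#' @param classes Class labels (default the three grades).
#' @param seed Integer seed.
#' @return Tibble with the 26 feature columns plus a `grade` factor.
#' @export
generate_feature_table <- function(n_per_class = 100L, class_means = NULL,
                                   class_sds = NULL, separation = 3,
                                   classes = c("grade3", "grade4", "grade5"),
                                   seed = 1L) {
  stopifnot(n_per_class >= 1L)
  p <- 26L
  nms <- feature_names()
  n_cls <- length(classes)
  base_mean <- c(400, 120, 900, 600, 10, 90, 40, 110, 25, 3000,
                 2500, 30, 45, 160, 45, 4, 28000, 120, 60, 300,
                 400, 260, 60, 500, 6000, 35)
  base_sd <- pmax(base_mean * 0.2, 0.5)
  if (is.null(class_means)) {
    signal <- seq(1, p, by = 2)
    class_means <- t(vapply(seq_len(n_cls), function(g) {
      mu <- base_mean
      mu[signal] <- mu[signal] + (g - 1) * separation * base_sd[signal]
      mu
    }, numeric(p)))
  }
  if (is.null(class_sds)) {
    class_sds <- matrix(base_sd, n_cls, p, byrow = TRUE)
  }
  class_means <- as.matrix(class_means); class_sds <- as.matrix(class_sds)
  if (!all(dim(class_means) == c(n_cls, p)) ||
      !all(dim(class_sds) == c(n_cls, p))) {
    stop(sprintf("class_means/class_sds must be %d x %d", n_cls, p),
         call. = FALSE)
  }
  with_seed(seed, {
    rows <- lapply(seq_len(n_cls), function(g) {
      X <- matrix(rnorm(n_per_class * p), n_per_class, p)
      X <- sweep(sweep(X, 2, class_sds[g, ], "*"), 2, class_means[g, ], "+")
      X <- pmax(X, 0)
      X[, nms == "n_clusters"] <- pmax(round(X[, nms == "n_clusters"]), 0)
      X
    })
    tab <- do.call(rbind, rows)
    colnames(tab) <- nms
    out <- tibble::as_tibble(as.data.frame(tab))
    out$grade <- factor(rep(classes, each = n_per_class), levels = classes)
    out
  })
}
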