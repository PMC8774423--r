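#' Convert RGB to HSI colour space
#'
#' Classical hue/saturation/intensity decomposition:
#' `I = (R + G + B) / 3`, `S = 1 - 3 min(R, G, B) / (R + G + B)` (0 for
#' black pixels), and `H` from the standard angular formula. Saturation of
#' the hematoxylin-stain image is the working channel for nuclei
#' segmentation: chromatin is the most saturated structure there.
#'
#' @param img Numeric RGB array on the 0--255 scale.
#' @return `[rows, cols, 3]` array: hue in degrees `[0, 360)`, saturation
#'   in `[0, 1]`, intensity on the input scale. Scale saturation by 255
#'   when an 8-bit channel is needed.
#' @export
rgb_to_hsi <- function(img) {
  assert_rgb(img)
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  s_sum <- r + g + b
  i <- s_sum / 3
  mn <- pmin(r, g, b)
  s <- ifelse(s_sum > 0, 1 - 3 * mn / s_sum, 0)
  num <- 0.5 * ((r - g) + (r - b))
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  theta <- acos(clamp(ifelse(den > 0, num / den, 0), -1, 1)) * 180 / pi
  h <- ifelse(b <= g, theta, 360 - theta)
  h[den == 0] <- 0
  out <- array(0, dim = dim(img))
  out[, , 1] <- h; out[, , 2] <- s; out[, , 3] <- i
  out
}

#' Percentile contrast stretch
#'
#' Linearly maps the `low_pct`/`high_pct` percentile intensities to 0/255,
#' clipping outside. The mapping is monotone non-decreasing; a constant
#' image is returned unchanged (no stretch is possible).
#'
#' @param img Single-channel numeric matrix, nominally 0--255.
#' @param low_pct,high_pct Percentiles mapped to 0 and 255
#'   (defaults 1 and 99).
#' @return Stretched matrix with values in `[0, 255]`.
#' @export
adjust_contrast <- function(img, low_pct = 1, high_pct = 99) {
  assert_channel(img)
  stopifnot(low_pct >= 0, high_pct <= 100, low_pct < high_pct)
  qs <- quantile(img, c(low_pct, high_pct) / 100, names = FALSE)
  if (qs[2] <= qs[1]) return(img)
  clamp((img - qs[1]) * 255 / (qs[2] - qs[1]), 0, 255)
}

#' Global (Otsu) threshold
#'
#' Selects the threshold maximising between-class variance over the 256
#' integer levels and returns the binary foreground `img > t`. Nuclei are
#' high-saturation, so foreground is the upper class.
#'
#' @param img Single-channel matrix on the 0--255 scale (rounded to
#'   integers internally for the histogram).
#' @return Integer 0/1 matrix. A constant image yields an empty mask with
#'   a warning.
#' @export
global_threshold <- function(img) {
  assert_channel(img)
  x <- clamp(round(img), 0, 255)
  if (max(x) == min(x)) {
    warning("constant image: empty foreground")
    return(matrix(0L, nrow(img), ncol(img)))
  }
  h <- tabulate(as.integer(x) + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  t_star <- which.max(sigma_b) - 1L  # threshold level; foreground > t
  out <- matrix(0L, nrow(img), ncol(img))
  out[x > t_star] <- 1L
  attr(out, "threshold") <- t_star
  out
}

disc_offsets <- function(radius) {
  r <- seq(-floor(radius), floor(radius))
  grid <- expand.grid(dr = r, dc = r)
  keep <- grid$dr^2 + grid$dc^2 <= radius^2
  list(r = as.integer(grid$dr[keep]), c = as.integer(grid$dc[keep]))
}

binary_dilate <- function(mask, radius) {
  off <- disc_offsets(radius)
  cpp_morph(mask, off$r, off$c, FALSE)
}

binary_erode <- function(mask, radius) {
  off <- disc_offsets(radius)
  cpp_morph(mask, off$r, off$c, TRUE)
}

remove_small <- function(bw, min_area, connectivity = 8L) {
  lab <- cpp_label(bw, connectivity)
  if (max(lab) == 0L) return(bw)
  areas <- tabulate(lab[lab > 0L])
  drop <- which(areas < min_area)
  if (length(drop)) bw[lab %in% drop] <- 0L
  bw
}

# Distance-transform local maxima with greedy minimum-separation
# suppression (strongest peak first, then raster order on ties).
find_markers <- function(dist, mask, min_sep) {
  nr <- nrow(dist); nc <- ncol(dist)
  is_max <- mask != 0L
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- dist
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
    is_max <- is_max & (dist >= nb)
  }
  idx <- which(is_max & dist > 0)
  if (!length(idx)) return(NULL)
  ord <- order(-dist[idx], idx)
  idx <- idx[ord]
  rows <- (idx - 1L) %% nr
  cols <- (idx - 1L) %/% nr
  keep_r <- numeric(0); keep_c <- numeric(0)
  for (k in seq_along(idx)) {
    if (!length(keep_r) ||
        min((keep_r - rows[k])^2 + (keep_c - cols[k])^2) >= min_sep^2) {
      keep_r <- c(keep_r, rows[k]); keep_c <- c(keep_c, cols[k])
    }
  }
  cbind(row = keep_r, col = keep_c)
}

#' Split touching nuclei by marker-controlled watershed
#'
#' Markers are local maxima of the exact Euclidean distance transform of
#' the foreground, thinned so no two markers are closer than `min_sep`
#' pixels. The watershed then floods the negated distance transform from
#' the markers, restricted to the foreground, so every foreground pixel
#' receives exactly one label.
#'
#' @param bw Integer 0/1 foreground mask.
#' @param min_sep Minimum marker separation in pixels (default 7).
#' @return Integer label matrix (0 = background).
#' @export
split_touching_nuclei <- function(bw, min_sep = 7) {
  assert_channel(bw, "bw")
  bw <- matrix(as.integer(bw != 0), nrow(bw), ncol(bw))
  if (!any(bw != 0L)) return(matrix(0L, nrow(bw), ncol(bw)))
  d <- cpp_edt(bw)
  mk <- find_markers(d, bw, min_sep)
  markers <- matrix(0L, nrow(bw), ncol(bw))
  markers[cbind(mk[, "row"] + 1L, mk[, "col"] + 1L)] <- seq_len(nrow(mk))
  lab <- cpp_watershed(-d, markers, bw)
  # isolated foreground unreachable from any marker (shouldn't happen with
  # 8-connectivity, but keep the partition contract): label as own objects
  orphan <- bw != 0L & lab == 0L
  if (any(orphan)) {
    extra <- cpp_label(matrix(as.integer(orphan), nrow(bw)), 8L)
    lab[orphan] <- extra[orphan] + max(lab)
  }
  lab
}

#' Clean a label mask and extract the nucleus set
#'
#' Removes objects below `min_area`, applies per-object morphological
#' closing then opening with a disc structuring element (smoothing the
#' nuclear boundary without merging neighbours), relabels consecutively,
#' and computes per-nucleus centroids.
#'
#' @param label_mask Integer label matrix.
#' @param min_area Minimum object area in pixels (default 30).
#' @param se_radius Disc structuring-element radius in pixels (default 2).
#' @return A `nucleus_set`: list with `mask` (relabelled integer matrix)
#'   and `centroids`, a tibble with `label`, `row`, `col` (0-based pixel
#'   centers) and `area`.
#' @export
clean_mask <- function(label_mask, min_area = 30, se_radius = 2) {
  assert_channel(label_mask, "label_mask")
  nr <- nrow(label_mask); nc <- ncol(label_mask)
  out <- matrix(0L, nr, nc)
  labs <- sort(unique(label_mask[label_mask > 0]))
  next_lab <- 0L
  pad <- as.integer(ceiling(se_radius)) + 1L
  for (l in labs) {
    idx <- which(label_mask == l)
    if (length(idx) < min_area) next
    rows <- (idx - 1L) %% nr + 1L
    cols <- (idx - 1L) %/% nr + 1L
    r0 <- max(1L, min(rows) - pad); r1 <- min(nr, max(rows) + pad)
    c0 <- max(1L, min(cols) - pad); c1 <- min(nc, max(cols) + pad)
    sub <- matrix(0L, r1 - r0 + 1L, c1 - c0 + 1L)
    sub[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- 1L
    if (se_radius > 0) {
      sub <- binary_erode(binary_dilate(sub, se_radius), se_radius)  # closing
      sub <- binary_dilate(binary_erode(sub, se_radius), se_radius)  # opening
    }
    if (sum(sub) < min_area) next
    next_lab <- next_lab + 1L
    block <- out[r0:r1, c0:c1]
    block[sub != 0L & block == 0L] <- next_lab
    out[r0:r1, c0:c1] <- block
  }
  nucleus_set(out)
}

#' Construct a nucleus set from a label mask
#'
#' @param mask Integer label matrix (labels need not be consecutive; they
#'   are relabelled in ascending order).
#' @return A `nucleus_set` (see [clean_mask()]).
#' @export
nucleus_set <- function(mask) {
  assert_channel(mask, "mask")
  labs <- sort(unique(mask[mask > 0]))
  relab <- matrix(0L, nrow(mask), ncol(mask))
  cents <- vector("list", length(labs))
  nr <- nrow(mask)
  for (k in seq_along(labs)) {
    idx <- which(mask == labs[k])
    relab[idx] <- k
    rows <- (idx - 1L) %% nr
    cols <- (idx - 1L) %/% nr
    cents[[k]] <- tibble::tibble(label = k, row = mean(rows),
                                 col = mean(cols), area = length(idx))
  }
  centroids <- if (length(cents)) dplyr::bind_rows(cents) else
    tibble::tibble(label = integer(), row = numeric(), col = numeric(),
                   area = integer())
  structure(list(mask = relab, centroids = centroids),
            class = "nucleus_set")
}

#' @export
print.nucleus_set <- function(x, ...) {
  cat(sprintf("<nucleus_set> %d nuclei in a %d x %d mask\n",
              nrow(x$centroids), nrow(x$mask), ncol(x$mask)))
  print(x$centroids, n = 5)
  invisible(x)
}

#' Segmentation configuration
#'
#' Collects every stage parameter of [segment_nuclei()] with the package
#' defaults. All values are plain numbers so the config serialises to
#' JSON losslessly.
#'
#' @param contrast_low,contrast_high Percentiles for the contrast stretch.
#' @param min_area Minimum nucleus area (px); applied before and after the
#'   watershed.
#' @param se_radius Disc structuring-element radius (px) for the
#'   closing/opening cleanup.
#' @param marker_min_sep Minimum watershed marker separation (px).
#' @param stain_matrix 2 x 3 H&E stain matrix.
#' @return A list of class `segment_config`.
#' @export
segment_config <- function(contrast_low = 1, contrast_high = 99,
                           min_area = 30, se_radius = 2,
                           marker_min_sep = 7,
                           stain_matrix = default_stain_matrix()) {
  structure(list(contrast_low = contrast_low, contrast_high = contrast_high,
                 min_area = min_area, se_radius = se_radius,
                 marker_min_sep = marker_min_sep,
                 stain_matrix = stain_matrix),
            class = "segment_config")
}

#' Segment cell nuclei in an H&E patch
#'
#' Full segmentation chain: optional stain normalization against a
#' reference, optical-density deconvolution, reconstruction of the
#' hematoxylin-stain image, HSI conversion, saturation-channel contrast
#' stretch, Otsu thresholding, small-object removal, marker-controlled
#' watershed splitting of touching nuclei, and morphological cleanup.
#' Deterministic for a fixed input and configuration.
#'
#' @param img RGB patch on the 0--255 scale.
#' @param config A [segment_config()].
#' @param reference Optional `stain_stats` (or RGB reference image) for
#'   stain normalization; skipped when `NULL`.
#' @return A `nucleus_set`.
#' @export
segment_nuclei <- function(img, config = segment_config(),
                           reference = NULL) {
  assert_rgb(img)
  if (!is.null(reference)) img <- normalize_stain(img, reference)
  od <- rgb_to_od(img)
  conc <- deconvolve_stains(od, config$stain_matrix)
  h_img <- reconstruct_stain_image(conc$h, config$stain_matrix[1, ])
  s8 <- rgb_to_hsi(h_img)[, , 2] * 255
  s_adj <- adjust_contrast(s8, config$contrast_low, config$contrast_high)
  bw <- suppressWarnings(global_threshold(s_adj))
  bw <- remove_small(bw, config$min_area)
  lab <- split_touching_nuclei(bw, config$marker_min_sep)
  clean_mask(lab, config$min_area, config$se_radius)
}
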