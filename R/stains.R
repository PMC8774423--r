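#' Default H&E stain matrix
#'
#' RGB optical-density components of the two stain vectors used for
#' deconvolution: hematoxylin `(0.587, 0.754, 0.294)` and eosin
#' `(0.136, 0.833, 0.536)`. Both rows are unit vectors to within 0.001.
#' A different matrix (e.g. estimated from a reference slide) can be passed
#' to [deconvolve_stains()] as a 2 x 3 matrix with rows `hematoxylin`,
#' `eosin`.
#'
#' @return A 2 x 3 numeric matrix, rows `hematoxylin`/`eosin`,
#'   columns `R`/`G`/`B`.
#' @export
default_stain_matrix <- function() {
  matrix(c(0.587, 0.754, 0.294,
           0.136, 0.833, 0.536),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("hematoxylin", "eosin"), c("R", "G", "B")))
}

# RGB (0..255) <-> CIE LAB, sRGB D65 white point (grDevices convention).
rgb_to_lab <- function(img) {
  assert_rgb(img)
  lab <- grDevices::convertColor(px_mat(img) / 255, from = "sRGB", to = "Lab")
  px_arr(lab, dim(img))
}

lab_to_rgb <- function(lab) {
  rgb <- grDevices::convertColor(px_mat(lab), from = "Lab", to = "sRGB")
  px_arr(clamp(rgb, 0, 1) * 255, dim(lab))
}

#' Per-channel LAB statistics of an RGB image
#'
#' Converts the image to CIE LAB (sRGB, D65 white point) and returns the
#' mean and standard deviation of each channel over all pixels. These
#' statistics drive [normalize_stain()]: the reference image is summarised
#' once and its statistics reused for every source patch.
#'
#' @param img Numeric `[rows, cols, 3]` RGB array on the 0--255 scale.
#' @return A one-row tibble of class `stain_stats` with columns `mean_l`,
#'   `mean_a`, `mean_b`, `sd_l`, `sd_a`, `sd_b` and a `white_point`
#'   attribute recording the conversion convention.
#' @export
compute_lab_stats <- function(img) {
  assert_rgb(img)
  lab <- px_mat(rgb_to_lab(img))
  n <- nrow(lab)
  mu <- colMeans(lab)
  # population SD: the normalization ratio is scale-free in the n/(n-1)
  # factor only if both images use the same convention; population keeps
  # the constant-image case exactly 0
  sdv <- sqrt(colMeans(lab^2) - mu^2)
  sdv[sdv < 0] <- 0
  out <- tibble::tibble(
    mean_l = mu[1], mean_a = mu[2], mean_b = mu[3],
    sd_l = sdv[1], sd_a = sdv[2], sd_b = sdv[3]
  )
  attr(out, "white_point") <- "sRGB/D65"
  class(out) <- c("stain_stats", class(out))
  out
}

#' Modified-LAB stain normalization
#'
#' Matches the colour statistics of a source patch to a reference in LAB
#' space. Each channel is mapped as
#' \deqn{x' = (x - \bar x_{src})\,\frac{\hat x_{tar}}{\hat x_{src}} +
#'   \frac{x + \bar x_{tar}}{2}}
#' where the bar denotes the channel mean and the hat the channel standard
#' deviation. Note the second term averages the *pixel value* with the
#' reference mean -- a deliberate modification of the classical Reinhard
#' transfer. A consequence worth knowing: normalizing an image against its
#' own statistics is *not* the identity map (the output is brightened
#' towards `1.5 x` around the mean).
#'
#' Out-of-gamut values after the inverse LAB transform are clipped to the
#' 8-bit range, not rescaled.
#'
#' @param source Numeric RGB array on the 0--255 scale.
#' @param reference Either a `stain_stats` row (from [compute_lab_stats()])
#'   or an RGB array to summarise.
#' @return Normalized RGB array, same shape as `source`, values in
#'   `[0, 255]`.
#' @export
normalize_stain <- function(source, reference) {
  assert_rgb(source, "source")
  tar <- if (inherits(reference, "stain_stats")) reference else
    compute_lab_stats(reference)
  src <- compute_lab_stats(source)
  src_sd <- c(src$sd_l, src$sd_a, src$sd_b)
  if (any(src_sd == 0)) {
    stop("degenerate source image: zero standard deviation in a LAB channel",
         call. = FALSE)
  }
  tar_sd <- c(tar$sd_l, tar$sd_a, tar$sd_b)
  if (any(tar_sd <= 0)) {
    stop("reference statistics must have positive standard deviations",
         call. = FALSE)
  }
  src_mu <- c(src$mean_l, src$mean_a, src$mean_b)
  tar_mu <- c(tar$mean_l, tar$mean_a, tar$mean_b)
  lab <- px_mat(rgb_to_lab(source))
  for (ch in 1:3) {
    lab[, ch] <- channel_transfer(lab[, ch], src_mu[ch], src_sd[ch],
                                  tar_mu[ch], tar_sd[ch])
  }
  lab_to_rgb(px_arr(lab, dim(source)))
}

# the modified per-channel transfer map: classical Reinhard scaling plus
# the pixel/target-mean average as the recentring term
channel_transfer <- function(x, mean_src, sd_src, mean_tar, sd_tar) {
  (x - mean_src) * (sd_tar / sd_src) + (x + mean_tar) / 2
}

#' Convert an RGB image to optical density
#'
#' Beer--Lambert transform `OD = -log10(I / 255)` per channel against a
#' brightfield intensity of 255. Intensities are clamped to at least 1
#' before the log so zero pixels map to a finite maximum OD
#' (`-log10(1/255) ~ 2.407`) rather than infinity.
#'
#' @param img Numeric RGB array on the 0--255 scale.
#' @return Numeric array of the same shape with non-negative OD values;
#'   exactly 0 where the input is at the brightfield level.
#' @export
rgb_to_od <- function(img) {
  assert_rgb(img)
  -log10(clamp(img, 1, 255) / 255)
}

#' Unmix an OD image into stain concentrations
#'
#' Projects each pixel's OD vector onto the two stain vectors by least
#' squares (the Moore--Penrose reading of "dividing" a 3-vector by a 2 x 3
#' stain matrix): `(c_H, c_E)` minimises
#' `|| c_H * M_H + c_E * M_E - OD ||^2`. Concentrations can come out
#' slightly negative for pixels off the stain plane; they are reported
#' as-is here and clipped at reconstruction.
#'
#' @param od OD array from [rgb_to_od()].
#' @param stain_matrix 2 x 3 stain matrix; rows hematoxylin and eosin.
#'   Default [default_stain_matrix()].
#' @return List with matrices `h` and `e` (`[rows, cols]`) of per-pixel
#'   stain concentrations.
#' @export
deconvolve_stains <- function(od, stain_matrix = default_stain_matrix()) {
  if (!is.array(od) || length(dim(od)) != 3L || dim(od)[3] != 3L) {
    stop("`od` must be a [rows, cols, 3] array", call. = FALSE)
  }
  m <- as.matrix(stain_matrix)
  stopifnot(nrow(m) == 2L, ncol(m) == 3L)
  gram <- m %*% t(m)
  if (abs(det(gram)) < 1e-10) {
    stop("stain matrix rows are collinear; cannot deconvolve", call. = FALSE)
  }
  # normal equations: C = OD M' (M M')^-1, per pixel
  conc <- px_mat(od) %*% t(m) %*% solve(gram)
  dims <- dim(od)[1:2]
  list(h = matrix(conc[, 1], dims[1], dims[2]),
       e = matrix(conc[, 2], dims[1], dims[2]))
}

#' Reconstruct a single-stain RGB image from a concentration map
#'
#' Inverse Beer--Lambert along one stain vector:
#' `I_c = 255 * 10^(-conc * row[c])` for each RGB channel `c`, using the
#' same log base as [rgb_to_od()] so that the
#' `rgb -> od -> deconvolve -> reconstruct` round trip closes for pixels in
#' the stain span. Negative concentrations are clipped to 0 (physical
#' non-negativity).
#'
#' @param conc Concentration matrix (e.g. `$h` from [deconvolve_stains()]).
#' @param stain_row Length-3 stain vector (a row of the stain matrix).
#' @return RGB array on the 0--255 scale.
#' @export
reconstruct_stain_image <- function(conc, stain_row) {
  assert_channel(conc, "conc")
  stopifnot(length(stain_row) == 3L)
  conc <- pmax(conc, 0)
  out <- array(0, dim = c(dim(conc), 3L))
  for (ch in 1:3) {
    out[, , ch] <- clamp(255 * 10^(-conc * stain_row[ch]), 0, 255)
  }
  out
}
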