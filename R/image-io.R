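#' Read an 8-bit RGB patch image
#'
#' Reads a PNG patch into the package's working representation: a numeric
#' `[rows, cols, 3]` array on the 0--255 scale. Grayscale PNGs are expanded
#' to three identical channels; an alpha channel, if present, is dropped.
#'
#' @param path Path to a PNG file.
#' @return Numeric `[rows, cols, 3]` array, values in `[0, 255]`.
#' @export
read_patch <- function(path) {
  img <- png::readPNG(path)
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' Write an 8-bit RGB patch image
#'
#' @param img Numeric `[rows, cols, 3]` array on the 0--255 scale; values are
#'   clipped and rounded.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_patch <- function(img, path) {
  assert_rgb(img)
  png::writePNG(clamp(round(img), 0, 255) / 255, path)
  invisible(path)
}

#' Write a label mask as plain-text PGM (P2)
#'
#' Label masks (0 = background, k = object k) are persisted in the portable
#' graymap text format, which carries 16-bit values and needs no binary
#' codec.
#'
#' @param mask Integer matrix of labels.
#' @param path Output path (`.pgm`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  assert_channel(mask, "mask")
  maxval <- max(1L, max(mask))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(mask), nrow(mask)), as.character(maxval)), con)
  # PGM is row-major
  write(t(mask), con, ncolumns = ncol(mask))
  invisible(path)
}

#' Read a plain-text PGM (P2) label mask
#'
#' @param path Path written by [write_mask()].
#' @return Integer matrix of labels.
#' @export
read_mask <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  stopifnot(toks[1] == "P2")
  nc <- as.integer(toks[2])
  nr <- as.integer(toks[3])
  vals <- as.integer(toks[-(1:4)])
  matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
}
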