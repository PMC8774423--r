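# Internal helpers shared across modules.

# Images are numeric arrays [rows, cols, 3] on the 8-bit scale (0..255),
# stored row/col in the usual R matrix orientation. Coordinates are
# (row, col), 0-based at pixel centers, as recorded in all outputs.

assert_rgb <- function(img, arg = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L ||
      !is.numeric(img)) {
    stop(sprintf("`%s` must be a numeric [rows, cols, 3] RGB array", arg),
         call. = FALSE)
  }
  invisible(img)
}

assert_channel <- function(img, arg = "image") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(sprintf("`%s` must be a numeric single-channel matrix", arg),
         call. = FALSE)
  }
  invisible(img)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Deterministic child seeds derived from a user seed; kept below 2^31.
derive_seed <- function(seed, k) {
  (as.integer(seed) * 10007L + as.integer(k) * 97L) %% 2000000011L
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# Flatten an RGB array to an n x 3 matrix of pixels and back.
px_mat <- function(img) {
  matrix(img, ncol = 3L)
}

px_arr <- function(mat, dims) {
  array(mat, dim = dims)
}
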