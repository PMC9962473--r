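# ---- Raster conventions -----------------------------------------------------
#
# RGB images   : numeric array h x w x 3, integer-valued samples in [0, 255].
# Gray images  : numeric matrix h x w, integer-valued samples in [0, 255].
# Binary masks : numeric/integer matrix h x w with values in {0, 1}; 1 is
#                foreground (plant or skeleton).
# Row-major reading order, origin at the top-left corner; R indices are 1-based
# but bounding boxes use 0-based half-open [min, max) intervals so that
# (row_max - row_min) is the box height.

#' Validate an RGB image array
#'
#' @param x object to check.
#' @return `x`, invisibly, if it is a valid `h x w x 3` array with samples in
#'   `[0, 255]`; otherwise an error is thrown.
#' @keywords internal
assert_rgb <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop("expected an h x w x 3 RGB array", call. = FALSE)
  if (dim(x)[1] < 1L || dim(x)[2] < 1L)
    stop("image must have positive height and width", call. = FALSE)
  rng <- range(x)
  if (!is.finite(rng[1]) || rng[1] < 0 || rng[2] > 255)
    stop("RGB samples must lie in [0, 255]", call. = FALSE)
  invisible(x)
}

#' @rdname assert_rgb
#' @keywords internal
assert_gray <- function(x) {
  if (!is.matrix(x)) stop("expected an h x w grayscale matrix", call. = FALSE)
  rng <- range(x)
  if (!is.finite(rng[1]) || rng[1] < 0 || rng[2] > 255)
    stop("gray samples must lie in [0, 255]", call. = FALSE)
  invisible(x)
}

#' @rdname assert_rgb
#' @keywords internal
assert_mask <- function(x) {
  if (!is.matrix(x)) stop("expected an h x w binary matrix", call. = FALSE)
  if (!all(x == 0 | x == 1)) stop("mask values must be 0 or 1", call. = FALSE)
  invisible(x)
}

#' Read and write PNG images as 0-255 arrays
#'
#' Thin wrappers over [png::readPNG()] / [png::writePNG()] converting between
#' the package's integer `[0, 255]` arrays and png's `[0, 1]` doubles.
#' Grayscale and RGBA files are promoted/truncated to 3 channels on read.
#'
#' @param path file path.
#' @param image an RGB array (see package conventions).
#' @return `read_image_png` returns an `h x w x 3` array; `write_image_png`
#'   returns `path` invisibly.
#' @export
read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (is.matrix(a)) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]
  if (dim(a)[3] == 2L) a <- array(rep(a[, , 1L], 3L), c(dim(a)[1:2], 3L))
  round(a * 255)
}

#' @rdname read_image_png
#' @export
write_image_png <- function(image, path) {
  assert_rgb(image)
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Run an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that rendering helpers are
#' deterministic without clobbering the caller's RNG stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Clamp numeric values into [0, 255]
#' @keywords internal
clamp255 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}
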