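# Label-preserving geometric augmentation: the original image plus eleven
# transforms, split into a realistic half (compressions, vertical flips and
# their compositions) and a non-realistic half (horizontal flip and
# rotations), all emitting 299 x 299 x 3 images with white padding.

REALISTIC_OPS <- c("identity", "compress_v", "compress_h", "flip_v",
                   "flip_v_compress_v", "flip_v_compress_h")
NONREALISTIC_OPS <- c("flip_h", "rot180", "rot90cw", "rot90cw_flip_v",
                      "rot90ccw", "rot90ccw_flip_v")

#' The twelve-member augmentation family
#'
#' @param set `"realistic6"` (original + five transforms that keep a
#'   plausible plant orientation), `"all12"`, or `"nonrealistic6"`.
#' @return a character vector of operation names accepted by
#'   [apply_transform()].
#' @export
augmentation_ops <- function(set = c("all12", "realistic6", "nonrealistic6")) {
  set <- match.arg(set)
  switch(set,
         all12 = c(REALISTIC_OPS, NONREALISTIC_OPS),
         realistic6 = REALISTIC_OPS,
         nonrealistic6 = NONREALISTIC_OPS)
}

flip_v <- function(img) img[nrow(img):1, , , drop = FALSE]
flip_h <- function(img) img[, ncol(img):1, , drop = FALSE]

rot90cw_ <- function(img) {
  # clockwise: out[r, c] = in[h - c + 1, r]
  aperm(img[nrow(img):1, , , drop = FALSE], c(2, 1, 3))
}
rot90ccw_ <- function(img) {
  # counterclockwise: out[r, c] = in[c, w - r + 1]
  aperm(img[, ncol(img):1, , drop = FALSE], c(2, 1, 3))
}

# scale one axis by `factor` (bilinear) and center on a white canvas of the
# original size
compress_axis <- function(img, factor, axis) {
  h <- nrow(img); w <- ncol(img)
  oh <- if (axis == "v") max(1L, floor(h * factor)) else h
  ow <- if (axis == "h") max(1L, floor(w * factor)) else w
  small <- resize_bilinear_rgb(img, oh, ow)
  canvas <- array(255, c(h, w, 3))
  r0 <- floor((h - oh) / 2); c0 <- floor((w - ow) / 2)
  canvas[(r0 + 1):(r0 + oh), (c0 + 1):(c0 + ow), ] <- round(small)
  canvas
}

#' Apply one augmentation transform
#'
#' Flips and rotations are exact pixel permutations; compressions scale one
#' axis by `compress_factor` about the image center and pad with white back
#' to the input size. Composite names apply left to right (e.g.
#' `"rot90cw_flip_v"` rotates, then flips vertically; `"flip_v_compress_h"`
#' flips vertically, then compresses horizontally). The leaf-count label is
#' unchanged by contract.
#'
#' @param image a square RGB array (conventionally `299 x 299 x 3`).
#' @param op an operation name from [augmentation_ops()].
#' @param compress_factor axis scale factor in `(0, 1]` for the compression
#'   ops.
#' @return an RGB array of the same shape.
#' @export
apply_transform <- function(image, op, compress_factor = 0.5) {
  assert_rgb(image)
  if (compress_factor <= 0 || compress_factor > 1)
    stop("compress_factor must lie in (0, 1]", call. = FALSE)
  switch(op,
    identity          = image,
    compress_v        = compress_axis(image, compress_factor, "v"),
    compress_h        = compress_axis(image, compress_factor, "h"),
    flip_v            = flip_v(image),
    flip_v_compress_v = compress_axis(flip_v(image), compress_factor, "v"),
    flip_v_compress_h = compress_axis(flip_v(image), compress_factor, "h"),
    flip_h            = flip_h(image),
    rot180            = flip_h(flip_v(image)),
    rot90cw           = rot90cw_(image),
    rot90cw_flip_v    = flip_v(rot90cw_(image)),
    rot90ccw          = rot90ccw_(image),
    rot90ccw_flip_v   = flip_v(rot90ccw_(image)),
    stop("unknown augmentation op '", op, "'", call. = FALSE)
  )
}

#' Expand the training split of a manifest over an augmentation set
#'
#' Each training row is replaced by one row per operation (identical
#' leaf-count label); validation and test rows pass through untouched, so
#' an 800-row training split becomes 4800 rows under the realistic 6-op set
#' and 9600 under the full 12-op set.
#'
#' @param manifest a dataset manifest.
#' @param ops character vector of operation names; must include
#'   `"identity"` (otherwise the originals would be dropped).
#' @return the expanded manifest; augmented rows carry the op name in the
#'   `augmentation` column and derived `image_id`s.
#' @export
expand_training_set <- function(manifest, ops = augmentation_ops("realistic6")) {
  validate_manifest(manifest)
  if (!length(ops) || !"identity" %in% ops)
    stop("ops must be non-empty and include 'identity'", call. = FALSE)
  if (!"augmentation" %in% names(manifest)) manifest$augmentation <- "identity"
  train <- manifest[manifest$split == "train", , drop = FALSE]
  rest <- manifest[manifest$split != "train", , drop = FALSE]
  if (!nrow(train)) return(manifest)
  out <- do.call(rbind, lapply(ops, function(op) {
    r <- train
    r$augmentation <- op
    if (op != "identity") {
      r$image_id <- paste0(r$image_id, "_", op)
      r$path <- file.path(dirname(r$path),
                          paste0(sub("\\.png$", "", basename(r$path)),
                                 "_", op, ".png"))
    }
    r
  }))
  res <- rbind(out, rest)
  rownames(res) <- NULL
  res
}

#' Materialize augmented training images on disk
#'
#' Applies [expand_training_set()] and writes every non-identity training
#' image to its manifest path, so dataset counts are auditable on disk.
#'
#' @param manifest a manifest whose identity-image paths exist on disk.
#' @param ops operation names (must include `"identity"`).
#' @param compress_factor passed to [apply_transform()].
#' @param out_dir optional directory for augmented images; defaults to each
#'   source image's directory.
#' @return the expanded manifest.
#' @export
augment_dataset <- function(manifest, ops = augmentation_ops("realistic6"),
                            compress_factor = 0.5, out_dir = NULL) {
  expanded <- expand_training_set(manifest, ops)
  train_src <- manifest[manifest$split == "train", , drop = FALSE]
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (op in setdiff(ops, "identity")) {
    sel <- which(expanded$augmentation == op)
    # expansion preserves the training-row order within each op block
    for (i in seq_along(sel)) {
      img <- read_image_png(train_src$path[i])
      outp <- expanded$path[sel[i]]
      if (!is.null(out_dir)) {
        outp <- file.path(out_dir, basename(outp))
        expanded$path[sel[i]] <- outp
      }
      write_image_png(apply_transform(img, op, compress_factor), outp)
    }
  }
  expanded
}
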