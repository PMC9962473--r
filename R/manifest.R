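# Dataset manifest I/O and validation.
#
# A manifest is a data.frame with columns
#   image_id, path, leaf_count, split, species, view_angle_deg, occluded,
#   augmentation
# binding each image to its integer leaf-count label and its train/val/test
# split. `augmentation` is "identity" for source images and the transform
# name for materialized augmented copies; non-identity rows may only occur in
# the training split.

MANIFEST_COLUMNS <- c("image_id", "path", "leaf_count", "split", "species",
                      "view_angle_deg", "occluded", "augmentation")

#' Validate a dataset manifest
#'
#' Checks the column set, integer leaf counts (>= 1), known split values and
#' that non-identity augmentations occur only in the training split. Errors
#' name the offending row and field.
#'
#' @param manifest a data.frame.
#' @return the manifest, invisibly.
#' @export
validate_manifest <- function(manifest) {
  missing <- setdiff(setdiff(MANIFEST_COLUMNS, "augmentation"), names(manifest))
  if (length(missing))
    stop("manifest is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!"augmentation" %in% names(manifest)) manifest$augmentation <- "identity"
  lc <- suppressWarnings(as.numeric(manifest$leaf_count))
  bad <- which(!is.finite(lc) | lc != round(lc) | lc < 1)
  if (length(bad))
    stop("manifest row ", bad[1], ": leaf_count '",
         manifest$leaf_count[bad[1]], "' is not a positive integer",
         call. = FALSE)
  bad <- which(!manifest$split %in% c("train", "val", "test"))
  if (length(bad))
    stop("manifest row ", bad[1], ": unknown split '",
         manifest$split[bad[1]], "'", call. = FALSE)
  occ <- manifest$occluded
  if (!is.logical(occ) && !all(occ %in% c("TRUE", "FALSE", "true", "false", 0, 1)))
    stop("manifest column 'occluded' must be logical", call. = FALSE)
  bad <- which(manifest$augmentation != "identity" & manifest$split != "train")
  if (length(bad))
    stop("manifest row ", bad[1],
         ": augmented rows are only allowed in the training split",
         call. = FALSE)
  invisible(manifest)
}

#' Read or write a dataset manifest CSV
#'
#' @param path CSV path with the documented header.
#' @param manifest a manifest data.frame.
#' @return `read_manifest` returns a validated data.frame;
#'   `write_manifest` returns `path` invisibly. The pair round-trips.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"augmentation" %in% names(m)) m$augmentation <- "identity"
  validate_manifest(m)
  m$leaf_count <- as.integer(m$leaf_count)
  m$occluded <- as.logical(m$occluded)
  m
}

#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
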