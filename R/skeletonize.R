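# Skeleton-structure derivation from cropped plant images: Otsu binarization,
# iterative thinning to a one-pixel-wide topology-preserving skeleton, a first
# dilation to reconnect broken leaf segments, removal of components smaller
# than 50 px, and a second dilation to strengthen the structure.

#' Binarize a cropped plant image
#'
#' Grayscale conversion followed by Otsu binarization. Cropped plants sit
#' dark on a light background, so the default polarity is `"dark"`.
#'
#' Pure-white pixels (level 255) are excluded from threshold estimation by
#' default: the aspect-preserving crop pads with white, and that artificial
#' third mode would otherwise dominate the two-class split. The threshold is
#' then applied to the full image (padding lands in the background class).
#' If exclusion leaves fewer than two gray levels — e.g. a black plant on a
#' literally white background — the full histogram is used instead.
#'
#' @param cropped an RGB array (typically `299 x 299 x 3`).
#' @param polarity foreground polarity for [otsu_binarize()].
#' @param exclude_white drop level-255 pixels from threshold estimation.
#' @return a 0/1 plant mask.
#' @export
binarize_plant <- function(cropped, polarity = "dark", exclude_white = TRUE) {
  g <- to_gray(cropped)
  est <- g
  if (exclude_white && length(unique(g[g < 255])) >= 2L)
    est <- matrix(g[g < 255], ncol = 1L)
  thr <- otsu_binarize(est, polarity)$threshold
  mask <- if (polarity == "bright") (g > thr) else (g <= thr)
  mask * 1
}

# shift a matrix by (dr, dc), padding with 0
shift0 <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Thin a binary mask to a one-pixel-wide skeleton
#'
#' Zhang-Suen iterative thinning: alternating sub-iterations delete border
#' pixels whose 8-neighborhood satisfies the connectivity-preserving
#' conditions, until no pixel changes. Anti-extensive (output is a subset of
#' the input) and idempotent on already-thin input.
#'
#' @param mask a 0/1 matrix.
#' @return a 0/1 matrix containing the skeleton.
#' @export
thin <- function(mask) {
  assert_mask(mask)
  m <- mask * 1
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      # neighbors clockwise from north: P2..P9
      p2 <- shift0(m, -1,  0); p3 <- shift0(m, -1,  1)
      p4 <- shift0(m,  0,  1); p5 <- shift0(m,  1,  1)
      p6 <- shift0(m,  1,  0); p7 <- shift0(m,  1, -1)
      p8 <- shift0(m,  0, -1); p9 <- shift0(m, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
           (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      cond <- m == 1 & b >= 2 & b <= 6 & a == 1
      if (phase == 1)
        cond <- cond & (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      else
        cond <- cond & (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      if (any(cond)) { m[cond] <- 0; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

#' Dilate a binary mask with a square structuring element
#'
#' Morphological dilation with a `(2 * radius + 1)` square element
#' (Minkowski sum); extensive (output contains the input). Used first to
#' reconnect discontinuous leaf segments of the thinned skeleton and again
#' after denoising to strengthen the final structure.
#'
#' @param mask a 0/1 matrix.
#' @param radius structuring-element radius in pixels (>= 1).
#' @return the dilated 0/1 matrix.
#' @export
dilate_mask <- function(mask, radius = 1L) {
  assert_mask(mask)
  if (radius < 1L) stop("radius must be >= 1", call. = FALSE)
  img <- EBImage::Image(t(mask))
  kern <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "box")
  t(as.array(EBImage::dilate(img, kern))) * 1
}

#' Remove small connected components
#'
#' Components with area strictly below `min_area` are treated as noise and
#' set to background; all others are kept verbatim. The conventional
#' threshold is 50 pixels.
#'
#' @param mask a 0/1 matrix.
#' @param min_area smallest area (in pixels) that survives.
#' @param connectivity component connectivity (default 8).
#' @return the filtered 0/1 matrix.
#' @export
remove_small_components <- function(mask, min_area = 50L, connectivity = 8) {
  assert_mask(mask)
  if (min_area < 0L) stop("min_area must be >= 0", call. = FALSE)
  if (min_area == 0L) return(mask * 1)
  comp <- connected_components(mask, connectivity)
  if (comp$n == 0L) return(mask * 1)
  drop <- comp$table$label[comp$table$area_px < min_area]
  out <- mask * 1
  out[comp$label_map %in% drop] <- 0
  out
}

#' Derive the skeleton-structure image of a cropped plant
#'
#' Composition [binarize_plant()] -> [thin()] -> [dilate_mask()] ->
#' [remove_small_components()] -> [dilate_mask()]. The final binary image is
#' the skeleton-structure representation fed to the regression model.
#'
#' @param cropped an RGB array (a preprocessed plant crop).
#' @param min_area small-component threshold in pixels (default 50).
#' @param dilate_radius structuring-element radius for both dilation stages.
#' @param polarity foreground polarity of the plant in the crop.
#' @param detail if `TRUE`, return all intermediate stages.
#' @return the final 0/1 skeleton mask; with `detail = TRUE`, a list with
#'   `binary`, `thinned`, `dilated1`, `denoised` and `skeleton`.
#' @export
skeleton_pipeline <- function(cropped, min_area = 50L, dilate_radius = 1L,
                              polarity = "dark", detail = FALSE) {
  binary <- binarize_plant(cropped, polarity)
  thinned <- thin(binary)
  dil1 <- dilate_mask(thinned, dilate_radius)
  den <- remove_small_components(dil1, min_area)
  skel <- dilate_mask(den, dilate_radius)
  if (!detail) return(skel)
  list(binary = binary, thinned = thinned, dilated1 = dil1,
       denoised = den, skeleton = skel)
}

#' Render a skeleton mask as a black-on-white RGB image
#'
#' Skeleton pixels are black on a white background, the form in which
#' skeleton-structure images are fed to the regression model (and the reason
#' the occlusion sliding window for skeleton datasets is black).
#'
#' @param mask a 0/1 skeleton mask.
#' @return an `h x w x 3` RGB array with values 0 (skeleton) and 255.
#' @export
skeleton_to_rgb <- function(mask) {
  assert_mask(mask)
  v <- (1 - mask) * 255
  array(rep(v, 3L), c(dim(mask), 3L))
}
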