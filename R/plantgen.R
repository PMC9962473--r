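# Procedural generator of monocot-style plant images with known leaf counts.
#
# The greenhouse scene is emulated as a light, textured equipment background
# (fixed layout across a whole dataset, per-image illumination jitter and
# sensor noise), a dark pot that belongs to the *background* scene, and a
# plant consisting of a vertical stem plus N elongated, curved leaf strokes
# attached alternately along the stem. The plant is darker than the local
# background so that background differencing and Otsu separate it cleanly.

#' Specification of a synthetic monocot plant image
#'
#' Collects every generative parameter of the synthetic scene. Identical
#' specs (including `seed`) render bit-identical images.
#'
#' @param leaf_count integer number of leaves (>= 1).
#' @param stem_height_frac stem height as a fraction of image height, in (0, 1].
#' @param leaf_length_range numeric length-2 vector, leaf length range in
#'   pixels (each leaf draws its length uniformly from this range).
#' @param leaf_width_px stroke width at the leaf base in pixels; leaves taper
#'   to ~2 px at the tip.
#' @param curvature dimensionless droop parameter of the leaf Bezier curve.
#' @param occlusion logical; if `TRUE`, at least two leaf strokes intersect.
#' @param illumination_jitter per-image brightness offset is drawn uniformly
#'   from `[-illumination_jitter, illumination_jitter]` gray levels.
#' @param noise_blob_count number of small dark distractor blobs (grass/soil
#'   analogues) composited away from the plant.
#' @param canvas_size integer length-2 `(height, width)` in pixels.
#' @param seed integer RNG seed.
#' @return an object of class `"plant_spec"` (a named list).
#' @export
#' @examples
#' sp <- plant_spec(leaf_count = 4, seed = 1)
#' pl <- render_plant(sp)
#' pl$leaf_count
plant_spec <- function(leaf_count = 4L,
                       stem_height_frac = 0.55,
                       leaf_length_range = NULL,
                       leaf_width_px = 6L,
                       curvature = 0.35,
                       occlusion = FALSE,
                       illumination_jitter = 8,
                       noise_blob_count = 3L,
                       canvas_size = c(512L, 512L),
                       seed = 1L) {
  if (length(leaf_count) != 1L || leaf_count < 1L)
    stop("leaf_count must be a single integer >= 1", call. = FALSE)
  if (any(canvas_size < 1L))
    stop("canvas dimensions must be positive", call. = FALSE)
  if (stem_height_frac <= 0 || stem_height_frac > 1)
    stop("stem_height_frac must lie in (0, 1]", call. = FALSE)
  if (is.null(leaf_length_range))
    leaf_length_range <- round(c(0.30, 0.42) * canvas_size[1])
  if (length(leaf_length_range) != 2L || diff(leaf_length_range) < 0)
    stop("leaf_length_range must be an increasing length-2 range", call. = FALSE)
  structure(list(
    leaf_count = as.integer(leaf_count),
    stem_height_frac = stem_height_frac,
    leaf_length_range = leaf_length_range,
    leaf_width_px = leaf_width_px,
    curvature = curvature,
    occlusion = isTRUE(occlusion),
    illumination_jitter = illumination_jitter,
    noise_blob_count = as.integer(noise_blob_count),
    canvas_size = as.integer(canvas_size),
    seed = as.integer(seed)
  ), class = "plant_spec")
}

#' @export
print.plant_spec <- function(x, ...) {
  cat("Synthetic plant spec:", x$leaf_count, "leaves,",
      paste(x$canvas_size, collapse = "x"), "canvas,",
      if (x$occlusion) "occluded," else "separated,",
      "seed", x$seed, "\n")
  invisible(x)
}

# Fixed equipment layout shared by every image of a scene: a vertical
# illumination gradient, two horizontal rails, a vertical post and the pot.
# Only the layout is fixed; jitter and sensor noise vary with the seed.
scene_layout <- function(h, w) {
  base <- matrix(170, h, w)
  base <- base + outer(seq(-12, 12, length.out = h), rep(1, w))  # vertical gradient
  # horizontal rails
  rail1 <- round(h * c(0.18, 0.21)); rail2 <- round(h * c(0.62, 0.645))
  base[rail1[1]:rail1[2], ] <- 146
  base[rail2[1]:rail2[2], ] <- 151
  # vertical post at the right edge
  post <- round(w * c(0.88, 0.915))
  base[, post[1]:post[2]] <- 142
  rgb <- array(0, c(h, w, 3))
  rgb[, , 1] <- base * 0.98
  rgb[, , 2] <- base
  rgb[, , 3] <- base * 0.95
  # pot: dark trapezoid-ish block near the bottom, part of the static scene
  pr <- round(h * c(0.86, 0.97)); pc <- round(w * c(0.39, 0.61))
  rgb[pr[1]:pr[2], pc[1]:pc[2], 1] <- 62
  rgb[pr[1]:pr[2], pc[1]:pc[2], 2] <- 50
  rgb[pr[1]:pr[2], pc[1]:pc[2], 3] <- 46
  rgb
}

#' Render a plant-free background image
#'
#' The equipment layout (rails, post, pot, illumination gradient) is a fixed
#' function of the canvas size, so averaging many backgrounds reproduces the
#' scene; the per-image illumination offset and low-amplitude sensor noise
#' are drawn from the spec's seed.
#'
#' @param spec a [plant_spec()].
#' @return an RGB array of size `canvas_size x 3`.
#' @export
render_background <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  h <- spec$canvas_size[1]; w <- spec$canvas_size[2]
  if (h < 1 || w < 1) stop("non-positive canvas dimensions", call. = FALSE)
  with_seed(spec$seed, {
    img <- scene_layout(h, w)
    jit <- if (spec$illumination_jitter > 0)
      stats::runif(1, -spec$illumination_jitter, spec$illumination_jitter) else 0
    noise <- matrix(stats::rnorm(h * w, 0, 2), h, w)
    for (k in 1:3) img[, , k] <- img[, , k] + jit + noise
    round(clamp255(img))
  })
}

# Stamp a tapering stroke along sampled curve points into a 0/1 mask.
# pts: n x 2 (row, col) doubles; widths: per-point stroke width in px.
stamp_stroke <- function(mask, pts, widths) {
  h <- nrow(mask); w <- ncol(mask)
  for (i in seq_len(nrow(pts))) {
    r <- pts[i, 1]; c <- pts[i, 2]; rad <- widths[i] / 2
    r0 <- max(1L, floor(r - rad)); r1 <- min(h, ceiling(r + rad))
    c0 <- max(1L, floor(c - rad)); c1 <- min(w, ceiling(c + rad))
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    d2 <- outer((rr - r)^2, (cc - c)^2, "+")
    mask[rr, cc][d2 <= rad^2] <- 1
  }
  mask
}

# Quadratic Bezier sample points between p0, p1 (control), p2.
bezier_pts <- function(p0, p1, p2, n = 240L) {
  t <- seq(0, 1, length.out = n)
  cbind((1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1],
        (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2])
}

# Draw one leaf as a tapering quadratic Bezier stroke; returns its mask and
# tip coordinates. Geometry is clipped to the canvas by shrinking the length.
draw_leaf <- function(h, w, attach, side, len, width_px, curvature, steep = 1) {
  repeat {
    dx <- side * len * 0.92
    dy_up <- -len * 0.38
    p1 <- c(attach[1] + dy_up, attach[2] + side * len * 0.45)
    droop <- curvature * len * steep
    p2 <- c(attach[1] - len * 0.15 + droop, attach[2] + dx)
    inside <- function(p) p[1] >= 3 && p[1] <= h - 2 && p[2] >= 3 && p[2] <= w - 2
    if (inside(p2) || len < 20) break
    len <- len * 0.85
  }
  if (len < 20 && !(p2[1] >= 3 && p2[1] <= h - 2 && p2[2] >= 3 && p2[2] <= w - 2))
    stop("leaf geometry leaves the canvas entirely", call. = FALSE)
  pts <- bezier_pts(attach, p1, p2)
  widths <- seq(width_px, 2, length.out = nrow(pts))
  mask <- stamp_stroke(matrix(0, h, w), pts, widths)
  list(mask = mask, tip = p2)
}

#' Render a synthetic plant image with known leaf count
#'
#' Composites a vertical stem and exactly `spec$leaf_count` curved leaf
#' strokes (attached alternately along the stem) over [render_background()],
#' plus small dark distractor blobs. Plant pixels are darker than the local
#' background. With `occlusion = TRUE` two leaves are forced to cross.
#'
#' @param spec a [plant_spec()].
#' @return a list with elements `image` (RGB array), `leaf_count` (ground
#'   truth), `plant_mask` (stem + leaves, 0/1), `stem_mask`, `leaf_masks`
#'   (list of per-leaf 0/1 masks), `tips` (`leaf_count x 2` matrix of
#'   row/col tip coordinates) and `occluded` (logical).
#' @export
render_plant <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  if (spec$leaf_count < 1) stop("leaf_count must be >= 1", call. = FALSE)
  h <- spec$canvas_size[1]; w <- spec$canvas_size[2]
  bg <- render_background(spec)
  with_seed(spec$seed + 7919L, {
    stem_top <- h * 0.87 - spec$stem_height_frac * h
    stem_base <- h * 0.865
    stem_col <- w / 2 + stats::runif(1, -0.02, 0.02) * w
    lean <- stats::runif(1, -0.015, 0.015) * w
    spts <- cbind(seq(stem_base, stem_top, length.out = 200),
                  seq(stem_col, stem_col + lean, length.out = 200))
    stem_mask <- stamp_stroke(matrix(0, h, w),
                              spts, rep(spec$leaf_width_px * 0.8, 200))

    n <- spec$leaf_count
    # attachment heights from just above the base to near the stem tip
    fr <- if (n == 1L) 0.8 else seq(0.30, 0.95, length.out = n)
    leaf_masks <- vector("list", n)
    tips <- matrix(0, n, 2)
    for (i in seq_len(n)) {
      side <- if (i %% 2 == 1) 1 else -1
      attach <- c(stem_base - fr[i] * (stem_base - stem_top),
                  stem_col + lean * fr[i])
      len <- stats::runif(1, spec$leaf_length_range[1], spec$leaf_length_range[2])
      lf <- draw_leaf(h, w, attach, side, len, spec$leaf_width_px,
                      spec$curvature * stats::runif(1, 0.8, 1.2))
      leaf_masks[[i]] <- lf$mask
      tips[i, ] <- lf$tip
    }
    if (spec$occlusion && n >= 2L) {
      # redraw the last leaf on the same side as its lower neighbour, attached
      # slightly above it and drooping harder, until the two strokes cross
      j <- n - 1L; side <- if (j %% 2 == 1) 1 else -1
      steep <- 1.6
      for (try in 1:8) {
        attach <- c(stem_base - min(fr[j] + 0.10, 0.98) * (stem_base - stem_top),
                    stem_col + lean * fr[j])
        len <- stats::runif(1, spec$leaf_length_range[1], spec$leaf_length_range[2])
        lf <- draw_leaf(h, w, attach, side, len, spec$leaf_width_px,
                        spec$curvature, steep = steep)
        if (sum(lf$mask * leaf_masks[[j]]) > 0) break
        steep <- steep + 0.5
      }
      leaf_masks[[n]] <- lf$mask
      tips[n, ] <- lf$tip
    }

    plant_mask <- stem_mask
    for (m in leaf_masks) plant_mask[m == 1] <- 1

    # distractor blobs: small dark clumps kept off the plant
    blob_mask <- matrix(0, h, w)
    if (spec$noise_blob_count > 0) {
      for (b in seq_len(spec$noise_blob_count)) {
        for (try in 1:20) {
          br <- stats::runif(1, 0.05 * h, 0.95 * h)
          bc <- stats::runif(1, 0.05 * w, 0.95 * w)
          rad <- stats::runif(1, 1.5, 3)
          cand <- stamp_stroke(matrix(0, h, w), cbind(br, bc), 2 * rad)
          if (sum(cand * plant_mask) == 0) { blob_mask[cand == 1] <- 1; break }
        }
      }
    }

    img <- bg
    green <- c(52, 78, 40) + stats::runif(3, -6, 6)
    for (k in 1:3) {
      ch <- img[, , k]
      ch[plant_mask == 1] <- green[k] + stats::rnorm(sum(plant_mask), 0, 3)
      ch[blob_mask == 1] <- 70 + stats::rnorm(sum(blob_mask), 0, 4)
      img[, , k] <- ch
    }
    img <- round(clamp255(img))
    list(image = img, leaf_count = spec$leaf_count, plant_mask = plant_mask,
         stem_mask = stem_mask, leaf_masks = leaf_masks, tips = tips,
         blob_mask = blob_mask, occluded = spec$occlusion)
  })
}

#' Generate a synthetic dataset with manifest and background set
#'
#' Writes `n` plant images (PNG), a set of plant-free background images of
#' the same scene, and a manifest CSV binding image paths to integer leaf
#' counts and train/val/test splits. Leaf counts are drawn uniformly from
#' `leaf_range`; exactly `floor(occluded_fraction * n)` images are rendered
#' with forced leaf-leaf occlusion.
#'
#' @param n number of plant images.
#' @param out_dir output directory (created if missing).
#' @param leaf_range integer length-2 `(min, max)` leaf counts.
#' @param occluded_fraction fraction of images with forced occlusion.
#' @param split_fracs length-3 `(train, val, test)` fractions summing to 1.
#' @param n_backgrounds number of plant-free background images (default 50,
#'   the size of the averaged background set).
#' @param canvas_size canvas `(height, width)`.
#' @param seed integer RNG seed; the whole dataset is reproducible from it.
#' @param ... further arguments passed to [plant_spec()].
#' @return a manifest `data.frame` (also written to `out_dir/manifest.csv`)
#'   with attribute `"background_dir"`.
#' @export
make_dataset <- function(n, out_dir,
                         leaf_range = c(2L, 6L),
                         occluded_fraction = 0,
                         split_fracs = c(0.8, 0.1, 0.1),
                         n_backgrounds = 50L,
                         canvas_size = c(512L, 512L),
                         seed = 1L, ...) {
  if (abs(sum(split_fracs) - 1) > 1e-8)
    stop("split_fracs must sum to 1", call. = FALSE)
  if (leaf_range[1] < 1L || leaf_range[2] < leaf_range[1])
    stop("invalid leaf_range", call. = FALSE)
  n_train <- round(n * split_fracs[1]); n_val <- round(n * split_fracs[2])
  n_test <- n - n_train - n_val
  if (n_test < 0) stop("n too small for requested split sizes", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  img_dir <- file.path(out_dir, "images")
  bg_dir <- file.path(out_dir, "backgrounds")
  dir.create(img_dir, showWarnings = FALSE)
  dir.create(bg_dir, showWarnings = FALSE)

  with_seed(seed, {
    counts <- sample(seq(leaf_range[1], leaf_range[2]), n, replace = TRUE)
    n_occ <- floor(occluded_fraction * n)
    occluded <- rep(FALSE, n)
    if (n_occ > 0) occluded[sample.int(n, n_occ)] <- TRUE
    angles <- sample(c(0L, 36L, 72L, 108L, 144L), n, replace = TRUE)
    img_seeds <- sample.int(.Machine$integer.max - 1L, n + n_backgrounds)
    split <- c(rep("train", n_train), rep("val", n_val), rep("test", n_test))
    split <- split[sample.int(n)]

    rows <- vector("list", n)
    for (i in seq_len(n)) {
      sp <- plant_spec(leaf_count = counts[i], occlusion = occluded[i],
                       canvas_size = canvas_size, seed = img_seeds[i], ...)
      pl <- render_plant(sp)
      id <- sprintf("plant_%04d", i)
      path <- file.path(img_dir, paste0(id, ".png"))
      write_image_png(pl$image, path)
      rows[[i]] <- data.frame(image_id = id, path = path,
                              leaf_count = counts[i], split = split[i],
                              species = "synthetic_sorghum",
                              view_angle_deg = angles[i],
                              occluded = occluded[i],
                              stringsAsFactors = FALSE)
    }
    for (b in seq_len(n_backgrounds)) {
      sp <- plant_spec(canvas_size = canvas_size, seed = img_seeds[n + b], ...)
      write_image_png(render_background(sp),
                      file.path(bg_dir, sprintf("bg_%03d.png", b)))
    }
    manifest <- do.call(rbind, rows)
    manifest$augmentation <- "identity"
    write_manifest(manifest, file.path(out_dir, "manifest.csv"))
    attr(manifest, "background_dir") <- bg_dir
    manifest
  })
}
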