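# Model interpretation: background-colored sliding-window occlusion maps
# (prediction change as an opaque window traverses the input) and Grad-CAM
# on the final convolutional feature map, with optional sigmoid emphasis.

new_heatmap <- function(values, kind, meta = list()) {
  structure(list(values = values, kind = kind, meta = meta),
            class = "leafcount_heatmap")
}

#' @export
print.leafcount_heatmap <- function(x, ...) {
  cat(sprintf("%s heatmap, %d x %d cells, range [%.4g, %.4g]\n", x$kind,
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Sliding-window occlusion-sensitivity map
#'
#' Paints an opaque `window x window` box, colored like the image
#' background, at every stride position (stepping its top-left corner by
#' `stride`, with the final positions clipped to the border so the window
#' stays inside), and records the signed difference between the occluded
#' prediction and the ground truth. Positive cells mean the occlusion made
#' the model over-count. The conventional geometry is a 10 x 10 window
#' (about one leaf width) moved by 5; the window is white for models of
#' original plant crops and black for skeleton-image models.
#'
#' @param model a predictor: anything with a [predict()] method mapping an
#'   RGB array to one number (e.g. a `"leaf_cnn"`).
#' @param image an RGB array.
#' @param ground_truth integer leaf count of the image.
#' @param window window side length in pixels (default 10).
#' @param stride step in pixels (default 5).
#' @param window_color length-1 or length-3 color in `[0, 255]` (default
#'   white, for light-background plant crops).
#' @return a `"leafcount_heatmap"` of kind `"occlusion"`; `values` has
#'   `floor((S - window) / stride) + 1` cells per side for image side `S`,
#'   and `meta` records window, stride, baseline prediction and ground
#'   truth.
#' @export
occlusion_heatmap <- function(model, image, ground_truth, window = 10L,
                              stride = 5L, window_color = 255) {
  assert_rgb(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (window > min(h, w)) stop("window exceeds the image", call. = FALSE)
  if (stride < 1L) stop("stride must be >= 1", call. = FALSE)
  if (length(window_color) == 1L) window_color <- rep(window_color, 3L)
  nr <- (h - window) %/% stride + 1L
  nc <- (w - window) %/% stride + 1L
  baseline <- as.numeric(predict(model, image))
  vals <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    r0 <- min((i - 1L) * stride, h - window)
    rows <- (r0 + 1L):(r0 + window)
    for (j in seq_len(nc)) {
      c0 <- min((j - 1L) * stride, w - window)
      occ <- image
      for (k in 1:3) occ[rows, (c0 + 1L):(c0 + window), k] <- window_color[k]
      vals[i, j] <- as.numeric(predict(model, occ)) - ground_truth
    }
  }
  new_heatmap(vals, "occlusion",
              list(window = window, stride = stride,
                   baseline_prediction = baseline,
                   ground_truth = ground_truth,
                   window_color = window_color))
}

#' Grad-CAM localization map for a count regression
#'
#' Channel weights are the spatial average of the gradient of the scalar
#' output with respect to the final convolutional feature map; with a
#' global-average-pooling head followed by a single-unit dense layer, that
#' gradient is exactly the dense weight divided by the number of feature-map
#' positions, so the map is computed in closed form from the exposed
#' feature map and head weights. The weighted channel sum is rectified
#' (negative values zeroed) and min-max normalized to `[0, 1]`; an all-equal
#' map normalizes to all zeros.
#'
#' @param model a `"leaf_cnn"` (or any model with [feature_map()] and
#'   [head_weights()] methods).
#' @param image an RGB array of the model's input size.
#' @return a `"leafcount_heatmap"` of kind `"gradcam"` whose `values` grid
#'   has the extent of the final feature map; `meta` records the feature
#'   extent, input size and baseline prediction.
#' @export
grad_cam <- function(model, image) {
  feat <- feature_map(model, image)
  hw <- head_weights(model)
  npos <- prod(dim(feat)[1:2])
  alpha <- hw$w / npos                 # spatial mean of d(yhat)/d(feat)
  fm <- matrix(feat, ncol = dim(feat)[3])
  cam <- matrix(fm %*% alpha, dim(feat)[1], dim(feat)[2])
  cam[cam < 0] <- 0
  rng <- range(cam)
  vals <- if (rng[2] > rng[1]) (cam - rng[1]) / (rng[2] - rng[1])
  else matrix(0, nrow(cam), ncol(cam))
  pred <- sum(hw$w * colMeans(fm)) + hw$b
  new_heatmap(vals, "gradcam",
              list(feature_extent = dim(feat)[1:2],
                   input_size = dim(image)[1:2],
                   baseline_prediction = pred))
}

#' Sigmoid emphasis of a Grad-CAM map
#'
#' Elementwise logistic `1 / (1 + exp(-steepness * (v - 0.5)))` applied to a
#' normalized Grad-CAM map, sharpening the boundary between contributing
#' and non-contributing regions.
#'
#' @param map a `"leafcount_heatmap"` of kind `"gradcam"`.
#' @param steepness slope of the logistic at 0.5 is `steepness / 4`
#'   (default 10).
#' @return a `"leafcount_heatmap"` of kind `"gradcam_emphasized"` with
#'   values in `(0, 1)`.
#' @export
emphasize <- function(map, steepness = 10) {
  if (!inherits(map, "leafcount_heatmap") || map$kind != "gradcam")
    stop("emphasize expects a gradcam heatmap", call. = FALSE)
  v <- 1 / (1 + exp(-steepness * (map$values - 0.5)))
  meta <- map$meta; meta$steepness <- steepness
  new_heatmap(v, "gradcam_emphasized", meta)
}

# blue-cyan-yellow-red colormap (cool = low, warm = high), n x 3 in [0,255]
heat_colors <- function(n = 256L) {
  ramp <- grDevices::colorRamp(c("#00007F", "blue", "cyan", "yellow",
                                 "red", "#7F0000"))
  ramp(seq(0, 1, length.out = n))
}

#' Upsample a heatmap to pixel resolution
#'
#' Nearest-neighbor upsampling of the cell grid to the given extent; each
#' cell keeps its single window/feature-position value (no inter-cell
#' interpolation).
#'
#' @param map a `"leafcount_heatmap"`.
#' @param height,width output extent in pixels.
#' @return a `height x width` numeric matrix.
#' @export
heatmap_to_pixels <- function(map, height, width) {
  resize_nearest(map$values, height, width)
}

#' Overlay a heatmap on an image
#'
#' Min-max normalizes the map, colorizes it with a cool-to-warm colormap
#' (cooler colors mark smaller values, warmer colors larger ones) and
#' alpha-blends it onto the image.
#'
#' @param map a `"leafcount_heatmap"`.
#' @param image the RGB array the map explains.
#' @param alpha blend weight of the heatmap in `[0, 1]`.
#' @return an RGB array of the image's size; attribute `"value_range"`
#'   records the colorbar range of the raw map values.
#' @export
render_overlay <- function(map, image, alpha = 0.5) {
  assert_rgb(image)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  vals <- heatmap_to_pixels(map, dim(image)[1], dim(image)[2])
  rng <- range(vals)
  norm <- if (rng[2] > rng[1]) (vals - rng[1]) / (rng[2] - rng[1])
  else matrix(0, nrow(vals), ncol(vals))
  pal <- heat_colors(256L)
  idx <- pmin(255L, floor(norm * 255)) + 1L
  out <- image
  for (k in 1:3) {
    layer <- matrix(pal[idx, k], nrow(vals), ncol(vals))
    out[, , k] <- round((1 - alpha) * image[, , k] + alpha * layer)
  }
  attr(out, "value_range") <- rng
  out
}

#' Leaf-feature diagnostics of a trained regressor on a synthetic plant
#'
#' Renders the plant described by `spec`, preprocesses it against the given
#' averaged background, and measures two qualitative properties of the
#' trained model on it:
#' \itemize{
#'   \item Grad-CAM contrast between leaf tips and the bare stem: the mean
#'     upsampled Grad-CAM value over a clamped 21 x 21 neighborhood of each
#'     leaf-tip, versus the mean over the lowest fifth of the stem (the
#'     segment below every leaf attachment, the only stem pixels whose
#'     coarse feature-map cells are not shared with crossing leaves).
#'   \item Disconnection sensitivity: the prediction change when an opaque
#'     `window x window` background-colored box severs the first leaf near
#'     its base, and near its tip.
#' }
#'
#' @param model a trained `"leaf_cnn"`.
#' @param spec a [plant_spec()] describing the reference plant.
#' @param avg_background averaged background of the same scene.
#' @param window side of the severing box in pixels (default 10).
#' @return a list with `tip_mean`, `stem_mean`, `tip_minus_stem`,
#'   `sever_base_delta`, `sever_tip_delta`, `prediction` and
#'   `ground_truth`.
#' @export
leaf_feature_diagnostics <- function(model, spec, avg_background,
                                     window = 10L) {
  plant <- render_plant(spec)
  crop <- preprocess_pipeline(plant$image, avg_background)
  geom <- attr(crop, "geometry")
  size <- dim(crop)[1]
  px <- heatmap_to_pixels(grad_cam(model, crop), size, size)

  tips <- map_to_crop(plant$tips, geom)
  tip_vals <- vapply(seq_len(nrow(tips)), function(i) {
    r <- min(max(round(tips[i, 1]), 1), size)
    c <- min(max(round(tips[i, 2]), 1), size)
    mean(px[max(1, r - 10):min(size, r + 10),
            max(1, c - 10):min(size, c + 10)])
  }, 0)

  sp <- which(plant$stem_mask == 1, arr.ind = TRUE)
  base_r <- max(sp[, 1]); top_r <- min(sp[, 1])
  bare <- sp[sp[, 1] > base_r - 0.22 * (base_r - top_r), , drop = FALSE]
  sc <- round(map_to_crop(bare, geom))
  keep <- sc[, 1] >= 1 & sc[, 1] <= size & sc[, 2] >= 1 & sc[, 2] <= size
  stem_mean <- mean(px[sc[keep, , drop = FALSE]])

  paint <- function(pt) {
    occ <- crop
    r0 <- min(max(round(pt[1]) - window %/% 2, 1), size - window + 1)
    c0 <- min(max(round(pt[2]) - window %/% 2, 1), size - window + 1)
    occ[r0:(r0 + window - 1), c0:(c0 + window - 1), ] <- 255
    occ
  }
  stem_c <- mean(sp[, 2])
  lmp <- which(plant$leaf_masks[[1]] == 1, arr.ind = TRUE)
  basept <- lmp[which.min(abs(lmp[, 2] - stem_c)), ]
  side <- sign(plant$tips[1, 2] - stem_c)
  near_base <- c(basept[1] - 2, basept[2] + side * 9)
  near_tip <- plant$tips[1, ] - c(0, side * 8)
  baseline <- as.numeric(predict(model, crop))
  sever_base <- as.numeric(predict(model,
    paint(map_to_crop(matrix(near_base, 1), geom))))
  sever_tip <- as.numeric(predict(model,
    paint(map_to_crop(matrix(near_tip, 1), geom))))

  list(tip_mean = mean(tip_vals), stem_mean = stem_mean,
       tip_minus_stem = mean(tip_vals) - stem_mean,
       sever_base_delta = sever_base - baseline,
       sever_tip_delta = sever_tip - baseline,
       prediction = baseline, ground_truth = plant$leaf_count)
}
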