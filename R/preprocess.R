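# Plant extraction from raw greenhouse-style images: averaged-background
# differencing, grayscale conversion, Otsu binarization, connected-component
# analysis, largest-component cropping and resizing to the network input
# resolution.

#' Average a set of plant-free background images
#'
#' Per-pixel, per-channel arithmetic mean over the background set, rounded
#' half-up to integers. The conventional set size is 50 randomly selected
#' plant-free images of the scene.
#'
#' @param backgrounds a list of RGB arrays of identical shape.
#' @return an RGB array of the common shape.
#' @export
average_background <- function(backgrounds) {
  if (length(backgrounds) < 1L) stop("need at least one background image",
                                     call. = FALSE)
  d <- dim(backgrounds[[1]])
  acc <- array(0, d)
  for (b in backgrounds) {
    if (!identical(dim(b), d)) stop("background shapes differ", call. = FALSE)
    acc <- acc + b
  }
  floor(acc / length(backgrounds) + 0.5)  # round half-up
}

#' Per-channel absolute difference image
#'
#' @param original,background RGB arrays of identical shape.
#' @return RGB array `|original - background|`.
#' @export
difference_image <- function(original, background) {
  if (!identical(dim(original), dim(background)))
    stop("image shapes differ", call. = FALSE)
  abs(original - background)
}

#' Convert RGB to grayscale (ITU-R 601 luma)
#'
#' Weighted sum `0.299 R + 0.587 G + 0.114 B`, rounded to integers.
#'
#' @param image an RGB array.
#' @return an `h x w` grayscale matrix in `[0, 255]`.
#' @export
to_gray <- function(image) {
  assert_rgb(image)
  round(0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3])
}

#' Otsu binarization
#'
#' Selects the threshold `T` in `0..254` that maximizes the between-class
#' variance of the two classes `{<= T}` and `{> T}` of the 256-level
#' histogram (ties broken toward the smallest `T`). Foreground is the class
#' above the threshold for `polarity = "bright"`, at-or-below for `"dark"`.
#'
#' @param image a grayscale matrix with at least two distinct levels.
#' @param polarity which side of the threshold is foreground.
#' @return a list with `mask` (0/1 matrix) and `threshold` (integer).
#' @export
otsu_binarize <- function(image, polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  assert_gray(image)
  g <- as.integer(round(image))
  if (length(unique(g)) < 2L)
    stop("constant image: no threshold separates two classes", call. = FALSE)
  p <- tabulate(g + 1L, nbins = 256L) / length(g)
  omega <- cumsum(p)                    # P(class <= T), T = 0..255
  mu <- cumsum(p * (0:255))             # first moment up to T
  mu_t <- mu[256]
  w0 <- omega[1:255]; w1 <- 1 - w0      # candidates T = 0..254
  sigma_b <- (mu_t * w0 - mu[1:255])^2 / (w0 * w1)
  sigma_b[!is.finite(sigma_b)] <- -Inf  # empty classes cannot win
  thr <- which.max(sigma_b) - 1L        # smallest argmax
  mask <- if (polarity == "bright") (image > thr) else (image <= thr)
  list(mask = mask * 1, threshold = thr)
}

#' Connected-component labeling of a binary mask
#'
#' Labels foreground components under 4- or 8-neighborhood adjacency (built
#' on the pixel-adjacency graph). Labels are contiguous from 1, ordered by
#' each component's first pixel in column-major scan order.
#'
#' @param mask a 0/1 matrix.
#' @param connectivity 4 or 8.
#' @return a list with `label_map` (integer matrix, 0 = background),
#'   `n` (component count) and `table` (data.frame with `label`, `area_px`,
#'   and 0-based half-open bbox columns `row_min`, `col_min`, `row_max`,
#'   `col_max`).
#' @export
connected_components <- function(mask, connectivity = 8) {
  assert_mask(mask)
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8",
                                       call. = FALSE)
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask == 1)                 # column-major linear indices
  label_map <- matrix(0L, h, w)
  empty <- data.frame(label = integer(), area_px = integer(),
                      row_min = integer(), col_min = integer(),
                      row_max = integer(), col_max = integer())
  if (!length(fg))
    return(list(label_map = label_map, n = 0L, table = empty))
  id <- matrix(0L, h, w); id[fg] <- seq_along(fg)
  rows <- ((fg - 1L) %% h) + 1L
  cols <- ((fg - 1L) %/% h) + 1L
  offsets <- list(c(1L, 0L), c(0L, 1L))                 # down, right
  if (connectivity == 8) offsets <- c(offsets, list(c(1L, 1L), c(-1L, 1L)))
  edges <- integer(0)
  for (off in offsets) {
    r2 <- rows + off[1]; c2 <- cols + off[2]
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    nb <- id[cbind(r2[ok], c2[ok])]
    keep <- nb > 0L
    if (any(keep))
      edges <- c(edges, rbind(id[fg][ok][keep], nb[keep]))
  }
  gph <- igraph::make_graph(edges = edges, n = length(fg), directed = FALSE)
  memb <- igraph::components(gph)$membership
  # relabel by first occurrence in scan order (fg is already sorted)
  relab <- integer(max(memb)); nxt <- 0L
  for (m in memb) if (relab[m] == 0L) { nxt <- nxt + 1L; relab[m] <- nxt }
  lab <- relab[memb]
  label_map[fg] <- lab
  area <- tabulate(lab, nbins = nxt)
  tab <- data.frame(
    label = seq_len(nxt),
    area_px = area,
    row_min = as.integer(tapply(rows, lab, min)) - 1L,
    col_min = as.integer(tapply(cols, lab, min)) - 1L,
    row_max = as.integer(tapply(rows, lab, max)),
    col_max = as.integer(tapply(cols, lab, max))
  )
  list(label_map = label_map, n = nxt, table = tab)
}

#' Bounding box of the largest connected component
#'
#' @param components result of [connected_components()].
#' @return a length-4 integer vector `c(row_min, col_min, row_max, col_max)`,
#'   0-based half-open. Ties in area are broken by the smallest label.
#' @export
largest_component_bbox <- function(components) {
  tab <- components$table
  if (!nrow(tab)) stop("no components", call. = FALSE)
  i <- which.max(tab$area_px)            # first max = smallest label
  c(row_min = tab$row_min[i], col_min = tab$col_min[i],
    row_max = tab$row_max[i], col_max = tab$col_max[i])
}

# Nearest-neighbor resize of a matrix/array plane with floor(center) index
# mapping: output pixel i samples input pixel floor((i - 0.5) * in / out) + 1.
resize_nearest <- function(plane, oh, ow) {
  ih <- nrow(plane); iw <- ncol(plane)
  ri <- pmin(ih, floor((seq_len(oh) - 0.5) * ih / oh) + 1L)
  ci <- pmin(iw, floor((seq_len(ow) - 0.5) * iw / ow) + 1L)
  plane[ri, ci, drop = FALSE]
}

# Bilinear RGB resize via EBImage (which stores images width x height, hence
# the transposes).
resize_bilinear_rgb <- function(image, oh, ow) {
  img <- EBImage::Image(aperm(image / 255, c(2, 1, 3)), colormode = "Color")
  out <- EBImage::resize(img, w = ow, h = oh, filter = "bilinear")
  clamp255(aperm(as.array(out), c(2, 1, 3)) * 255)
}

#' Crop to a bounding box and resize to the network input size
#'
#' Crops `image` to the 0-based half-open box, rescales so that the longer
#' side equals `out_size` (aspect ratio preserved) and pads the shorter side
#' symmetrically with white to `out_size x out_size x 3`.
#'
#' @param image an RGB array.
#' @param box length-4 `c(row_min, col_min, row_max, col_max)`, 0-based
#'   half-open, within the image.
#' @param out_size output side length (default 299, the network input).
#' @param method `"bilinear"` (RGB content) or `"nearest"` (masks, exact
#'   index mapping).
#' @param pad_value padding sample value; white (255) for plant crops, 0 for
#'   ground-truth masks.
#' @return an `out_size x out_size x 3` RGB array.
#' @export
crop_resize <- function(image, box, out_size = 299L,
                        method = c("bilinear", "nearest"), pad_value = 255) {
  method <- match.arg(method)
  assert_rgb(image)
  box <- as.integer(box)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (box[1] < 0 || box[2] < 0 || box[3] > h || box[4] > w ||
      box[3] <= box[1] || box[4] <= box[2])
    stop("degenerate or out-of-bounds box", call. = FALSE)
  crop <- image[(box[1] + 1L):box[3], (box[2] + 1L):box[4], , drop = FALSE]
  ch <- dim(crop)[1]; cw <- dim(crop)[2]
  s <- out_size / max(ch, cw)
  oh <- max(1L, round(ch * s)); ow <- max(1L, round(cw * s))
  resized <- if (method == "bilinear") resize_bilinear_rgb(crop, oh, ow)
  else {
    out <- array(0, c(oh, ow, 3))
    for (k in 1:3) out[, , k] <- resize_nearest(crop[, , k], oh, ow)
    out
  }
  canvas <- array(pad_value, c(out_size, out_size, 3))
  r0 <- floor((out_size - oh) / 2); c0 <- floor((out_size - ow) / 2)
  canvas[(r0 + 1):(r0 + oh), (c0 + 1):(c0 + ow), ] <- round(resized)
  canvas
}

#' Full plant-extraction pipeline
#'
#' Composition of [difference_image()], [to_gray()], [otsu_binarize()]
#' (bright polarity: plant pixels differ most from the background),
#' [connected_components()], [largest_component_bbox()] and [crop_resize()].
#'
#' @param original an RGB plant image.
#' @param avg_background the averaged background of the same scene.
#' @param out_size output side length (default 299).
#' @param connectivity component connectivity (default 8).
#' @param min_plant_area smallest plausible plant component in pixels; if the
#'   largest component is below it, no plant was found and an error is
#'   raised.
#' @param min_contrast smallest mean gray-level difference (over the largest
#'   component) that counts as a plant; below it the input is treated as
#'   plant-free and an error is raised.
#' @param detail if `TRUE`, return all intermediate artifacts.
#' @return the `out_size x out_size x 3` cropped plant image, with the crop
#'   box and scale stored in attribute `"geometry"`; with `detail = TRUE`, a
#'   list with elements `output`, `difference`, `gray`, `mask`, `threshold`,
#'   `components` and `box`.
#' @export
preprocess_pipeline <- function(original, avg_background, out_size = 299L,
                                connectivity = 8, min_plant_area = 200L,
                                min_contrast = 40, detail = FALSE) {
  diff <- difference_image(original, avg_background)
  gray <- to_gray(diff)
  ob <- otsu_binarize(gray, "bright")
  comp <- connected_components(ob$mask, connectivity)
  if (comp$n == 0L) stop("no plant component found", call. = FALSE)
  box <- largest_component_bbox(comp)
  big <- which.max(comp$table$area_px)
  if (comp$table$area_px[big] < min_plant_area)
    stop("no plant component found (largest component below min_plant_area)",
         call. = FALSE)
  if (mean(gray[comp$label_map == big]) < min_contrast)
    stop("no plant component found (difference contrast below min_contrast)",
         call. = FALSE)
  out <- crop_resize(original, box, out_size)
  ch <- box[3] - box[1]; cw <- box[4] - box[2]
  s <- out_size / max(ch, cw)
  geom <- list(box = box, scale = s,
               offset = c(floor((out_size - round(ch * s)) / 2),
                          floor((out_size - round(cw * s)) / 2)))
  attr(out, "geometry") <- geom
  if (!detail) return(out)
  list(output = out, difference = diff, gray = gray, mask = ob$mask,
       threshold = ob$threshold, components = comp, box = box,
       geometry = geom)
}

#' Map canvas coordinates into the preprocessed crop
#'
#' Transforms `(row, col)` coordinates of the original canvas into the
#' coordinate frame of the image returned by [preprocess_pipeline()], using
#' its `"geometry"` attribute.
#'
#' @param coords an `n x 2` matrix of (row, col) canvas coordinates (1-based).
#' @param geometry the `"geometry"` attribute of a preprocessed image.
#' @return an `n x 2` matrix of crop coordinates (1-based, unclamped).
#' @export
map_to_crop <- function(coords, geometry) {
  cbind((coords[, 1] - geometry$box[1]) * geometry$scale + geometry$offset[1],
        (coords[, 2] - geometry$box[2]) * geometry$scale + geometry$offset[2])
}
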