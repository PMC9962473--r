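# Shared fixtures, built once per test run and memoized. All images are
# generated in code; nothing is read from the repository.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# a small rendered scene: 4-leaf plant on a 256 px canvas, with its averaged
# background and preprocessed 299 px crop
fixture_scene <- function() {
  memo("scene", function() {
    spec <- plant_spec(leaf_count = 4L, canvas_size = c(256L, 256L),
                       seed = 42L)
    plant <- render_plant(spec)
    bgs <- lapply(1:50, function(s)
      render_background(plant_spec(canvas_size = c(256L, 256L),
                                   seed = 9000L + s)))
    avg <- average_background(bgs)
    crop <- preprocess_pipeline(plant$image, avg)
    list(spec = spec, plant = plant, backgrounds = bgs, avg = avg,
         crop = crop)
  })
}

# a tiny on-disk dataset (20 plants, 256 px canvas) with preprocessed crops
fixture_dataset <- function() {
  memo("dataset", function() {
    dir <- file.path(tempdir(), "leafcount-fixture-ds")
    raw <- make_dataset(n = 20L, out_dir = dir, leaf_range = c(2L, 5L),
                        split_fracs = c(0.8, 0.1, 0.1),
                        n_backgrounds = 50L,
                        canvas_size = c(256L, 256L), seed = 77L)
    bgs <- lapply(list.files(attr(raw, "background_dir"), full.names = TRUE),
                  read_image_png)
    avg <- average_background(bgs)
    crop_dir <- file.path(dir, "crops")
    dir.create(crop_dir, showWarnings = FALSE)
    man <- raw
    man$path <- vapply(seq_len(nrow(raw)), function(i) {
      crop <- preprocess_pipeline(read_image_png(raw$path[i]), avg)
      p <- file.path(crop_dir, paste0(raw$image_id[i], ".png"))
      write_image_png(crop, p)
      p
    }, "")
    list(raw = raw, manifest = man, avg = avg, dir = dir)
  })
}

# the desk-scale benchmark (expensive; built once, shared by the end-to-end
# acceptance checks)
fixture_benchmark <- function() {
  memo("benchmark", function() {
    train_synthetic_benchmark(seed = 101L)
  })
}

# a manifest data.frame without any files behind it, for pure bookkeeping
fake_manifest <- function(n_train, n_val, n_test, leaf_counts = NULL) {
  n <- n_train + n_val + n_test
  if (is.null(leaf_counts)) leaf_counts <- rep_len(2:6, n)
  data.frame(
    image_id = sprintf("img_%05d", seq_len(n)),
    path = file.path("imgs", sprintf("img_%05d.png", seq_len(n))),
    leaf_count = as.integer(leaf_counts),
    split = c(rep("train", n_train), rep("val", n_val), rep("test", n_test)),
    species = "synthetic_sorghum",
    view_angle_deg = 0L,
    occluded = FALSE,
    augmentation = "identity",
    stringsAsFactors = FALSE
  )
}

# stub predictor that ignores its input
constant_predictor <- function(value) {
  structure(list(value = value), class = "constant_predictor")
}
predict.constant_predictor <- function(object, newdata, ...) object$value
registerS3method("predict", "constant_predictor", predict.constant_predictor,
                 envir = asNamespace("stats"))
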