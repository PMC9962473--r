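# Desk-scale reference experiment on synthetic plants: a fully seeded
# generate -> preprocess -> train -> evaluate run small enough for a CPU.

#' Desk-scale synthetic leaf-counting benchmark
#'
#' Generates a synthetic dataset with known leaf counts, preprocesses every
#' image against the averaged background set, trains the reduced-backbone
#' count regressor on the training split and evaluates it on the held-out
#' test split. The defaults — 300 training and 50 test plants with 2 to 6
#' clearly separated leaves, 30 epochs — are the package's reference
#' conditions for a CPU-sized experiment; they are a scaled-down surrogate
#' for greenhouse-scale training, not a reproduction of it.
#'
#' @param dir working directory for images and manifests (default a
#'   temporary directory).
#' @param seed integer seed driving dataset generation and training.
#' @param n total number of plants; split 6/7 train, 1/7 test.
#' @param leaf_range inclusive leaf-count range.
#' @param epochs training epochs (default 30).
#' @param learning_rate RMSprop learning rate for this desk-scale run
#'   (default 0.01; see [leaf_cnn_config()]).
#' @param lr_decay per-epoch learning-rate decay (default 0.97).
#' @param occluded_fraction fraction of plants with forced occlusion.
#' @param verbose print a line per epoch.
#' @return a list with `model` (the trained `"leaf_cnn"`), `eval` (a
#'   `"leafcount_eval"` on the test split), `manifest` (crop manifest),
#'   `raw_manifest`, `avg_background` and `dir`.
#' @export
train_synthetic_benchmark <- function(dir = tempfile("leafbench"),
                                      seed = 1L, n = 350L,
                                      leaf_range = c(2L, 6L),
                                      epochs = 30L, learning_rate = 0.01,
                                      lr_decay = 0.97,
                                      occluded_fraction = 0,
                                      verbose = FALSE) {
  raw <- make_dataset(n = n, out_dir = dir, leaf_range = leaf_range,
                      occluded_fraction = occluded_fraction,
                      split_fracs = c(6 / 7, 0, 1 / 7), seed = seed)
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
  model <- build_leaf_cnn(leaf_cnn_config(backbone = "reduced", seed = seed))
  model <- train_leaf_cnn(model, man, epochs = epochs,
                          learning_rate = learning_rate,
                          lr_decay = lr_decay, verbose = verbose)
  te <- man[man$split == "test", , drop = FALSE]
  yhat <- predict(model, te)
  ev <- evaluate_predictions(te$leaf_count, yhat)
  list(model = model, eval = ev, manifest = man, raw_manifest = raw,
       avg_background = avg, dir = dir)
}
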