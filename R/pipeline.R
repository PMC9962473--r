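# End-to-end orchestration: a YAML-configured pipeline gluing synthesis,
# preprocessing, skeletonization, augmentation, training, evaluation and
# explanation, with a run log and a machine-readable summary.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the leaf-counting pipeline from a configuration file
#'
#' Executes the requested stages in order on one dataset directory. The
#' configuration is a YAML file with an `out_dir`, a `stages` list (any of
#' `synth`, `preprocess`, `skeletonize`, `augment`, `train`, `evaluate`,
#' `explain`) and one block per stage. Seeds are mandatory for the `synth`
#' and `train` stages; every stage appends a line with its parameters and
#' input/output record counts to `run.log`, and a machine-readable
#' `run_summary.json` is written at the end.
#'
#' Stage blocks and their keys (defaults in parentheses):
#' \describe{
#'   \item{synth}{`n`, `seed` (required); `leaf_range` (2 6),
#'     `occluded_fraction` (0), `split_fracs` (.8 .1 .1),
#'     `n_backgrounds` (50), `canvas_size` (512 512).}
#'   \item{preprocess}{`out_size` (299).}
#'   \item{skeletonize}{`min_area` (50), `dilate_radius` (1).}
#'   \item{augment}{`set` (realistic6), `factor` (0.5), `input`
#'     (original or skeleton; original).}
#'   \item{train}{`seed` (required); `backbone` (reduced), `epochs` (500),
#'     `learning_rate` (1e-4), `batch_size` (16), `lr_decay` (1), `input`
#'     (original).}
#'   \item{evaluate}{none; predicts the test split and writes
#'     `report.json` with `rmse`, `r2`, `accuracy`, `n`.}
#'   \item{explain}{`method` (gradcam or occlusion; gradcam), `image_id`
#'     (first test row), `window` (10), `stride` (5).}
#' }
#'
#' @param config_file path to the YAML configuration.
#' @return the run summary (named list), invisibly; artifacts are written
#'   under `out_dir`.
#' @export
run_pipeline <- function(config_file) {
  cfg <- yaml::read_yaml(config_file)
  if (is.null(cfg$out_dir)) stop("config is missing 'out_dir'", call. = FALSE)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- cfg$stages %||%
    c("synth", "preprocess", "skeletonize", "augment", "train", "evaluate")
  known <- c("synth", "preprocess", "skeletonize", "augment", "train",
             "evaluate", "explain")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  log_path <- file.path(out_dir, "run.log")
  summary <- list()
  log_line <- function(...) cat(..., "\n", file = log_path, append = TRUE)

  manifest_path <- function(kind)
    file.path(out_dir, paste0("manifest_", kind, ".csv"))
  current_manifest <- function(kind = "crops") {
    p <- manifest_path(kind)
    if (!file.exists(p)) stop("stage input missing: ", p,
                              " (run earlier stages first)", call. = FALSE)
    read_manifest(p)
  }

  for (stage in stages) {
    sc <- cfg[[stage]] %||% list()
    t0 <- Sys.time()
    rec <- switch(stage,
      synth = {
        if (is.null(sc$n)) stop("synth stage requires 'n'", call. = FALSE)
        if (is.null(sc$seed))
          stop("synth stage requires an explicit 'seed'", call. = FALSE)
        man <- make_dataset(
          n = sc$n, out_dir = out_dir,
          leaf_range = unlist(sc$leaf_range %||% c(2, 6)),
          occluded_fraction = sc$occluded_fraction %||% 0,
          split_fracs = unlist(sc$split_fracs %||% c(0.8, 0.1, 0.1)),
          n_backgrounds = sc$n_backgrounds %||% 50L,
          canvas_size = unlist(sc$canvas_size %||% c(512L, 512L)),
          seed = sc$seed)
        file.copy(file.path(out_dir, "manifest.csv"), manifest_path("raw"),
                  overwrite = TRUE)
        list(n_in = sc$n, n_out = nrow(man))
      },
      preprocess = {
        man <- current_manifest("raw")
        bg_dir <- file.path(out_dir, "backgrounds")
        bgs <- lapply(list.files(bg_dir, full.names = TRUE), read_image_png)
        avg <- average_background(bgs)
        crop_dir <- file.path(out_dir, "crops")
        dir.create(crop_dir, showWarnings = FALSE)
        out_size <- sc$out_size %||% 299L
        man$path <- vapply(seq_len(nrow(man)), function(i) {
          crop <- preprocess_pipeline(read_image_png(man$path[i]), avg,
                                      out_size = out_size)
          p <- file.path(crop_dir, paste0(man$image_id[i], ".png"))
          write_image_png(crop, p)
          p
        }, "")
        write_manifest(man, manifest_path("crops"))
        list(n_in = nrow(man), n_out = nrow(man))
      },
      skeletonize = {
        man <- current_manifest("crops")
        sk_dir <- file.path(out_dir, "skeletons")
        dir.create(sk_dir, showWarnings = FALSE)
        man$path <- vapply(seq_len(nrow(man)), function(i) {
          skel <- skeleton_pipeline(read_image_png(man$path[i]),
                                    min_area = sc$min_area %||% 50L,
                                    dilate_radius = sc$dilate_radius %||% 1L)
          p <- file.path(sk_dir, paste0(man$image_id[i], ".png"))
          write_image_png(skeleton_to_rgb(skel), p)
          p
        }, "")
        write_manifest(man, manifest_path("skeletons"))
        list(n_in = nrow(man), n_out = nrow(man))
      },
      augment = {
        kind <- if (identical(sc$input, "skeleton")) "skeletons" else "crops"
        man <- current_manifest(kind)
        ops <- augmentation_ops(sc$set %||% "realistic6")
        man2 <- augment_dataset(man, ops, compress_factor = sc$factor %||% 0.5)
        write_manifest(man2, manifest_path(paste0(kind, "_aug")))
        list(n_in = nrow(man), n_out = nrow(man2))
      },
      train = {
        if (is.null(sc$seed))
          stop("train stage requires an explicit 'seed'", call. = FALSE)
        kind <- if (identical(sc$input, "skeleton")) "skeletons" else "crops"
        aug_p <- manifest_path(paste0(kind, "_aug"))
        man <- if (file.exists(aug_p)) read_manifest(aug_p)
        else current_manifest(kind)
        mcfg <- leaf_cnn_config(
          backbone = sc$backbone %||% "reduced",
          batch_size = sc$batch_size %||% 16L,
          learning_rate = sc$learning_rate %||% 1e-4,
          epochs = sc$epochs %||% 500L,
          seed = sc$seed)
        model <- build_leaf_cnn(mcfg)
        model <- train_leaf_cnn(model, man, lr_decay = sc$lr_decay %||% 1)
        save_leaf_cnn(model, file.path(out_dir, "model.ckpt"))
        utils::write.csv(model$history,
                         file.path(out_dir, "training_history.csv"),
                         row.names = FALSE)
        list(n_in = sum(man$split == "train"),
             n_out = nrow(model$history))
      },
      evaluate = {
        kind <- if (identical(sc$input, "skeleton")) "skeletons" else "crops"
        man <- current_manifest(kind)
        te <- man[man$split == "test", , drop = FALSE]
        model <- load_leaf_cnn(file.path(out_dir, "model.ckpt"))
        yhat <- predict(model, te)
        # R^2 is undefined for a constant test split (degenerate tiny runs)
        r2 <- if (length(unique(te$leaf_count)) > 1L)
          r_squared(te$leaf_count, yhat) else NA
        utils::write.csv(
          data.frame(image_id = te$image_id, leaf_count = te$leaf_count,
                     prediction = yhat),
          file.path(out_dir, "predictions.csv"), row.names = FALSE)
        jsonlite::write_json(
          list(rmse = rmse(te$leaf_count, yhat), r2 = r2,
               accuracy = count_accuracy(te$leaf_count, yhat), n = nrow(te)),
          file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
        list(n_in = nrow(te), n_out = nrow(te))
      },
      explain = {
        kind <- if (identical(sc$input, "skeleton")) "skeletons" else "crops"
        man <- current_manifest(kind)
        te <- man[man$split == "test", , drop = FALSE]
        row <- if (!is.null(sc$image_id))
          man[man$image_id == sc$image_id, , drop = FALSE] else te[1, ]
        if (!nrow(row)) stop("explain: image_id not found", call. = FALSE)
        model <- load_leaf_cnn(file.path(out_dir, "model.ckpt"))
        img <- read_image_png(row$path[1])
        method <- sc$method %||% "gradcam"
        map <- if (method == "occlusion")
          occlusion_heatmap(model, img, row$leaf_count[1],
                            window = sc$window %||% 10L,
                            stride = sc$stride %||% 5L,
                            window_color = if (kind == "skeletons") 0 else 255)
        else emphasize(grad_cam(model, img))
        utils::write.csv(map$values,
                         file.path(out_dir, paste0("heatmap_", method, ".csv")),
                         row.names = FALSE)
        write_image_png(render_overlay(map, img),
                        file.path(out_dir, paste0("overlay_", method, ".png")))
        list(n_in = 1L, n_out = 1L)
      }
    )
    rec$seconds <- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
    rec$params <- sc
    summary[[stage]] <- rec
    log_line(sprintf("[%s] stage %s: %d in, %d out (%.2fs)",
                     format(Sys.time()), stage, rec$n_in, rec$n_out,
                     rec$seconds))
  }
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
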