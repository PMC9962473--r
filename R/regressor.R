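# User-facing count-regression model: configuration, construction, training
# with RMSprop on mean squared error, prediction, and the usual fitted-model
# methods.

#' Configuration of the count-regression network
#'
#' The network is a strided convolutional stack closed by a global average
#' pooling layer and a single-unit dense head emitting the raw (unrounded)
#' leaf-count estimate. The conventional training hyperparameters are batch
#' size 16, learning rate 1e-4, the RMSprop optimizer, mean-squared-error
#' loss and a fixed 500 epochs (no early stopping). The `"reduced"` backbone
#' width-scales the stack and halves the input resolution so that training
#' runs at desk scale on a CPU; for desk-scale runs of the reduced backbone a
#' larger learning rate (0.01) is appropriate because training starts from
#' random weights for a few dozen epochs rather than fine-tuning pretrained
#' weights for hundreds.
#'
#' @param backbone `"reduced"` (default; width multiplier 0.25, input pooled
#'   2x) or `"full"` (width multiplier 1, no input pooling).
#' @param width_mult channel-width multiplier overriding the backbone
#'   default.
#' @param input_size input image side length (299).
#' @param batch_size minibatch size (default 16).
#' @param learning_rate RMSprop learning rate (default 1e-4).
#' @param epochs training epochs (default 500).
#' @param seed integer seed controlling initialization and data order.
#' @param rho RMSprop decay (default 0.9).
#' @return an object of class `"leaf_cnn_config"`.
#' @export
leaf_cnn_config <- function(backbone = c("reduced", "full"),
                            width_mult = NULL, input_size = 299L,
                            batch_size = 16L, learning_rate = 1e-4,
                            epochs = 500L, seed = 1L, rho = 0.9) {
  backbone <- match.arg(backbone)
  if (batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (is.null(width_mult))
    width_mult <- if (backbone == "reduced") 0.25 else 1
  structure(list(
    backbone = backbone, width_mult = width_mult,
    input_size = as.integer(input_size),
    batch_size = as.integer(batch_size),
    learning_rate = learning_rate, optimizer = "rmsprop", loss = "mse",
    epochs = as.integer(epochs), seed = as.integer(seed), rho = rho
  ), class = "leaf_cnn_config")
}

BASE_WIDTHS <- c(32L, 64L, 128L, 192L)

#' Build an (untrained) count-regression network
#'
#' Accepts `input_size x input_size x 3` images and emits one real scalar.
#' The final convolutional feature map (after ReLU) is exposed through
#' [feature_map()] for Grad-CAM.
#'
#' @param config a [leaf_cnn_config()].
#' @return an object of class `"leaf_cnn"`.
#' @export
build_leaf_cnn <- function(config = leaf_cnn_config()) {
  stopifnot(inherits(config, "leaf_cnn_config"))
  widths <- pmax(1L, round(BASE_WIDTHS * config$width_mult))
  pool <- if (config$backbone == "reduced") 2L else 1L
  params <- init_params(widths, seed = config$seed)
  structure(list(config = config, widths = widths, pool = pool,
                 params = params, trained = FALSE, history = NULL),
            class = "leaf_cnn")
}

#' Number of trainable parameters
#' @param model a `"leaf_cnn"`.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "leaf_cnn"))
  sum(vapply(model$params$conv, function(l) length(l$W) + length(l$b), 0)) +
    length(model$params$head$w) + 1L
}

check_input_image <- function(model, image) {
  s <- model$config$input_size
  if (!is.array(image) || length(dim(image)) != 3L ||
      !all(dim(image) == c(s, s, 3L)))
    stop("expected a ", s, " x ", s, " x 3 image", call. = FALSE)
  invisible(image)
}

#' Final convolutional feature map of an image
#'
#' @param model a `"leaf_cnn"`.
#' @param image an `input_size x input_size x 3` RGB array.
#' @return the post-ReLU final feature map (`h x w x C` array).
#' @export
feature_map <- function(model, image) {
  check_input_image(model, image)
  x <- prepare_input(image, model$pool)
  cnn_features(model$params, x)$feat
}

#' Weights of the single-unit dense head
#'
#' @param model a `"leaf_cnn"`.
#' @return a list with `w` (one weight per feature-map channel) and `b`.
#' @export
head_weights <- function(model) {
  stopifnot(inherits(model, "leaf_cnn"))
  model$params$head
}

load_image_any <- function(x, size) {
  img <- if (is.character(x)) read_image_png(x) else x
  if (!all(dim(img) == c(size, size, 3L)))
    stop("image is not ", size, " x ", size, " x 3", call. = FALSE)
  img
}

#' Train a count-regression network
#'
#' Minimizes the mean squared error between the scalar output and the
#' integer leaf-count labels of the manifest's training split with
#' minibatch RMSprop; all parameters are trainable. The per-epoch training
#' and validation losses are recorded in the returned model's `history`.
#' Seeded: the same configuration and seed reproduce the identical loss
#' curve.
#'
#' @param model an untrained (or previously trained) `"leaf_cnn"`.
#' @param manifest a dataset manifest whose `path` column points to
#'   `input_size`-sized RGB images (e.g. preprocessed crops or rendered
#'   skeletons).
#' @param epochs,learning_rate,batch_size overrides of the model's config.
#' @param lr_decay multiplicative per-epoch learning-rate decay (1 = the
#'   conventional constant rate; values just below 1 damp RMSprop's
#'   end-of-training oscillation in small desk-scale runs).
#' @param verbose print a line per epoch.
#' @return the trained `"leaf_cnn"` with `history` (data.frame of epoch,
#'   train_mse, val_mse), `fitted` (training-set predictions in manifest
#'   order) and `train_labels`.
#' @export
train_leaf_cnn <- function(model, manifest, epochs = NULL,
                           learning_rate = NULL, batch_size = NULL,
                           lr_decay = 1, verbose = FALSE) {
  stopifnot(inherits(model, "leaf_cnn"))
  validate_manifest(manifest)
  cfg <- model$config
  epochs <- if (is.null(epochs)) cfg$epochs else as.integer(epochs)
  lr <- if (is.null(learning_rate)) cfg$learning_rate else learning_rate
  bs <- if (is.null(batch_size)) cfg$batch_size else as.integer(batch_size)

  tr <- manifest[manifest$split == "train", , drop = FALSE]
  va <- manifest[manifest$split == "val", , drop = FALSE]
  if (!nrow(tr)) stop("manifest has no training rows", call. = FALSE)
  size <- cfg$input_size
  xs <- lapply(tr$path, function(p)
    prepare_input(load_image_any(p, size), model$pool))
  ys <- as.numeric(tr$leaf_count)
  xv <- lapply(va$path, function(p)
    prepare_input(load_image_any(p, size), model$pool))
  yv <- as.numeric(va$leaf_count)

  params <- model$params
  state <- zero_like_params(params)
  n <- length(xs)
  hist <- data.frame(epoch = integer(), train_mse = numeric(),
                     val_mse = numeric())
  with_seed(cfg$seed + 1L, {
    for (ep in seq_len(epochs)) {
      ep_lr <- lr * lr_decay^(ep - 1)
      ord <- sample.int(n)
      sse <- 0
      for (start in seq(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        bgrads <- NULL
        for (i in idx) {
          fwd <- cnn_forward(params, xs[[i]], keep_cache = TRUE)
          err <- fwd$yhat - ys[i]
          sse <- sse + err^2
          g <- cnn_backward(params, fwd, 2 * err / length(idx))
          bgrads <- if (is.null(bgrads)) g else add_grads(bgrads, g)
        }
        if (!all(is.finite(c(bgrads$head$w, bgrads$head$b))))
          stop("non-finite loss gradient at epoch ", ep, call. = FALSE)
        st <- rmsprop_step(params, bgrads, state, ep_lr, cfg$rho)
        params <- st$params; state <- st$state
      }
      train_mse <- sse / n
      val_mse <- if (length(xv))
        mean((vapply(xv, function(x) cnn_forward(params, x)$yhat, 0) - yv)^2)
      else NA_real_
      hist <- rbind(hist, data.frame(epoch = ep, train_mse = train_mse,
                                     val_mse = val_mse))
      if (verbose)
        cat(sprintf("epoch %3d  train MSE %.4f  val MSE %s\n", ep, train_mse,
                    ifelse(is.na(val_mse), "-", sprintf("%.4f", val_mse))))
    }
  })
  model$params <- params
  model$trained <- TRUE
  model$history <- hist
  model$fitted <- vapply(xs, function(x) cnn_forward(params, x)$yhat, 0)
  model$train_labels <- ys
  model
}

add_grads <- function(a, b) {
  for (l in seq_along(a$conv)) {
    a$conv[[l]]$dW <- a$conv[[l]]$dW + b$conv[[l]]$dW
    a$conv[[l]]$db <- a$conv[[l]]$db + b$conv[[l]]$db
  }
  a$head$w <- a$head$w + b$head$w
  a$head$b <- a$head$b + b$head$b
  a
}

#' Predict leaf counts
#'
#' Returns the raw (unrounded) scalar regression output for each image;
#' deterministic for fixed parameters and input.
#'
#' @param object a `"leaf_cnn"`.
#' @param newdata a single RGB array, a list of arrays, a character vector
#'   of PNG paths, or a manifest data.frame (its `path` column is used).
#' @param ... unused.
#' @return a numeric vector of raw count estimates.
#' @export
predict.leaf_cnn <- function(object, newdata, ...) {
  size <- object$config$input_size
  items <- if (is.data.frame(newdata)) as.list(newdata$path)
  else if (is.character(newdata)) as.list(newdata)
  else if (is.array(newdata) && length(dim(newdata)) == 3L) list(newdata)
  else if (is.list(newdata)) newdata
  else stop("unsupported newdata type", call. = FALSE)
  vapply(items, function(it) {
    x <- prepare_input(load_image_any(it, size), object$pool)
    cnn_forward(object$params, x)$yhat
  }, 0)
}

#' @export
print.leaf_cnn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Leaf-count regression CNN (%s backbone)\n", cfg$backbone))
  cat(sprintf("  input %dx%dx3 (internal pool %dx), conv widths %s\n",
              cfg$input_size, cfg$input_size, x$pool,
              paste(x$widths, collapse = "-")))
  cat(sprintf("  head: global average pooling + 1-unit dense; %d parameters\n",
              n_parameters(x)))
  cat(if (x$trained)
    sprintf("  trained %d epochs; final train MSE %.4f\n",
            nrow(x$history), utils::tail(x$history$train_mse, 1))
    else "  untrained\n")
  invisible(x)
}

#' @export
summary.leaf_cnn <- function(object, ...) {
  print(object)
  if (object$trained) {
    h <- object$history
    cat(sprintf("  loss curve: train %.4f -> %.4f", h$train_mse[1],
                utils::tail(h$train_mse, 1)))
    if (!all(is.na(h$val_mse)))
      cat(sprintf("; val %.4f -> %.4f", h$val_mse[1],
                  utils::tail(h$val_mse, 1)))
    cat("\n")
  }
  invisible(object)
}

#' @export
coef.leaf_cnn <- function(object, ...) {
  c(object$params$head$w, bias = object$params$head$b)
}

#' @export
residuals.leaf_cnn <- function(object, ...) {
  if (!object$trained) stop("model is untrained", call. = FALSE)
  object$fitted - object$train_labels
}

#' Plot training history
#'
#' @param x a trained `"leaf_cnn"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.leaf_cnn <- function(x, ...) {
  if (!x$trained) stop("model is untrained", call. = FALSE)
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_mse, h$val_mse), type = "l",
                    lty = 1, col = c("black", "red3"),
                    xlab = "epoch", ylab = "MSE", ...)
  graphics::legend("topright", c("train", "val"), lty = 1,
                   col = c("black", "red3"), bty = "n")
  invisible(x)
}

#' Save or load a trained model checkpoint
#'
#' Single-file checkpoint holding parameters, configuration and training
#' history.
#'
#' @param model a `"leaf_cnn"`.
#' @param path checkpoint file path.
#' @return `load_leaf_cnn` returns the model; `save_leaf_cnn` returns
#'   `path` invisibly.
#' @export
save_leaf_cnn <- function(model, path) {
  stopifnot(inherits(model, "leaf_cnn"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_leaf_cnn
#' @export
load_leaf_cnn <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "leaf_cnn"))
  model
}
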