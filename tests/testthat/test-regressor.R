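# The count-regression network: contracts, gradients, training behavior.

test_that("the network maps one image to one finite scalar, batches to vectors", {
  model <- build_leaf_cnn(leaf_cnn_config(seed = 3L))
  zero <- array(0, c(299, 299, 3))
  p <- predict(model, zero)
  expect_length(p, 1L)
  expect_true(is.finite(p))

  batch <- lapply(1:16, function(i) random_rgb(299, 299, seed = i))
  preds <- predict(model, batch)
  expect_length(preds, 16L)
  expect_true(all(is.finite(preds)))

  expect_error(predict(model, array(0, c(100, 100, 3))), "not 299")
  expect_error(build_leaf_cnn(leaf_cnn_config(learning_rate = 0)), "learning_rate")
})

test_that("the reduced backbone is a small fraction of the full one", {
  full <- build_leaf_cnn(leaf_cnn_config(backbone = "full"))
  reduced <- build_leaf_cnn(leaf_cnn_config(width_mult = 0.125))
  expect_lt(n_parameters(reduced) / n_parameters(full), 0.05)
})

test_that("the head is exactly global average pooling plus one dense unit", {
  model <- build_leaf_cnn(leaf_cnn_config(seed = 5L))
  img <- random_rgb(299, 299, seed = 21)
  feat <- feature_map(model, img)
  hw <- head_weights(model)
  gap <- colMeans(matrix(feat, ncol = dim(feat)[3]))
  expect_equal(sum(hw$w * gap) + hw$b, predict(model, img), tolerance = 1e-12)
})

test_that("backpropagated gradients match numerical differentiation", {
  set.seed(9)
  x <- array(runif(21 * 21 * 3, -1, 1), c(21, 21, 3))
  params <- leafcount:::init_params(c(2L, 3L), seed = 4L)
  fwd <- leafcount:::cnn_forward(params, x, keep_cache = TRUE)
  gr <- leafcount:::cnn_backward(params, fwd, 1)
  numgrad <- function(set) {
    eps <- 1e-6
    (leafcount:::cnn_forward(set(params, eps), x)$yhat - fwd$yhat) / eps
  }
  cases <- list(
    list(got = gr$conv[[1]]$dW[1, 2, 1, 2],
         num = numgrad(function(p, e) { p$conv[[1]]$W[1, 2, 1, 2] <-
           p$conv[[1]]$W[1, 2, 1, 2] + e; p })),
    list(got = gr$conv[[2]]$dW[3, 1, 2, 1],
         num = numgrad(function(p, e) { p$conv[[2]]$W[3, 1, 2, 1] <-
           p$conv[[2]]$W[3, 1, 2, 1] + e; p })),
    list(got = gr$conv[[2]]$db[2],
         num = numgrad(function(p, e) { p$conv[[2]]$b[2] <-
           p$conv[[2]]$b[2] + e; p })),
    list(got = gr$head$w[1],
         num = numgrad(function(p, e) { p$head$w[1] <- p$head$w[1] + e; p }))
  )
  for (cs in cases) expect_equal(cs$got, cs$num, tolerance = 1e-4)
})

test_that("the first recorded epoch loss equals the initial-model MSE", {
  ds <- fixture_dataset()
  man <- ds$manifest
  tr <- man[man$split == "train", ][1:4, ]
  model <- build_leaf_cnn(leaf_cnn_config(seed = 13L))
  init_preds <- predict(model, tr)
  hand_mse <- mean((init_preds - tr$leaf_count)^2)
  trained <- train_leaf_cnn(model, tr, epochs = 1, batch_size = 4L,
                            learning_rate = 1e-4)
  # one full-set batch: the epoch's loss is accumulated before the update
  expect_equal(trained$history$train_mse[1], hand_mse, tolerance = 1e-10)
})

test_that("training is seeded-deterministic and reduces the loss", {
  ds <- fixture_dataset()
  man <- ds$manifest
  run <- function() train_leaf_cnn(build_leaf_cnn(leaf_cnn_config(seed = 7L)),
                                   man, epochs = 5, learning_rate = 0.01)
  m1 <- run(); m2 <- run()
  expect_identical(m1$history, m2$history)
  expect_lt(tail(m1$history$train_mse, 1), m1$history$train_mse[1])
  expect_true(all(is.finite(m1$history$val_mse)))

  # methods on the fitted object
  expect_output(print(m1), "trained 5 epochs")
  expect_length(coef(m1), length(head_weights(m1)$w) + 1L)
  expect_length(residuals(m1), sum(man$split == "train"))
  expect_silent(grDevices::png(tempfile(fileext = ".png")))
  plot(m1); grDevices::dev.off()
})

test_that("a single repeated sample is memorized within half a leaf", {
  ds <- fixture_dataset()
  one <- ds$manifest[ds$manifest$split == "train", ][1, ]
  one$leaf_count <- 3L
  model <- train_leaf_cnn(build_leaf_cnn(leaf_cnn_config(seed = 5L)), one,
                          epochs = 50, learning_rate = 0.01, lr_decay = 0.95)
  pred <- predict(model, read_image_png(one$path))
  expect_lt(abs(pred - 3), 0.5)
})

test_that("inference is deterministic; checkpoints round-trip", {
  model <- build_leaf_cnn(leaf_cnn_config(seed = 31L))
  img <- random_rgb(299, 299, seed = 44)
  expect_identical(predict(model, img), predict(model, img))
  # augmented views may change the prediction; both are finite raw scalars
  both <- c(predict(model, img), predict(model, apply_transform(img, "flip_h")))
  expect_true(all(is.finite(both)))

  ck <- tempfile(fileext = ".ckpt")
  save_leaf_cnn(model, ck)
  expect_identical(predict(load_leaf_cnn(ck), img), predict(model, img))
})
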