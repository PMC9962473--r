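# Plant extraction: background averaging, differencing, grayscale, Otsu,
# connected components, cropping and resizing.

test_that("background averaging is an exact rounded per-pixel mean", {
  img <- random_rgb(8, 8, seed = 1)
  expect_identical(average_background(list(img, img, img)), img * 1)

  z <- array(0, c(4, 4, 3)); two <- array(2, c(4, 4, 3))
  expect_identical(average_background(list(z, two)), array(1, c(4, 4, 3)))

  set <- lapply(1:50, function(s) random_rgb(6, 6, seed = s))
  got <- average_background(set)
  # independent second path: stack, plain mean, then round half-up
  stack <- simplify2array(set)
  oracle <- floor(apply(stack, 1:3, mean) + 0.5)
  expect_lte(max(abs(got - oracle)), 1)
  expect_identical(got, oracle)

  expect_error(average_background(list()), "at least one")
  expect_error(average_background(list(z, array(0, c(5, 4, 3)))), "differ")
})

test_that("difference image is the per-channel absolute difference", {
  img <- random_rgb(10, 10, seed = 2)
  expect_true(all(difference_image(img, img) == 0))

  a <- array(0, c(12, 24, 3)); b <- array(0, c(12, 24, 3))
  a[10, 20, ] <- c(100, 100, 100); b[10, 20, ] <- c(90, 110, 100)
  expect_equal(difference_image(a, b)[10, 20, ], c(10, 10, 0))
  expect_error(difference_image(a, array(0, c(5, 5, 3))), "differ")
})

test_that("difference against own background lights up the plant mask", {
  sc <- fixture_scene()
  diff <- difference_image(sc$plant$image, sc$avg)
  nz <- apply(diff, c(1, 2), max) > 0
  expect_gte(mean(nz[sc$plant$plant_mask == 1]), 0.95)
})

test_that("grayscale conversion uses luma weights that sum to one", {
  expect_true(all(to_gray(array(255, c(3, 3, 3))) == 255))
  for (v in c(0L, 1L, 77L, 128L, 254L, 255L))
    expect_true(all(to_gray(array(v, c(2, 2, 3))) == v))

  img <- random_rgb(15, 15, seed = 3)
  oracle <- round(apply(img, c(1, 2), function(px)
    sum(px * c(0.299, 0.587, 0.114))))
  expect_identical(to_gray(img), oracle)
})

test_that("Otsu threshold separates a two-level image and flips with polarity", {
  g <- matrix(10, 10, 10); g[3:6, 4:8] <- 200
  res <- otsu_binarize(g, "bright")
  expect_true(all(res$mask[g == 200] == 1))
  expect_true(all(res$mask[g == 10] == 0))
  expect_gte(res$threshold, 10); expect_lte(res$threshold, 199)

  r <- random_gray(24, 24, seed = 4)
  m1 <- otsu_binarize(r, "bright")$mask
  m2 <- otsu_binarize(255 - r, "dark")$mask
  expect_identical(m1, m2)

  expect_error(otsu_binarize(matrix(7, 5, 5)), "constant")
})

test_that("Otsu threshold equals the exhaustive between-class-variance search", {
  for (s in 1:20) {
    g <- random_gray(20, 20, seed = 100 + s)
    expect_identical(otsu_binarize(g)$threshold, otsu_bruteforce(g))
  }
})

test_that("connected components match the flood-fill oracle", {
  empty <- matrix(0, 5, 5)
  expect_equal(connected_components(empty)$n, 0L)

  diag2 <- matrix(0, 4, 4); diag2[1, 1] <- 1; diag2[2, 2] <- 1
  expect_equal(connected_components(diag2, 8)$n, 1L)
  expect_equal(connected_components(diag2, 4)$n, 2L)

  for (s in 1:10) for (conn in c(4, 8)) {
    m <- random_mask(18, 15, p = 0.35, seed = 200 + s)
    got <- connected_components(m, conn)
    oracle <- floodfill_components(m, conn)
    expect_equal(got$n, max(oracle))
    expect_identical(sort(got$table$area_px), sort(as.integer(tabulate(oracle[oracle > 0]))))
    # identical partitions: labels must map one-to-one
    fg <- which(m == 1)
    expect_equal(length(unique(paste(got$label_map[fg], oracle[fg]))),
                 got$n)
    expect_equal(sum(got$table$area_px), sum(m))
  }
})

test_that("largest-component bbox follows the half-open convention and ties", {
  m <- matrix(0, 10, 12); m[3:5, 6:8] <- 1
  cc <- connected_components(m)
  expect_equal(unname(largest_component_bbox(cc)), c(2L, 5L, 5L, 8L))

  m2 <- matrix(0, 10, 20); m2[1:2, 1:5] <- 1; m2[5:9, 8:17] <- 1
  box <- largest_component_bbox(connected_components(m2))
  expect_equal(unname(box), c(4L, 7L, 9L, 17L))

  # equal areas: smallest label (first in scan order) wins
  m3 <- matrix(0, 6, 12); m3[1:2, 1:2] <- 1; m3[4:5, 8:9] <- 1
  expect_equal(unname(largest_component_bbox(connected_components(m3))),
               c(0L, 0L, 2L, 2L))
  expect_error(largest_component_bbox(connected_components(matrix(0, 3, 3))),
               "no components")
})

test_that("crop_resize preserves aspect, pads white and has an exact nearest mode", {
  img <- random_rgb(40, 40, seed = 5)
  sq <- crop_resize(img, c(0, 0, 40, 40), out_size = 20)
  expect_equal(dim(sq), c(20L, 20L, 3L))
  expect_false(any(sq == 255 & !any(img == 255)))  # no padding introduced

  tall <- random_rgb(100, 50, seed = 6)
  tall[tall == 255] <- 254
  out <- crop_resize(tall, c(0, 0, 100, 50), out_size = 299)
  expect_equal(dim(out), c(299L, 299L, 3L))
  pad_cols <- apply(out, 2, function(col) all(col == 255))
  expect_gt(sum(pad_cols), 100)            # ~149 padded columns
  content_cols <- which(!pad_cols)
  expect_equal(length(content_cols), 150)  # round(50 * 299/100)

  # hand-worked nearest-neighbor case: 2x2 upsampled to 4x4 duplicates each
  # pixel into a 2x2 block (output i samples input floor((i-.5)*2/4)+1)
  tiny <- array(0, c(2, 2, 3))
  tiny[1, 1, ] <- 10; tiny[1, 2, ] <- 20; tiny[2, 1, ] <- 30; tiny[2, 2, ] <- 40
  up <- crop_resize(tiny, c(0, 0, 2, 2), out_size = 4, method = "nearest")
  expect_equal(up[, , 1],
               matrix(c(10, 10, 30, 30,
                        10, 10, 30, 30,
                        20, 20, 40, 40,
                        20, 20, 40, 40), 4, 4))

  # idempotence: full-frame box at the native size is a no-op (nearest)
  native <- random_rgb(32, 32, seed = 7)
  expect_identical(crop_resize(native, c(0, 0, 32, 32), 32,
                               method = "nearest"), native * 1)
  expect_error(crop_resize(img, c(5, 5, 5, 10)), "degenerate")
})

test_that("pipeline crops the plant, excludes far distractors, errors on no plant", {
  sc <- fixture_scene()
  out <- preprocess_pipeline(sc$plant$image, sc$avg)
  expect_equal(dim(out), c(299L, 299L, 3L))

  # bbox captures nearly all true plant pixels
  box <- attr(out, "geometry")$box
  inbox <- sc$plant$plant_mask[(box[1] + 1):box[3], (box[2] + 1):box[4]]
  expect_gte(sum(inbox) / sum(sc$plant$plant_mask), 0.99)

  # a 40-px distractor blob far from the plant stays outside the crop
  img2 <- sc$plant$image
  img2[3:7, 3:10, ] <- 30              # 5 x 8 = 40 px dark blob, top-left
  out2 <- preprocess_pipeline(img2, sc$avg)
  box2 <- attr(out2, "geometry")$box
  expect_true(box2[1] > 7 || box2[2] > 10)

  expect_error(
    preprocess_pipeline(render_background(plant_spec(
      canvas_size = c(256L, 256L), seed = 12345L)), sc$avg),
    "no plant")
})

test_that("growing the plant never shrinks the largest component", {
  areas <- vapply(1:5, function(k) {
    pl <- render_plant(plant_spec(leaf_count = k,
                                  canvas_size = c(256L, 256L), seed = 19L))
    bg <- render_background(plant_spec(canvas_size = c(256L, 256L),
                                       seed = 19L))
    d <- to_gray(difference_image(pl$image, bg))
    cc <- connected_components(otsu_binarize(d, "bright")$mask)
    max(cc$table$area_px)
  }, 0)
  expect_true(all(diff(areas) >= 0))
})
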