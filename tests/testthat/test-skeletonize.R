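# Skeleton-structure derivation: binarization, thinning, dilation,
# small-component removal and the composed pipeline.

test_that("plant binarization is polarity-symmetric and matches ground truth", {
  img <- array(230, c(20, 20, 3))
  img[5:15, 8:12, ] <- 15
  m <- binarize_plant(img, "dark")
  expect_identical(m, (to_gray(img) < 100) * 1)

  m2 <- binarize_plant(255 - img, "bright", exclude_white = FALSE)
  m3 <- binarize_plant(img, "dark", exclude_white = FALSE)
  expect_identical(m2, m3)

  sc <- fixture_scene()
  mask <- binarize_plant(sc$crop)
  geom <- attr(sc$crop, "geometry")
  gt3 <- array(rep(sc$plant$plant_mask * 255, 3),
               c(dim(sc$plant$plant_mask), 3L))
  gt <- crop_resize(gt3, geom$box, 299, method = "nearest", pad_value = 0)[, , 1] / 255
  expect_gte(sum(mask * gt) / sum(gt), 0.90)

  expect_error(binarize_plant(array(128, c(5, 5, 3))), "constant")
})

test_that("thinning produces a one-pixel skeleton with preserved topology", {
  # 5 x 100 bar: reference morphology oracle yields a single 1-px row of
  # length 96 (ends eroded); accept the same within +-4 px
  bar <- matrix(0, 20, 110); bar[8:12, 6:105] <- 1
  tb <- thin(bar)
  rows <- unique(which(tb == 1, arr.ind = TRUE)[, 1])
  expect_length(rows, 1L)
  expect_gte(sum(tb), 92); expect_lte(sum(tb), 100)

  # idempotence on an already-thin line
  line <- matrix(0, 10, 40); line[5, 3:37] <- 1
  expect_identical(thin(line), line)

  # a filled annulus keeps exactly one cycle: its complement still has an
  # inside and an outside under 4-connectivity
  ann <- matrix(0, 41, 41)
  d2 <- outer((1:41 - 21)^2, (1:41 - 21)^2, "+")
  ann[d2 >= 36 & d2 <= 144] <- 1
  ta <- thin(ann)
  expect_equal(connected_components(1 - ta, 4)$n, 2L)
  expect_equal(connected_components(ta, 8)$n, 1L)

  # anti-extensivity on random blobs
  for (s in 1:5) {
    m <- dilate_mask(random_mask(30, 30, p = 0.2, seed = 300 + s), 1)
    expect_true(all(thin(m) <= m))
  }
})

test_that("dilation is the Minkowski sum with a square element", {
  center <- matrix(0, 5, 5); center[3, 3] <- 1
  expect_identical(dilate_mask(center, 1), {
    b <- matrix(0, 5, 5); b[2:4, 2:4] <- 1; b
  })

  # a 2-px gap between collinear segments closes at radius 1
  seg <- matrix(0, 7, 20); seg[4, 2:8] <- 1; seg[4, 11:19] <- 1
  expect_equal(connected_components(seg)$n, 2L)
  expect_equal(connected_components(dilate_mask(seg, 1))$n, 1L)

  for (s in 1:5) for (r in 1:2) {
    m <- random_mask(16, 14, p = 0.15, seed = 400 + s)
    got <- dilate_mask(m, r)
    expect_identical(got, minkowski_dilate(m, r))
    expect_true(all(got >= m))  # extensivity
  }
})

test_that("area filtering keeps components at or above the threshold", {
  m <- matrix(0, 40, 60)
  m[2:8, 2:8] <- 1          # 49 px
  m[2:6, 20:29] <- 1        # 50 px
  m[20:22, 2:18] <- 1       # 51 px
  out <- remove_small_components(m, 50)
  expect_equal(sum(out[2:8, 2:8]), 0)
  expect_equal(sum(out[2:6, 20:29]), 50)
  expect_equal(sum(out[20:22, 2:18]), 51)

  expect_identical(remove_small_components(m, 0), m)

  for (s in 1:5) {
    mm <- random_mask(25, 25, p = 0.3, seed = 500 + s)
    got <- remove_small_components(mm, 5)
    lab <- floodfill_components(mm, 8)
    areas <- tabulate(lab[lab > 0])
    oracle <- mm
    for (l in which(areas < 5)) oracle[lab == l] <- 0
    expect_identical(got, oracle)
    # monotone in min_area
    counts <- vapply(c(0, 2, 5, 10, 50), function(a)
      sum(remove_small_components(mm, a)), 0)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("the skeleton pipeline denoises and unifies a clean plant", {
  sc <- fixture_scene()
  stages <- skeleton_pipeline(sc$crop, detail = TRUE)
  expect_equal(connected_components(stages$skeleton)$n, 1L)
  expect_true(all(stages$thinned <= stages$binary))
  expect_true(all(stages$dilated1 >= stages$thinned))
  expect_identical(skeleton_pipeline(sc$crop), stages$skeleton)

  # a 30-px distractor blob vanishes from the final skeleton
  img2 <- sc$crop
  img2[10:14, 10:15, ] <- 20           # 5 x 6 = 30 px blob
  sk2 <- skeleton_pipeline(img2)
  expect_equal(sum(sk2[8:17, 8:18]), 0)

  expect_error(skeleton_pipeline(array(255, c(50, 50, 3))), "constant")
})

test_that("dilation repairs a 2-px break that thinning alone leaves open", {
  # synthetic leaf stroke with a deliberately inserted 2-px weak segment
  leaf <- matrix(0, 60, 120)
  for (t in seq(0, 1, length.out = 200)) {
    r <- round(45 - 35 * t + 20 * t^2); c <- round(5 + 110 * t)
    leaf[max(1, r - 2):min(60, r + 2), max(1, c - 2):min(120, c + 2)] <- 1
  }
  thinned <- thin(leaf)
  broken <- thinned
  broken[, 60:61] <- 0                 # 2-px break in the thinned skeleton
  n_broken <- connected_components(broken)$n
  expect_equal(n_broken, connected_components(thinned)$n + 1L)

  repaired <- dilate_mask(remove_small_components(
    dilate_mask(broken, 1), 50), 1)
  expect_equal(connected_components(repaired)$n, n_broken - 1L)
})

test_that("skeleton rendering is black-on-white RGB", {
  m <- matrix(0, 5, 5); m[3, ] <- 1
  rgb <- skeleton_to_rgb(m)
  expect_equal(dim(rgb), c(5L, 5L, 3L))
  expect_true(all(rgb[3, , ] == 0))
  expect_true(all(rgb[1, , ] == 255))
})
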