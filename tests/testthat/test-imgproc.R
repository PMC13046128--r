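# Projection, masking, background subtraction, thresholding, cleanup.

test_that("maximum projection equals a brute-force triple loop", {
  set.seed(1)
  v <- array(runif(3 * 4 * 4, 0, 65535), dim = c(4, 4, 3))
  got <- max_project(v)
  ref <- matrix(0, 4, 4)
  for (y in 1:4) for (x in 1:4) for (z in 1:3) {
    ref[y, x] <- max(ref[y, x], v[y, x, z])
  }
  expect_equal(got, ref)
  one <- array(0, dim = c(3, 3, 3)); one[, , 2] <- 7
  expect_equal(max_project(one), matrix(7, 3, 3))
  expect_equal(max_project(array(0, dim = c(2, 2, 2))), matrix(0, 2, 2))
  expect_error(max_project(array(0, dim = c(2, 2, 0))), "stack")
})

test_that("masking zeroes outside pixels and leaves inside untouched", {
  img <- matrix(1:20, 4, 5)
  expect_equal(apply_mask(img, matrix(1, 4, 5)), img)
  expect_equal(apply_mask(img, matrix(0, 4, 5)), matrix(0, 4, 5))
  half <- matrix(0, 4, 5); half[, 1:2] <- 1
  m <- apply_mask(img, half)
  expect_equal(m[, 1:2], img[, 1:2])
  expect_true(all(m[, 3:5] == 0))
  expect_error(apply_mask(img, matrix(1, 5, 4)), "shapes")
})

test_that("background subtraction flattens constants and keeps small disks", {
  expect_true(all(subtract_background(matrix(500, 60, 60), 20) == 0))
  img <- matrix(200, 120, 120) + 1000 * raster_disk(120, 120, 60, 60, 5)
  out <- subtract_background(img, 20)
  expect_gte(max(out), 800)
  set.seed(2)
  rnd <- matrix(runif(80 * 80, 0, 4000), 80, 80)
  out <- subtract_background(rnd, 10)
  expect_true(all(out <= rnd + 1e-9))
  expect_true(all(out >= 0))
  expect_error(subtract_background(rnd, 0), ">= 1")
})

test_that("mask-aware background estimation removes the tissue-edge rim", {
  # a tissue strip narrower than the ball: the plain opening collapses to
  # zero there and subtraction leaves the whole strip bright, while the
  # mask-aware estimate keeps only the small cell
  mask <- matrix(0, 120, 120); mask[49:72, ] <- 1
  img <- (1000 + 600 * raster_disk(120, 120, 60, 60, 5)) * mask
  plain <- subtract_background(img, 20)
  aware <- subtract_background(img, 20, mask = mask)
  off_cell <- mask == 1 & raster_disk(120, 120, 60, 60, 8) == 0
  expect_gt(max(plain[off_cell]), 500)
  expect_lt(max(aware[off_cell]), 50)
  expect_gte(max(aware), 550)
})

test_that("maximum-entropy threshold separates a bimodal image", {
  set.seed(3)
  vals <- c(rep(50, 800), rep(200, 200))
  img <- matrix(sample(vals), 40, 25)
  thr <- threshold_max_entropy(img)
  expect_gt(thr, 50)
  expect_lt(thr, 200)
  expect_error(threshold_max_entropy(matrix(7, 5, 5)), "degenerate")
})

test_that("maximum-entropy threshold equals the exhaustive oracle", {
  set.seed(9)
  for (rep in 1:10) {
    img <- matrix(runif(60 * 60, 0, 65535)^2 / 65535, 60, 60)
    expect_equal(threshold_max_entropy(img), oracle_max_entropy(as.vector(img)))
  }
})

test_that("out-of-mask pixels never influence the threshold", {
  set.seed(10)
  img <- matrix(runif(50 * 50, 0, 1000), 50, 50)
  mask <- matrix(0, 50, 50); mask[11:40, 11:40] <- 1
  t0 <- threshold_max_entropy(img, mask)
  img2 <- img
  img2[mask == 0] <- runif(sum(mask == 0), 0, 65535)
  expect_equal(threshold_max_entropy(img2, mask), t0)
})

test_that("binarise-and-clean despeckles, fills holes and is idempotent", {
  img <- matrix(0, 20, 20)
  img[5, 5] <- 10                       # isolated speckle
  bin <- binarize_clean(img, 1)
  expect_equal(sum(bin), 0)
  sq <- matrix(0, 20, 20); sq[6:15, 6:15] <- 10; sq[10, 10] <- 0
  bin <- binarize_clean(sq, 1)
  expect_equal(bin[10, 10], 1)          # interior hole closed
  disk <- 10 * raster_disk(60, 60, 30, 30, 15)
  bin <- binarize_clean(disk, 1)
  plain <- (disk > 1) * 1
  boundary <- EBImage::dilate(plain, matrix(1L, 3, 3)) -
    EBImage::erode(plain, matrix(1L, 3, 3))
  expect_true(all(bin[boundary == 0] == plain[boundary == 0]))
  twice <- binarize_clean(bin, 0.5)
  expect_equal(twice, binarize_clean(disk, 1))
})

test_that("channel segmentation recovers a rendered disk mask", {
  sec <- simulate_section(tiny_config(seed = 3))
  seg <- segment_channel(sec$stacks$Calbindin, sec$geometry)
  expect_true(all(seg$mask %in% c(0, 1)))
  expect_true(all(seg$mask[sec$geometry$gray_mask == 0] == 0))
  truth <- sec$truth[sec$truth$Calbindin, ]
  for (i in seq_len(nrow(truth))) {
    expect_equal(seg$mask[round(truth$y_px[i]), round(truth$x_px[i])], 1)
  }
})
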