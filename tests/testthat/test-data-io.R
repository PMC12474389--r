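# Manifest validation, cropping arithmetic, 7:2:1 splitting, preprocessing.

write_tmp_manifest <- function(df) {
  p <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
  p
}

test_that("read_manifest validates structure and names the offending row", {
  good <- data.frame(path = c("a.png", "b.png"), x0 = c(1, 2), y0 = c(1, 2),
                     x1 = c(10, 12), y1 = c(20, 22), bcs = c(3.25, 4.25))
  expect_equal(nrow(read_manifest(write_tmp_manifest(good))), 2)

  bad_label <- good; bad_label$bcs[2] <- 3.30
  expect_error(read_manifest(write_tmp_manifest(bad_label)), "row 2.*3.3")

  bad_box <- good; bad_box$x1[1] <- 1  # x1 <= x0
  expect_error(read_manifest(write_tmp_manifest(bad_box)), "row 1.*bbox")

  expect_error(read_manifest(write_tmp_manifest(good[, -6])), "missing columns.*bcs")
  expect_error(read_manifest(tempfile()), "not found")
})

test_that("crop_tail follows the half-open convention", {
  img <- array(seq_len(100 * 100 * 3) / 3e4, c(100, 100, 3))
  expect_identical(crop_tail(img, c(0, 0, 100, 100)), img)
  cr <- crop_tail(img, c(10, 20, 30, 60))
  expect_equal(dim(cr), c(40, 20, 3))
  expect_identical(cr, img[21:60, 11:30, , drop = FALSE])
  # idempotent under a full-extent recrop
  expect_identical(crop_tail(cr, c(0, 0, 20, 40)), cr)
  expect_error(crop_tail(img, c(0, 0, 0, 10)), "empty bbox")
  expect_error(crop_tail(img, c(90, 0, 110, 10)), "outside image bounds")
})

test_that("split sizes follow the floor-remainder rule", {
  sp <- split_dataset(53566, seed = 1)
  expect_equal(lengths(sp), c(train = 37496, val = 10713, test = 5357))
  expect_equal(lengths(split_dataset(10)), c(train = 7, val = 2, test = 1))
  expect_equal(lengths(split_dataset(11)), c(train = 7, val = 2, test = 2))
  expect_error(split_dataset(2), "n must be >= 3")
  expect_error(split_dataset(10, ratios = c(0.5, 0.2, 0.2)), "summing to 1")
})

test_that("splits partition the index range for random n", {
  set.seed(99)
  for (n in sample(3:500, 20)) {
    sp <- split_dataset(n, seed = n)
    all_idx <- sort(c(sp$train, sp$val, sp$test))
    expect_identical(all_idx, 0:(n - 1))
    expect_length(intersect(sp$train, sp$val), 0)
    expect_length(intersect(sp$train, sp$test), 0)
  }
})

test_that("split sizes depend only on n; membership only on the seed", {
  a <- split_dataset(100, seed = 1)
  b <- split_dataset(100, seed = 2)
  expect_equal(lengths(a), lengths(b))
  expect_false(identical(a$train, b$train))
  expect_identical(a, split_dataset(100, seed = 1))
})

test_that("preprocess resizes and channel-normalizes", {
  mean_c <- c(0.485, 0.456, 0.406); sd_c <- c(0.229, 0.224, 0.225)
  out <- preprocess(array(0, c(17, 31, 3)), 224)
  expect_equal(dim(out), c(224, 224, 3))
  for (ch in 1:3)
    expect_equal(unique(as.vector(out[, , ch])), -mean_c[ch] / sd_c[ch])
  # uniform gray 128 on the 0-255 scale
  out <- preprocess(array(128, c(10, 10, 3)), 8)
  for (ch in 1:3)
    expect_equal(unique(as.vector(out[, , ch])),
                 (128 / 255 - mean_c[ch]) / sd_c[ch], tolerance = 1e-12)
  expect_error(preprocess(array(0, c(5, 5)), 8), "RGB")
})

test_that("bilinear resize is exact on constants and preserves range", {
  expect_equal(bilinear_resize(matrix(0.7, 9, 13), 5, 7), matrix(0.7, 5, 7))
  set.seed(1)
  img <- matrix(runif(64), 8, 8)
  up <- bilinear_resize(img, 19, 19)
  expect_true(min(up) >= min(img) - 1e-12 && max(up) <= max(img) + 1e-12)
})
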