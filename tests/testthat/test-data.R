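test_that("IDX files round-trip and hand-assembled bytes parse correctly", {
  set.seed(1)
  ds <- synth_textured_dataset(3, 2, seed = 1)
  ds$images <- ds$images[, 1:4, 1:4, , drop = FALSE]
  fi <- tempfile(); fl <- tempfile()
  write_idx(ds, fi, fl)
  back <- load_idx(fi, fl)
  expect_equal(back$images, ds$images)
  expect_equal(back$labels, ds$labels)
  # grayscale 3-D layout
  g <- ds; g$images <- ds$images[, , , 1, drop = FALSE]
  write_idx(g, fi, fl)
  expect_equal(load_idx(fi, fl)$images, g$images)
  # bytes assembled by hand per the big-endian layout: 2 images of 2x2,
  # row-major pixels 10..17
  con <- file(fi, "wb")
  writeBin(c(0x00000803L, 2L, 2L, 2L), con, size = 4, endian = "big")
  writeBin(as.integer(10:17), con, size = 1)
  close(con)
  con <- file(fl, "wb")
  writeBin(c(0x00000801L, 2L), con, size = 4, endian = "big")
  writeBin(c(0L, 1L), con, size = 1)
  close(con)
  parsed <- load_idx(fi, fl)
  expect_equal(parsed$images[1, , , 1], matrix(c(10, 11, 12, 13), 2, byrow = TRUE))
  expect_equal(parsed$images[2, , , 1], matrix(c(14, 15, 16, 17), 2, byrow = TRUE))
  expect_equal(parsed$labels, c(0L, 1L))
  unlink(c(fi, fl))
})

test_that("IDX count mismatches and bad magics are rejected", {
  fi <- tempfile(); fl <- tempfile()
  con <- file(fi, "wb")
  writeBin(c(0x00000803L, 3L, 2L, 2L), con, size = 4, endian = "big")
  writeBin(as.integer(rep(0, 12)), con, size = 1)
  close(con)
  con <- file(fl, "wb")
  writeBin(c(0x00000801L, 2L), con, size = 4, endian = "big")
  writeBin(c(0L, 1L), con, size = 1)
  close(con)
  expect_error(load_idx(fi, fl), "does not match")
  expect_error(load_idx(fl, fi), "magic")
  unlink(c(fi, fl))
})

test_that("image folders load with sorted class order and resizing", {
  skip_if_not_installed("EBImage")
  root <- tempfile()
  dir.create(file.path(root, "malignant"), recursive = TRUE)
  dir.create(file.path(root, "benign"), recursive = TRUE)
  # 32x32 image with a bright top-left quadrant (orientation probe)
  probe <- array(0, c(32, 32, 3))
  probe[1:8, 1:8, ] <- 1
  png::writePNG(probe, file.path(root, "benign", "a.png"))
  png::writePNG(array(runif(64 * 64 * 3), c(64, 64, 3)),
                file.path(root, "malignant", "b.png"))  # resized 64 -> 32
  png::writePNG(array(0.5, c(32, 32, 3)), file.path(root, "malignant", "c.png"))
  ds <- load_image_folder(root, shape = c(32L, 32L, 3L))
  expect_equal(ds$class_names, c("benign", "malignant"))
  expect_equal(ds$labels, c(0L, 1L, 1L))
  expect_equal(dim(ds$images), c(3, 32, 32, 3))
  # orientation preserved: the bright quadrant stays top-left
  expect_gt(mean(ds$images[1, 1:8, 1:8, ]), 200)
  expect_lt(mean(ds$images[1, 20:32, 20:32, ]), 50)
  # undecodable files are skipped with a warning
  writeLines("not a png", file.path(root, "benign", "broken.png"))
  expect_warning(ds2 <- load_image_folder(root), "skipping")
  expect_equal(length(ds2$labels), 3)
  expect_error(load_image_folder(tempfile()), "no class subdirectories")
  unlink(root, recursive = TRUE)
})

test_that("the stratified split is a deterministic partition with a validation floor", {
  ds <- synth_textured_dataset(100, 2, seed = 3)
  sp <- split_80_20(ds, seed = 0)
  expect_equal(length(sp$val$labels), 20)
  expect_equal(sum(sp$val$labels == 0), 10)
  expect_equal(sort(c(sp$train_idx, sp$val_idx)), 1:100)
  expect_length(intersect(sp$train_idx, sp$val_idx), 0)
  sp2 <- split_80_20(ds, seed = 0)
  expect_identical(sp$val_idx, sp2$val_idx)
  expect_false(identical(sp$val_idx, split_80_20(ds, seed = 1)$val_idx))
  # 7-sample class: floor(7/5) = 1 validation sample
  small <- list(images = array(0, c(10, 4, 4, 1)),
                labels = c(rep(0L, 7), rep(1L, 3)))
  small <- structure(small, class = "image_dataset")
  sps <- split_80_20(small, seed = 0)
  expect_equal(sum(sps$val$labels == 0), 1)
  expect_equal(sum(sps$val$labels == 1), 1)
  # classes of size < 2 are rejected
  tiny <- structure(list(images = array(0, c(3, 4, 4, 1)),
                         labels = c(0L, 0L, 1L)), class = "image_dataset")
  expect_error(split_80_20(tiny), "at least 2")
})

test_that("the (0, 0) augmentation tuple is the identity", {
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  out <- random_transform(img, 0, 0)
  expect_equal(array(out, dim(img)), img)
})

test_that("translation moves pixels by the drawn integer shift", {
  delta <- matrix(0, 16, 16)
  delta[8, 8] <- 1
  set.seed(42)
  out <- random_transform(delta, max_shift = 2, max_angle = 0)
  sh <- attr(out, "shift")
  expect_true(all(sh >= -2 & sh <= 2))
  expect_equal(out[8 + sh[1], 8 + sh[2]], 1)
  expect_equal(sum(out), 1)
})

test_that("shift + rotation matches an independent pixelwise oracle", {
  set.seed(7)
  img <- matrix(runif(21 * 21), 21, 21)
  for (rep in 1:5) {
    seed <- 100 + rep
    set.seed(seed)
    out <- random_transform(img, max_shift = 2, max_angle = 90)
    sh <- attr(out, "shift"); ang <- attr(out, "angle")
    ref <- naive_shift_rotate(img, sh[1], sh[2], ang)
    expect_equal(array(out, dim(ref)), ref, tolerance = 1e-12)
  }
})
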