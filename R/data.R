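# Dataset plumbing: IDX-format readers/writers (big-endian byte layout used
# by the fashion-MNIST distribution), class-per-subdirectory image folders,
# the stratified 80:20 split, and the translation/rotation augmenter.
#
# A dataset is a list: `images` (n x H x W x C array, 8-bit values 0..255 at
# rest), `labels` (0-based integers), `class_names` (character).

IDX_MAGIC_IMAGES3 <- 0x00000803  # n x rows x cols (grayscale)
IDX_MAGIC_IMAGES4 <- 0x00000804  # n x rows x cols x channels
IDX_MAGIC_LABELS <- 0x00000801

new_dataset <- function(images, labels, class_names = NULL) {
  stopifnot(length(dim(images)) == 4L, dim(images)[1] == length(labels))
  if (length(labels) && (min(images) < 0 || max(images) > 255)) {
    stop("at-rest image values must lie in [0, 255]")
  }
  if (is.null(class_names)) {
    class_names <- as.character(sort(unique(as.integer(labels))))
  }
  structure(list(images = images, labels = as.integer(labels),
                 class_names = class_names),
            class = "image_dataset")
}

#' @export
print.image_dataset <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("image dataset: %d images of %dx%dx%d, %d classes\n",
              d[1], d[2], d[3], d[4], length(x$class_names)))
  invisible(x)
}

#' Read an IDX image/label file pair
#'
#' Parses the big-endian IDX byte layout: a 4-byte magic number (0x803 for
#' 3-D image tensors, 0x804 for 4-D, 0x801 for label vectors), one 4-byte
#' big-endian size per dimension, then unsigned bytes.
#'
#' @param image_file,label_file file paths.
#' @return An image dataset (grayscale files yield C = 1).
#' @export
load_idx <- function(image_file, label_file) {
  img <- read_idx_file(image_file)
  if (!img$magic %in% c(IDX_MAGIC_IMAGES3, IDX_MAGIC_IMAGES4)) {
    stop(sprintf("bad IDX image magic 0x%08x in %s", img$magic, image_file))
  }
  lab <- read_idx_file(label_file)
  if (lab$magic != IDX_MAGIC_LABELS) {
    stop(sprintf("bad IDX label magic 0x%08x in %s", lab$magic, label_file))
  }
  dims <- img$dims
  if (length(dims) == 3L) dims <- c(dims, 1L)
  if (dims[1] != lab$dims[1]) {
    stop(sprintf("image count %d does not match label count %d", dims[1], lab$dims[1]))
  }
  # IDX stores row-major: dims (n, H, W[, C]) with the last index fastest
  arr <- aperm(array(img$data, dim = rev(dims)), rev(seq_along(dims)))
  new_dataset(arr, lab$data)
}

read_idx_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  ndim <- bitwAnd(magic, 0xFF)
  dims <- readBin(con, "integer", ndim, size = 4, endian = "big")
  n <- prod(dims)
  data <- readBin(con, "integer", n, size = 1, signed = FALSE)
  if (length(data) < n) stop("truncated IDX payload in ", path)
  list(magic = magic, dims = dims, data = data)
}

#' Write an IDX image/label file pair
#'
#' @param ds an image dataset.
#' @param image_file,label_file output paths.  Datasets with C = 1 are
#'   written as 3-D IDX (magic 0x803), otherwise 4-D (0x804).
#' @return Invisibly, the two paths.
#' @export
write_idx <- function(ds, image_file, label_file) {
  d <- dim(ds$images)
  gray <- d[4] == 1L
  dims <- if (gray) d[1:3] else d
  magic <- if (gray) IDX_MAGIC_IMAGES3 else IDX_MAGIC_IMAGES4
  con <- file(image_file, "wb")
  writeBin(as.integer(magic), con, size = 4, endian = "big")
  writeBin(as.integer(dims), con, size = 4, endian = "big")
  arr <- if (gray) array(ds$images, d[1:3]) else ds$images
  # row-major byte order: last index fastest
  writeBin(as.integer(aperm(arr, rev(seq_along(dims)))), con, size = 1)
  close(con)
  con <- file(label_file, "wb")
  writeBin(as.integer(IDX_MAGIC_LABELS), con, size = 4, endian = "big")
  writeBin(length(ds$labels), con, size = 4, endian = "big")
  writeBin(as.integer(ds$labels), con, size = 1)
  close(con)
  invisible(c(image_file, label_file))
}

#' Load a class-per-subdirectory image folder
#'
#' Each subdirectory of `root` is one class; the class index is the sorted
#' subdirectory order.  Images are decoded with EBImage and resized to
#' `shape` with bilinear interpolation.  Undecodable files are skipped with a
#' warning.
#'
#' @param root dataset root directory.
#' @param shape target c(H, W, C); C = 3 keeps/expands to RGB, C = 1
#'   converts to grayscale.
#' @return An image dataset with `class_names` = the subdirectory names.
#' @export
load_image_folder <- function(root, shape = c(32L, 32L, 3L)) {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    stop("load_image_folder() needs the EBImage package")
  }
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0L) stop("no class subdirectories under ", root)
  images <- list(); labels <- integer(0); skipped <- 0L
  for (k in seq_along(classes)) {
    files <- sort(list.files(file.path(root, classes[k]), full.names = TRUE))
    for (f in files) {
      img <- tryCatch(EBImage::readImage(f), error = function(e) NULL)
      if (is.null(img)) {
        warning("skipping undecodable file: ", f)
        skipped <- skipped + 1L
        next
      }
      images[[length(images) + 1L]] <- decode_to_shape(img, shape)
      labels <- c(labels, k - 1L)
    }
  }
  if (length(images) == 0L) stop("no decodable images under ", root)
  arr <- array(0, dim = c(length(images), shape))
  for (i in seq_along(images)) arr[i, , , ] <- images[[i]]
  ds <- new_dataset(arr, labels, class_names = classes)
  attr(ds, "skipped") <- skipped
  ds
}

# EBImage gives (W, H[, C]) in [0,1]; return (H, W, C) 0..255.
decode_to_shape <- function(img, shape) {
  data <- EBImage::imageData(img)
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  nc <- dim(data)[3]
  if (shape[3] == 3L && nc == 1L) data <- array(rep(data, 3), c(dim(data)[1:2], 3L))
  if (shape[3] == 1L && nc >= 3L) {
    data <- array(0.299 * data[, , 1] + 0.587 * data[, , 2] + 0.114 * data[, , 3],
                  c(dim(data)[1:2], 1L))
  }
  if (dim(data)[3] > shape[3]) data <- data[, , seq_len(shape[3]), drop = FALSE]
  resized <- EBImage::resize(EBImage::Image(data, colormode = "Color"),
                             w = shape[2], h = shape[1])
  out <- EBImage::imageData(resized)
  if (length(dim(out)) == 2L) dim(out) <- c(dim(out), 1L)
  aperm(array(out[, , seq_len(shape[3])], c(shape[2], shape[1], shape[3])),
        c(2, 1, 3)) * 255
}

#' Stratified 80:20 split
#'
#' Per class, `max(1, floor(n_k / 5))` samples go to validation and the rest
#' to training; the assignment is a deterministic function of the seed and
#' the two index sets are disjoint and exhaustive.
#'
#' @param ds an image dataset; every class must have at least 2 samples.
#' @param seed integer seed.
#' @return A list with `train` and `val` datasets and the index vectors
#'   `train_idx`, `val_idx`.
#' @export
split_80_20 <- function(ds, seed = 0L) {
  labels <- ds$labels
  tab <- table(labels)
  if (any(tab < 2L)) {
    stop("every class needs at least 2 samples; offending class(es): ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  }
  set.seed(seed)
  val_idx <- integer(0)
  for (cl in as.integer(names(tab))) {
    idx <- which(labels == cl)
    n_val <- max(1L, length(idx) %/% 5L)
    val_idx <- c(val_idx, sample(idx, n_val))
  }
  val_idx <- sort(val_idx)
  train_idx <- setdiff(seq_along(labels), val_idx)
  subset_ds <- function(i) {
    new_dataset(ds$images[i, , , , drop = FALSE], ds$labels[i], ds$class_names)
  }
  list(train = subset_ds(train_idx), val = subset_ds(val_idx),
       train_idx = train_idx, val_idx = val_idx)
}

#' Random translation + rotation augmentation
#'
#' Draws an integer shift uniformly from `[-max_shift, max_shift]` per axis
#' and a rotation angle uniformly from `[-max_angle, max_angle]` degrees,
#' shifts the image (zero fill), then rotates it about the image center
#' (bilinear interpolation, zero fill outside the canvas).  The augmentation
#' tuple notation (t, theta) corresponds to `(max_shift, max_angle)`; the
#' tuple (0, 0) is the identity.
#'
#' @param image an H x W x C array (or H x W matrix).
#' @param max_shift maximum absolute shift in pixels (>= 0).
#' @param max_angle maximum absolute rotation in degrees (>= 0).
#' @return The transformed image, same shape; the drawn `shift` (dy, dx) and
#'   `angle` are attached as attributes.
#' @export
random_transform <- function(image, max_shift = 2, max_angle = 180) {
  stopifnot(max_shift >= 0, max_angle >= 0)
  was_mat <- is.matrix(image)
  if (was_mat) dim(image) <- c(dim(image), 1L)
  dy <- if (max_shift > 0) sample(seq.int(-max_shift, max_shift), 1L) else 0L
  dx <- if (max_shift > 0) sample(seq.int(-max_shift, max_shift), 1L) else 0L
  theta <- if (max_angle > 0) stats::runif(1, -max_angle, max_angle) else 0
  out <- shift_image(image, dy, dx)
  if (theta != 0) out <- rotate_image(out, theta)
  if (was_mat) dim(out) <- dim(out)[1:2]
  attr(out, "shift") <- c(dy, dx)
  attr(out, "angle") <- theta
  out
}

# out[i, j] = in[i - dy, j - dx], zero fill
shift_image <- function(image, dy, dx) {
  d <- dim(image)
  out <- array(0, d)
  src_i <- seq_len(d[1]) - dy
  src_j <- seq_len(d[2]) - dx
  ok_i <- src_i >= 1L & src_i <= d[1]
  ok_j <- src_j >= 1L & src_j <= d[2]
  out[which(ok_i), which(ok_j), ] <- image[src_i[ok_i], src_j[ok_j], , drop = FALSE]
  out
}

# Rotation by `theta` degrees about the image center: each output pixel is
# bilinearly sampled at the inverse-rotated source location, zero outside.
rotate_image <- function(image, theta) {
  d <- dim(image)
  rad <- theta * pi / 180
  cy <- (d[1] + 1) / 2
  cx <- (d[2] + 1) / 2
  gi <- matrix(seq_len(d[1]), d[1], d[2])
  gj <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  # inverse map: rotate output coordinates by -theta
  si <- cy + cos(rad) * (gi - cy) + sin(rad) * (gj - cx)
  sj <- cx - sin(rad) * (gi - cy) + cos(rad) * (gj - cx)
  i0 <- floor(si); j0 <- floor(sj)
  fi <- si - i0; fj <- sj - j0
  out <- array(0, d)
  sample_at <- function(ii, jj) {
    ok <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2]
    ii2 <- pmin(pmax(ii, 1L), d[1])
    jj2 <- pmin(pmax(jj, 1L), d[2])
    idx <- cbind(as.vector(ii2), as.vector(jj2))
    vals <- matrix(0, d[1] * d[2], d[3])
    for (ch in seq_len(d[3])) {
      v <- image[, , ch][idx]
      v[!as.vector(ok)] <- 0
      vals[, ch] <- v
    }
    vals
  }
  w00 <- as.vector((1 - fi) * (1 - fj))
  w01 <- as.vector((1 - fi) * fj)
  w10 <- as.vector(fi * (1 - fj))
  w11 <- as.vector(fi * fj)
  acc <- w00 * sample_at(i0, j0) + w01 * sample_at(i0, j0 + 1) +
    w10 * sample_at(i0 + 1, j0) + w11 * sample_at(i0 + 1, j0 + 1)
  array(acc, d)
}
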