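# Synthetic multi-class textured images (32x32x3) whose class archetypes are
# texture families with abundant equal-valued pixel runs, so the 2x2 texton
# detector fires informatively: stripes (horizontal / vertical / diagonal),
# checkerboards, and -- for the 10-class variant -- blobs, rings, axis
# gradients, block speckle, dot lattices and crosses.  Per-sample colors,
# phases and stripe widths are randomized; a fraction of pixels can be
# replaced by uniform noise.  Everything is driven by one seed.

SYNTH_CLASSES <- c("hstripe", "vstripe", "dstripe", "checker", "blob", "ring",
                   "gradient", "speckle", "dots", "cross")

#' Generate a synthetic textured dataset
#'
#' Balanced classes, 32 x 32 x 3 images with 8-bit values, fully determined
#' by `seed`.  With 2 classes the archetypes are horizontal/vertical stripes;
#' with 4, stripes in two orientations, diagonal stripes and checkerboard;
#' with 10, six further texture families are added.  Each image gets two
#' random colors, a random stripe width (2-5 px) and phase; `noise_frac` of
#' its pixels are then replaced by uniform noise.
#'
#' @param n number of images (>= n_classes).
#' @param n_classes 2, 4 or 10.
#' @param seed integer seed.
#' @param noise_frac fraction of pixels replaced by uniform noise, in
#'   `[0, 1]` (default 0.05).
#' @return An image dataset (see the data readers) with `class_names` set to
#'   the texture family names.
#' @export
synth_textured_dataset <- function(n, n_classes = 4L, seed = 0L,
                                   noise_frac = 0.05) {
  stopifnot(n_classes %in% c(2L, 4L, 10L), n >= n_classes,
            noise_frac >= 0, noise_frac <= 1)
  set.seed(seed)
  H <- 32L; W <- 32L
  labels <- rep_len(0:(n_classes - 1L), n)
  images <- array(0, dim = c(n, H, W, 3L))
  for (i in seq_len(n)) {
    images[i, , , ] <- synth_one(labels[i], H, W, noise_frac)
  }
  new_dataset(images, labels, class_names = SYNTH_CLASSES[seq_len(n_classes)])
}

# One image of the given class (0-based), values 0..255.
synth_one <- function(class0, H, W, noise_frac) {
  col_a <- sample(0:255, 3, replace = TRUE)
  col_b <- sample(0:255, 3, replace = TRUE)
  # keep the two colors separated so the pattern survives quantization
  while (max(abs(col_a - col_b)) < 64) col_b <- sample(0:255, 3, replace = TRUE)
  width <- sample(2:5, 1)
  phase <- sample(0:(2 * width - 1), 1)
  gi <- matrix(seq_len(H) - 1L, H, W)
  gj <- matrix(seq_len(W) - 1L, H, W, byrow = TRUE)
  pattern <- switch(SYNTH_CLASSES[class0 + 1],
    hstripe = ((gi + phase) %/% width) %% 2L,
    vstripe = ((gj + phase) %/% width) %% 2L,
    dstripe = ((gi + gj + phase) %/% width) %% 2L,
    checker = (((gi + phase) %/% width) + ((gj + phase) %/% width)) %% 2L,
    blob = {
      cy <- sample(8:(H - 9), 1); cx <- sample(8:(W - 9), 1)
      r <- sample(5:9, 1)
      as.integer((gi - cy)^2 + (gj - cx)^2 <= r^2)
    },
    ring = {
      cy <- H / 2; cx <- W / 2
      r <- sample(7:11, 1)
      dist2 <- (gi - cy)^2 + (gj - cx)^2
      as.integer(dist2 <= r^2 & dist2 >= (r - 3)^2)
    },
    gradient = {
      # flat bands of monotonically increasing level (plateaus, not a ramp)
      nb <- sample(4:8, 1)
      band <- pmin((gi * nb) %/% H, nb - 1L)
      return(add_noise(grad_bands(band, nb, col_a, col_b, H, W), noise_frac))
    },
    speckle = {
      blk <- sample(2:4, 1)
      cells <- matrix(sample(0:1, ceiling(H / blk) * ceiling(W / blk), replace = TRUE),
                      ceiling(H / blk))
      matrix(cells[cbind(as.vector(gi %/% blk + 1L), as.vector(gj %/% blk + 1L))], H, W)
    },
    dots = {
      pitch <- sample(4:6, 1)
      as.integer((gi %% pitch) < 2 & (gj %% pitch) < 2)
    },
    cross = {
      cy <- sample(10:(H - 11), 1); cx <- sample(10:(W - 11), 1)
      arm <- sample(3:5, 1)
      as.integer(abs(gi - cy) <= arm | abs(gj - cx) <= arm)
    }
  )
  img <- array(0, c(H, W, 3L))
  for (ch in 1:3) img[, , ch] <- ifelse(pattern == 1L, col_a[ch], col_b[ch])
  add_noise(img, noise_frac)
}

grad_bands <- function(band, nb, col_a, col_b, H, W) {
  img <- array(0, c(H, W, 3L))
  for (ch in 1:3) {
    levels_ch <- round(seq(col_a[ch], col_b[ch], length.out = nb))
    img[, , ch] <- matrix(levels_ch[band + 1L], H, W)
  }
  img
}

add_noise <- function(img, noise_frac) {
  if (noise_frac <= 0) return(img)
  d <- dim(img)
  n_pix <- d[1] * d[2]
  n_noise <- round(noise_frac * n_pix)
  if (n_noise == 0) return(img)
  pick <- sample.int(n_pix, n_noise)
  ii <- (pick - 1L) %% d[1] + 1L
  jj <- (pick - 1L) %/% d[1] + 1L
  for (ch in seq_len(d[3])) {
    img[cbind(ii, jj, ch)] <- sample(0:255, n_noise, replace = TRUE)
  }
  img
}
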