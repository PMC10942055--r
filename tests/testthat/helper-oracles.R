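# Independent reference implementations used as oracles.  These are written
# as plain nested loops, deliberately sharing no code with the package
# internals they check.

# Naive texton detector: tests all selected pairs at every anchor and ORs the
# kept 2x2 grids.
naive_detect_textons <- function(image, step = 1, textons = 1:6) {
  H <- nrow(image); W <- ncol(image)
  keep <- matrix(FALSE, H, W)
  pairs <- list(c(1, 2), c(2, 3), c(1, 3), c(1, 4), c(2, 4), c(3, 4))
  if (H >= 2 && W >= 2) {
    for (i in seq(1, H - 1, by = step)) {
      for (j in seq(1, W - 1, by = step)) {
        corners <- c(image[i, j], image[i, j + 1], image[i + 1, j], image[i + 1, j + 1])
        hit <- FALSE
        for (k in textons) {
          if (corners[pairs[[k]][1]] == corners[pairs[[k]][2]]) hit <- TRUE
        }
        if (hit) {
          keep[i, j] <- keep[i, j + 1] <- keep[i + 1, j] <- keep[i + 1, j + 1] <- TRUE
        }
      }
    }
  }
  list(values = image * keep, mask = keep)
}

# Loop transcription of the routing procedure: softmax over upper capsules,
# weighted vote sums, squash, in-loop agreement update.
naive_routing <- function(votes, r) {
  N <- dim(votes)[1]; J <- dim(votes)[2]; D <- dim(votes)[3]
  b <- matrix(0, N, J)
  sq <- function(s) {
    n2 <- sum(s^2)
    s * (n2 / (1 + n2)) / sqrt(n2 + 1e-9)
  }
  v <- matrix(0, J, D)
  cc <- matrix(0, N, J)
  for (it in seq_len(r)) {
    for (i in seq_len(N)) cc[i, ] <- exp(b[i, ]) / sum(exp(b[i, ]))
    for (j in seq_len(J)) {
      s <- numeric(D)
      for (i in seq_len(N)) s <- s + cc[i, j] * votes[i, j, ]
      v[j, ] <- sq(s)
    }
    for (i in seq_len(N)) {
      for (j in seq_len(J)) b[i, j] <- b[i, j] + sum(v[j, ] * votes[i, j, ])
    }
  }
  list(v = v, couplings = cc, logits = b)
}

# Independent shift + rotate oracle (nearest math re-derived by hand, zero
# fill, bilinear sampling) for a single-channel image.
naive_shift_rotate <- function(img, dy, dx, theta_deg) {
  H <- nrow(img); W <- ncol(img)
  shifted <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      si <- i - dy; sj <- j - dx
      if (si >= 1 && si <= H && sj >= 1 && sj <= W) shifted[i, j] <- img[si, sj]
    }
  }
  if (theta_deg == 0) return(shifted)
  rad <- theta_deg * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  out <- matrix(0, H, W)
  at <- function(ii, jj) {
    if (ii < 1 || ii > H || jj < 1 || jj > W) 0 else shifted[ii, jj]
  }
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      si <- cy + cos(rad) * (i - cy) + sin(rad) * (j - cx)
      sj <- cx - sin(rad) * (i - cy) + cos(rad) * (j - cx)
      i0 <- floor(si); j0 <- floor(sj)
      fi <- si - i0; fj <- sj - j0
      out[i, j] <- (1 - fi) * (1 - fj) * at(i0, j0) +
        (1 - fi) * fj * at(i0, j0 + 1) +
        fi * (1 - fj) * at(i0 + 1, j0) +
        fi * fj * at(i0 + 1, j0 + 1)
    }
  }
  out
}

# Tiny model configuration that exercises all three levels quickly.
toy_model_config <- function(n_classes = 3L, input = c(21L, 21L, 1L)) {
  capsnet_config(
    input_shape = input, n_classes = n_classes, preset = "small",
    pc = list(n_types = 2L, dim = 4L, kernels = c(5L, 5L, 3L), strides = c(2L, 2L, 2L)),
    dense = dense_block_config(1L, 2L, 3L),
    heads = c(4L, 4L, 4L, 4L), routing = 2L,
    texton = list(enabled = TRUE, levels = 8L, step = 1L, textons = 1:6),
    decoder = c(8L, 8L, 16L)
  )
}

random_toy_batch <- function(B, input = c(21L, 21L, 1L)) {
  array(runif(B * prod(input)), c(B, input))
}
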