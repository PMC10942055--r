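# Densely connected convolution block: each layer consumes the concatenation
# of the block input and all previous layers' outputs, and contributes
# `growth` new channels at unchanged spatial size (3x3 same-padded
# convolutions, pre-activation ordering: batch norm -> ReLU -> conv).

#' Dense block configuration
#'
#' @param n_layers number of convolution layers in the block (default 8).
#' @param growth channels added per layer (default 32; the printed channel
#'   arithmetic of the full model, 3 + 8*32 = 259 and 96 + 8*32 = 352,
#'   requires this value).
#' @param kernel convolution kernel size (default 3, same-padded).
#' @return A list of class `dense_block_config`.
#' @export
dense_block_config <- function(n_layers = 8L, growth = 32L, kernel = 3L) {
  stopifnot(n_layers >= 0L, growth >= 0L, kernel >= 1L, kernel %% 2L == 1L)
  structure(list(n_layers = as.integer(n_layers), growth = as.integer(growth),
                 kernel = as.integer(kernel)),
            class = "dense_block_config")
}

dense_block_init <- function(cfg, c_in) {
  layers <- vector("list", cfg$n_layers)
  for (t in seq_len(cfg$n_layers)) {
    ct <- c_in + (t - 1L) * cfg$growth
    layers[[t]] <- list(
      gamma = rep(1, ct),
      beta = rep(0, ct),
      w = array(stats::rnorm(cfg$kernel^2 * ct * cfg$growth,
                             sd = sqrt(2 / (cfg$kernel^2 * ct))),
                dim = c(cfg$kernel, cfg$kernel, ct, cfg$growth)),
      b = rep(0, cfg$growth)
    )
  }
  layers
}

dense_block_state_init <- function(cfg, c_in) {
  lapply(seq_len(cfg$n_layers), function(t) {
    ct <- c_in + (t - 1L) * cfg$growth
    list(mean = rep(0, ct), var = rep(1, ct))
  })
}

# x: (B, H, W, C).  Returns list(out (B, H, W, C + n_layers*growth), state,
# cache).  The first C output channels are the input unchanged.
dense_block_forward_batch <- function(x, cfg, params, state, training = FALSE,
                                      keep_cache = FALSE) {
  d <- dim(x)
  pad <- (cfg$kernel - 1L) %/% 2L
  c_out <- d[4] + cfg$n_layers * cfg$growth
  out <- array(0, dim = c(d[1], d[2], d[3], c_out))
  out[, , , seq_len(d[4])] <- x
  caches <- if (keep_cache) vector("list", cfg$n_layers) else NULL
  for (t in seq_len(cfg$n_layers)) {
    ct <- d[4] + (t - 1L) * cfg$growth
    ht <- out[, , , seq_len(ct), drop = FALSE]
    bn <- batchnorm_forward(ht, params[[t]]$gamma, params[[t]]$beta,
                            state[[t]], training = training,
                            keep_cache = keep_cache)
    state[[t]] <- bn$state
    rl <- relu_forward(bn$out)
    cv <- conv2d_forward(rl$out, params[[t]]$w, params[[t]]$b,
                         stride = 1L, pad = pad, keep_cache = keep_cache)
    out[, , , ct + seq_len(cfg$growth)] <- cv$out
    if (keep_cache) caches[[t]] <- list(bn = bn$cache, relu = rl$mask, conv = cv$cache)
  }
  list(out = out, state = state, cache = caches)
}

# dout: gradient wrt the full concatenated output.  Returns list(dx, grads)
# where grads parallels the params list.
dense_block_backward_batch <- function(dout, cfg, params, caches, c_in) {
  grads <- vector("list", cfg$n_layers)
  dacc <- dout
  for (t in rev(seq_len(cfg$n_layers))) {
    ct <- c_in + (t - 1L) * cfg$growth
    dnew <- dacc[, , , ct + seq_len(cfg$growth), drop = FALSE]
    cb <- conv2d_backward(dnew, caches[[t]]$conv)
    drl <- relu_backward(cb$dx, caches[[t]]$relu)
    bb <- batchnorm_backward(drl, caches[[t]]$bn)
    grads[[t]] <- list(gamma = bb$dgamma, beta = bb$dbeta, w = cb$dw, b = cb$db)
    dacc <- dacc[, , , seq_len(ct), drop = FALSE]
    dacc <- dacc + bb$dx
  }
  list(dx = dacc, grads = grads)
}

#' Dense block forward pass (single feature map)
#'
#' Runs a densely connected convolution block on one H x W x C feature map.
#' Layer `t` consumes the concatenation of the input and all previous layers'
#' outputs (batch norm, ReLU, then a same-padded convolution adding `growth`
#' channels); the output concatenates the unchanged input with all layers'
#' outputs, giving `C + n_layers * growth` channels at unchanged spatial size.
#'
#' @param x an H x W x C numeric array (or a matrix, taken as C = 1).
#' @param cfg a [dense_block_config()].
#' @param params optional parameter list from an internal initializer; fresh
#'   random parameters are drawn when omitted.
#' @param training logical; use batch statistics (TRUE) or running statistics
#'   in the normalization layers.
#' @return An H x W x (C + n_layers*growth) array.
#' @export
dense_block_forward <- function(x, cfg = dense_block_config(), params = NULL,
                                training = TRUE) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (is.null(params)) params <- dense_block_init(cfg, d[3])
  state <- dense_block_state_init(cfg, d[3])
  xb <- aperm(array(x, c(d, 1L)), c(4, 1, 2, 3))
  res <- dense_block_forward_batch(xb, cfg, params, state, training = training)
  array(res$out[1, , , ], dim(res$out)[2:4])
}
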