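# The three-level texton-dense capsule network.
#
# Each level applies: texton layer -> dense convolution block -> primary
# capsule convolution (squashed).  The squashed primary-capsule tensor,
# re-laid-out as a feature map, feeds the next level.  Four class-capsule
# heads are routed: head 1 from the concatenation of all three primary
# capsule sets, heads 2-4 from the individual levels.  At test time the four
# heads' class capsules are concatenated (54D under the default head widths)
# and the concatenated length is the class score.  A four-layer fully
# connected decoder reconstructs the input from the selected class's
# concatenated capsule.

#' Model configuration
#'
#' Collects every architectural hyperparameter of the three-level
#' texton-dense capsule network.  The `"full"` preset reproduces the printed
#' architecture for 32x32 inputs: dense blocks of 8 layers with growth 32
#' (so 3 + 8*32 = 259 channels after block 1 and 96 + 8*32 = 352 after
#' blocks 2 and 3), primary capsules of 12 types x 8D with kernels 5/5/3 and
#' stride 2 (spatial chain 32 -> 14 -> 5 -> 2), head widths 16/16/12/10
#' (54D concatenated capsules) and decoder widths 512/512/1024/(H*W*C).  The
#' `"small"` preset is a reduced architecture of identical topology used for
#' fast CPU training experiments.
#'
#' @param input_shape c(H, W, C); C must be 1 or 3.
#' @param n_classes number of classes.
#' @param preset `"full"` or `"small"`.
#' @param pc list(n_types, dim, kernels, strides) for the three primary
#'   capsule convolutions.
#' @param dense a [dense_block_config()] shared by the three blocks.
#' @param heads integer widths of the four class-capsule heads
#'   (combined head first).
#' @param routing number of routing iterations.
#' @param texton list(enabled, levels, step, textons) for the in-network
#'   texton layers (per-channel uniform quantization to `levels` bins before
#'   detection).
#' @param decoder widths of the first three decoder layers; the final layer
#'   width is always H*W*C.
#' @param loss list(m_plus, m_minus, lambda, alpha): margin-loss constants
#'   and the reconstruction weight.
#' @return A list of class `capsnet_config`.
#' @export
capsnet_config <- function(input_shape = c(32L, 32L, 3L),
                           n_classes = 4L,
                           preset = c("full", "small"),
                           pc = NULL, dense = NULL, heads = NULL,
                           routing = 3L, texton = NULL, decoder = NULL,
                           loss = NULL) {
  preset <- match.arg(preset)
  def <- if (preset == "full") {
    list(pc = list(n_types = 12L, dim = 8L, kernels = c(5L, 5L, 3L),
                   strides = c(2L, 2L, 2L)),
         dense = dense_block_config(8L, 32L, 3L),
         heads = c(16L, 16L, 12L, 10L),
         texton = list(enabled = TRUE, levels = 256L, step = 1L, textons = 1:6),
         decoder = c(512L, 512L, 1024L))
  } else {
    list(pc = list(n_types = 4L, dim = 8L, kernels = c(5L, 5L, 3L),
                   strides = c(2L, 2L, 2L)),
         dense = dense_block_config(2L, 8L, 3L),
         heads = c(8L, 8L, 8L, 8L),
         texton = list(enabled = TRUE, levels = 16L, step = 1L, textons = 1:6),
         decoder = c(128L, 128L, 256L))
  }
  cfg <- list(
    input_shape = as.integer(input_shape),
    n_classes = as.integer(n_classes),
    preset = preset,
    pc = pc %||% def$pc,
    dense = dense %||% def$dense,
    heads = as.integer(heads %||% def$heads),
    routing = as.integer(routing),
    texton = texton %||% def$texton,
    decoder = as.integer(decoder %||% def$decoder),
    loss = loss %||% list(m_plus = 0.9, m_minus = 0.1, lambda = 0.5, alpha = 5e-4)
  )
  stopifnot(length(cfg$input_shape) == 3L, cfg$input_shape[3] %in% c(1L, 3L),
            cfg$n_classes >= 2L, length(cfg$heads) == 4L, cfg$routing >= 1L,
            length(cfg$pc$kernels) == 3L, length(cfg$pc$strides) == 3L,
            length(cfg$decoder) == 3L)
  cfg$shapes <- capsnet_shapes(cfg)
  class(cfg) <- "capsnet_config"
  cfg
}

# Static shape chain: per level the dense-block output channels, the
# primary-capsule grid and the capsule count.
capsnet_shapes <- function(cfg) {
  H <- cfg$input_shape[1]; W <- cfg$input_shape[2]; C <- cfg$input_shape[3]
  pc_ch <- cfg$pc$n_types * cfg$pc$dim
  levels <- vector("list", 3L)
  for (l in 1:3) {
    dense_out <- C + cfg$dense$n_layers * cfg$dense$growth
    k <- cfg$pc$kernels[l]; s <- cfg$pc$strides[l]
    if (k > H || k > W) stop(sprintf("level %d kernel %d exceeds input %dx%d", l, k, H, W))
    Ho <- (H - k) %/% s + 1L
    Wo <- (W - k) %/% s + 1L
    levels[[l]] <- list(in_shape = c(H, W, C), dense_channels = dense_out,
                        grid = c(Ho, Wo, cfg$pc$n_types),
                        n_caps = Ho * Wo * cfg$pc$n_types, pc_channels = pc_ch)
    H <- Ho; W <- Wo; C <- pc_ch
  }
  n_caps <- vapply(levels, function(x) x$n_caps, numeric(1))
  list(levels = levels, n_lower = c(sum(n_caps), n_caps),
       concat_dim = sum(cfg$heads),
       decoder_out = prod(cfg$input_shape))
}

#' Build a capsule network model
#'
#' Initializes all trainable parameters: dense-block batch-norm and
#' convolution parameters (He-scaled normal), primary-capsule convolutions,
#' routing transformation matrices W_ij (normal, sd 0.01), and the decoder.
#'
#' @param cfg a [capsnet_config()].
#' @param seed optional integer seed for reproducible initialization.
#' @return A list of class `capsnet_model` with elements `config`, `params`,
#'   `state` (batch-norm running statistics), and `shapes`.
#' @export
capsnet_build <- function(cfg = capsnet_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sh <- cfg$shapes
  J <- cfg$n_classes
  pc_ch <- cfg$pc$n_types * cfg$pc$dim
  levels <- vector("list", 3L)
  state <- vector("list", 3L)
  for (l in 1:3) {
    ls <- sh$levels[[l]]
    c_in <- ls$in_shape[3]
    k <- cfg$pc$kernels[l]
    levels[[l]] <- list(
      dense = dense_block_init(cfg$dense, c_in),
      pc = list(
        w = array(stats::rnorm(k^2 * ls$dense_channels * pc_ch,
                               sd = sqrt(2 / (k^2 * ls$dense_channels))),
                  dim = c(k, k, ls$dense_channels, pc_ch)),
        b = rep(0, pc_ch)
      )
    )
    state[[l]] <- dense_block_state_init(cfg$dense, c_in)
  }
  heads <- lapply(1:4, function(h) {
    N <- sh$n_lower[h]
    list(w = array(stats::rnorm(N * J * cfg$pc$dim * cfg$heads[h], sd = 0.01),
                   dim = c(N, J, cfg$pc$dim, cfg$heads[h])))
  })
  dwidths <- cfg$decoder
  din <- sh$concat_dim
  he <- function(n_in, n_out) {
    list(w = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
         b = rep(0, n_out))
  }
  decoder <- list(
    fc1 = he(din, dwidths[1]),
    fc2 = he(dwidths[1], dwidths[2]),
    fc3 = he(dwidths[1] + dwidths[2], dwidths[3]),
    fc4 = he(dwidths[3], sh$decoder_out)
  )
  structure(list(config = cfg,
                 params = list(levels = levels, heads = heads, decoder = decoder),
                 state = state,
                 shapes = sh),
            class = "capsnet_model")
}

#' @export
print.capsnet_model <- function(x, ...) {
  cat(sprintf("capsule network (%s preset): %dx%dx%d input, %d classes, %s-D heads\n",
              x$config$preset, x$config$input_shape[1], x$config$input_shape[2],
              x$config$input_shape[3], x$config$n_classes,
              paste(x$config$heads, collapse = "/")))
  cat(sprintf("  %d trainable parameters\n", count_parameters(x)))
  invisible(x)
}

# ---- class-capsule heads (batched) ----------------------------------------

# u: (N, B, Din); w: (N, J, Din, Dout).  Votes are stored as an (N*B, J*Dout)
# matrix with rows (i, b), i fastest, and columns (j, d), j fastest.
head_forward <- function(u, w, r, keep_cache = FALSE) {
  N <- dim(u)[1]; B <- dim(u)[2]; Din <- dim(u)[3]
  J <- dim(w)[2]; Dout <- dim(w)[4]
  JD <- J * Dout
  ridx <- rep(seq_len(N), times = B)
  votes <- matrix(0, N * B, JD)
  for (d_in in seq_len(Din)) {
    wd <- matrix(w[, , d_in, ], N, JD)
    votes <- votes + as.vector(u[, , d_in]) * wd[ridx, , drop = FALSE]
  }
  b0 <- matrix(0, N * B, J)
  jrep <- rep(seq_len(J), times = Dout)
  v_rows <- s_rows <- NULL
  cc <- NULL
  for (it in seq_len(r)) {
    cc <- softmax_rows(b0)
    weighted <- votes * cc[, jrep, drop = FALSE]
    dim(weighted) <- c(N, B * JD)
    s_m <- matrix(colSums(weighted), B, JD)
    s_rows <- s_m
    dim(s_rows) <- c(B * J, Dout)
    v_rows <- squash(s_rows)
    v_m <- v_rows
    dim(v_m) <- c(B, JD)
    b0 <- b0 + agreement(votes, NULL, N * B, J, Dout,
                         vexp = v_m[rep(seq_len(B), each = N), , drop = FALSE])
  }
  len <- matrix(sqrt(rowSums(v_rows * v_rows)), B, J)
  v_arr <- array(v_rows, c(B, J, Dout))
  cache <- NULL
  if (keep_cache) cache <- list(votes = votes, cc = cc, s_rows = s_rows,
                                u = u, dims = c(N, B, Din, J, Dout))
  list(v = v_arr, lengths = len, cache = cache)
}

# dv_rows: (B*J, Dout) gradient wrt the squashed head output.  Coupling
# coefficients are treated as constants of the backward pass.
head_backward <- function(dv_rows, cache, w) {
  dm <- cache$dims
  N <- dm[1]; B <- dm[2]; Din <- dm[3]; J <- dm[4]; Dout <- dm[5]
  JD <- J * Dout
  ds_rows <- squash_backward(cache$s_rows, dv_rows)
  ds_m <- ds_rows
  dim(ds_m) <- c(B, JD)
  jrep <- rep(seq_len(J), times = Dout)
  dvotes <- cache$cc[, jrep, drop = FALSE] * ds_m[rep(seq_len(B), each = N), , drop = FALSE]
  ridx <- rep(seq_len(N), times = B)
  dw <- array(0, dim = c(N, J, Din, Dout))
  du <- array(0, dim = c(N, B, Din))
  for (d_in in seq_len(Din)) {
    u_vec <- as.vector(cache$u[, , d_in])
    dw[, , d_in, ] <- array(rowsum(dvotes * u_vec, ridx, reorder = TRUE),
                            c(N, J, Dout))
    wd <- matrix(w[, , d_in, ], N, JD)
    du[, , d_in] <- matrix(rowSums(dvotes * wd[ridx, , drop = FALSE]), N, B)
  }
  list(dw = dw, du = du)
}

# ---- forward / backward ----------------------------------------------------

# Reshape a primary-capsule conv output (B, Ho, Wo, n_types*dim) into capsule
# rows (N*B, dim) with capsule index i over (h, w, type), i fastest in rows.
pc_to_caps <- function(conv_out, n_types, cdim) {
  d <- dim(conv_out)
  arr <- array(conv_out, c(d[1], d[2], d[3], cdim, n_types))
  arr <- aperm(arr, c(2, 3, 5, 1, 4))  # (Ho, Wo, type, B, dim)
  matrix(arr, d[2] * d[3] * n_types * d[1], cdim)
}

caps_to_pc <- function(caps_rows, B, Ho, Wo, n_types, cdim) {
  arr <- array(caps_rows, c(Ho, Wo, n_types, B, cdim))
  arr <- aperm(arr, c(4, 1, 2, 5, 3))  # (B, Ho, Wo, dim, type)
  array(arr, c(B, Ho, Wo, cdim * n_types))
}

#' Forward pass
#'
#' Runs a batch through the network.  When `mask_labels` is given (training),
#' the decoder reconstructs from the true class's concatenated capsule;
#' otherwise from the argmax class.
#'
#' @param model a [capsnet_build()] model.
#' @param x input batch: a (B, H, W, C) array (or a single H x W x C image),
#'   values in `[0, 1]`.
#' @param mask_labels optional B x n_classes one-hot matrix.
#' @param training logical; batch-norm uses batch statistics and running
#'   statistics are updated.
#' @param keep_cache keep intermediate activations for a backward pass.
#' @return A list: `head_caps` (four (B, n_classes, D_h) arrays),
#'   `head_lengths` (four B x n_classes matrices), `concat_caps`
#'   (B x n_classes x sum(heads)), `scores` (B x n_classes concatenated
#'   capsule lengths), `reconstruction` (B x H*W*C), `shapes` (per-stage
#'   dimension trace), `state` (updated batch-norm state), and `cache`.
#' @export
capsnet_forward <- function(model, x, mask_labels = NULL, training = FALSE,
                            keep_cache = FALSE) {
  cfg <- model$config
  if (length(dim(x)) == 3L) x <- aperm(array(x, c(dim(x), 1L)), c(4, 1, 2, 3))
  d <- dim(x)
  if (!all(d[2:4] == cfg$input_shape)) {
    stop(sprintf("input shape %s does not match configured %s",
                 paste(d[2:4], collapse = "x"),
                 paste(cfg$input_shape, collapse = "x")))
  }
  if (min(x) < -1e-8 || max(x) > 1 + 1e-8) stop("input values must lie in [0, 1]")
  B <- d[1]
  J <- cfg$n_classes
  cdim <- cfg$pc$dim
  state <- model$state
  shapes <- list()
  level_caches <- vector("list", 3L)
  u_levels <- vector("list", 3L)
  cur <- x
  for (l in 1:3) {
    lc <- list()
    if (isTRUE(cfg$texton$enabled)) {
      mask <- texton_mask_batch(cur, levels = cfg$texton$levels,
                                step = cfg$texton$step,
                                textons = cfg$texton$textons)
      cur <- cur * mask
      if (keep_cache) lc$tex_mask <- mask
    }
    db <- dense_block_forward_batch(cur, cfg$dense, model$params$levels[[l]]$dense,
                                    state[[l]], training = training,
                                    keep_cache = keep_cache)
    state[[l]] <- db$state
    lc$dense <- db$cache
    lc$c_in <- dim(cur)[4]
    shapes[[paste0("block", l)]] <- dim(db$out)[2:4]
    cv <- conv2d_forward(db$out, model$params$levels[[l]]$pc$w,
                         model$params$levels[[l]]$pc$b,
                         stride = cfg$pc$strides[l], pad = 0L,
                         keep_cache = keep_cache)
    lc$pc_conv <- cv$cache
    od <- dim(cv$out)
    s_rows <- pc_to_caps(cv$out, cfg$pc$n_types, cdim)
    u_rows <- squash(s_rows)
    if (keep_cache) lc$pc_s <- s_rows
    lc$grid <- od
    u_levels[[l]] <- array(u_rows, c(od[2] * od[3] * cfg$pc$n_types, B, cdim))
    cur <- caps_to_pc(u_rows, B, od[2], od[3], cfg$pc$n_types, cdim)
    shapes[[paste0("pc", l)]] <- dim(cur)[2:4]
    level_caches[[l]] <- lc
  }
  # combined lower-capsule set for the first head
  n_low <- model$shapes$n_lower
  u0 <- array(0, dim = c(n_low[1], B, cdim))
  off <- 0L
  for (l in 1:3) {
    u0[off + seq_len(n_low[l + 1]), , ] <- u_levels[[l]]
    off <- off + n_low[l + 1]
  }
  lower <- c(list(u0), u_levels)
  head_out <- vector("list", 4L)
  for (h in 1:4) {
    head_out[[h]] <- head_forward(lower[[h]], model$params$heads[[h]]$w,
                                  cfg$routing, keep_cache = keep_cache)
  }
  head_caps <- lapply(head_out, `[[`, "v")
  head_lengths <- lapply(head_out, `[[`, "lengths")
  concat_dim <- model$shapes$concat_dim
  concat_caps <- array(0, dim = c(B, J, concat_dim))
  off <- 0L
  for (h in 1:4) {
    concat_caps[, , off + seq_len(cfg$heads[h])] <- head_caps[[h]]
    off <- off + cfg$heads[h]
  }
  scores <- sqrt(Reduce(`+`, lapply(head_lengths, function(l) l * l)))
  if (!is.null(mask_labels)) {
    stopifnot(all(dim(mask_labels) == c(B, J)))
    sel <- max.col(mask_labels, ties.method = "first")
  } else {
    sel <- max.col(scores, ties.method = "first")
  }
  vec_in <- matrix(0, B, concat_dim)
  for (dd in seq_len(concat_dim)) {
    vec_in[, dd] <- concat_caps[cbind(seq_len(B), sel, rep(dd, B))]
  }
  dec <- decoder_forward(vec_in, model$params$decoder, keep_cache = keep_cache)
  out <- list(head_caps = head_caps, head_lengths = head_lengths,
              concat_caps = concat_caps, scores = scores,
              reconstruction = dec$out, selected = sel, shapes = shapes,
              state = state)
  if (keep_cache) {
    out$cache <- list(levels = level_caches, heads = lapply(head_out, `[[`, "cache"),
                      decoder = dec$cache, vec_in = vec_in, sel = sel, x = x)
  }
  out
}

decoder_forward <- function(x, dp, keep_cache = FALSE) {
  z1 <- fc_forward(x, dp$fc1$w, dp$fc1$b); a1 <- pmax(z1, 0)
  z2 <- fc_forward(a1, dp$fc2$w, dp$fc2$b); a2 <- pmax(z2, 0)
  ccat <- cbind(a1, a2)
  z3 <- fc_forward(ccat, dp$fc3$w, dp$fc3$b); a3 <- pmax(z3, 0)
  z4 <- fc_forward(a3, dp$fc4$w, dp$fc4$b)
  out <- sigmoid(z4)
  cache <- NULL
  if (keep_cache) cache <- list(x = x, a1 = a1, a2 = a2, ccat = ccat, a3 = a3,
                                m1 = z1 > 0, m2 = z2 > 0, m3 = z3 > 0, out = out)
  list(out = out, cache = cache)
}

decoder_backward <- function(dout, dp, cache) {
  dz4 <- dout * cache$out * (1 - cache$out)
  g4 <- fc_backward(dz4, cache$a3, dp$fc4$w)
  dz3 <- g4$dx * cache$m3
  g3 <- fc_backward(dz3, cache$ccat, dp$fc3$w)
  w1 <- ncol(cache$a1)
  da2 <- g3$dx[, w1 + seq_len(ncol(cache$a2)), drop = FALSE]
  dz2 <- da2 * cache$m2
  g2 <- fc_backward(dz2, cache$a1, dp$fc2$w)
  da1 <- g3$dx[, seq_len(w1), drop = FALSE] + g2$dx
  dz1 <- da1 * cache$m1
  g1 <- fc_backward(dz1, cache$x, dp$fc1$w)
  list(dx = g1$dx,
       grads = list(fc1 = list(w = g1$dw, b = g1$db),
                    fc2 = list(w = g2$dw, b = g2$db),
                    fc3 = list(w = g3$dw, b = g3$db),
                    fc4 = list(w = g4$dw, b = g4$db)))
}

# Backward pass for the whole network given a cached training forward.
# targets: B x J one-hot.  Returns list(grads, loss, parts).
capsnet_backward <- function(model, fwd, targets) {
  cfg <- model$config
  cache <- fwd$cache
  B <- dim(cache$x)[1]
  J <- cfg$n_classes
  cdim <- cfg$pc$dim
  alpha <- cfg$loss$alpha
  xflat <- matrix(cache$x, B, prod(cfg$input_shape))
  # loss terms
  margin_terms <- vapply(fwd$head_lengths, function(len) {
    mean(margin_loss(len, targets, cfg$loss$m_plus, cfg$loss$m_minus, cfg$loss$lambda))
  }, numeric(1))
  rec_err <- fwd$reconstruction - xflat
  recon_term <- alpha * mean(rowSums(rec_err * rec_err))
  loss <- sum(margin_terms) + recon_term
  # decoder backward
  dec_g <- decoder_backward(2 * alpha * rec_err / B, model$params$decoder,
                            cache$decoder)
  # split the 54D gradient over the heads at the selected class only
  sel <- cache$sel
  dv_rows <- vector("list", 4L)
  off <- 0L
  for (h in 1:4) {
    Dh <- cfg$heads[h]
    len <- fwd$head_lengths[[h]]
    dlen <- margin_loss_backward(len, targets, cfg$loss$m_plus,
                                 cfg$loss$m_minus, cfg$loss$lambda) / B
    v_rows <- matrix(fwd$head_caps[[h]], B * J, Dh)
    len_safe <- sqrt(rowSums(v_rows * v_rows) + SQUASH_EPS)
    dvh <- v_rows * (as.vector(dlen) / len_safe)
    dec_slice <- dec_g$dx[, off + seq_len(Dh), drop = FALSE]
    rows <- seq_len(B) + B * (sel - 1L)
    dvh[rows, ] <- dvh[rows, , drop = FALSE] + dec_slice
    dv_rows[[h]] <- dvh
    off <- off + Dh
  }
  # heads backward
  n_low <- model$shapes$n_lower
  head_grads <- vector("list", 4L)
  du_levels <- vector("list", 3L)
  for (h in 1:4) {
    hb <- head_backward(dv_rows[[h]], cache$heads[[h]], model$params$heads[[h]]$w)
    head_grads[[h]] <- list(w = hb$dw)
    if (h == 1L) {
      off2 <- 0L
      for (l in 1:3) {
        du_levels[[l]] <- hb$du[off2 + seq_len(n_low[l + 1]), , , drop = FALSE]
        off2 <- off2 + n_low[l + 1]
      }
    } else {
      du_levels[[h - 1L]] <- du_levels[[h - 1L]] + hb$du
    }
  }
  # levels backward, deepest first
  level_grads <- vector("list", 3L)
  dfmap_next <- NULL
  for (l in 3:1) {
    lc <- cache$levels[[l]]
    od <- lc$grid  # (B, Ho, Wo, n_types*dim)
    du_rows <- matrix(du_levels[[l]], n_low[l + 1] * B, cdim)
    if (!is.null(dfmap_next)) {
      du_rows <- du_rows + pc_to_caps(dfmap_next, cfg$pc$n_types, cdim)
    }
    ds_rows <- squash_backward(lc$pc_s, du_rows)
    dconv <- caps_to_pc(ds_rows, B, od[2], od[3], cfg$pc$n_types, cdim)
    cb <- conv2d_backward(dconv, lc$pc_conv)
    dbk <- dense_block_backward_batch(cb$dx, cfg$dense,
                                      model$params$levels[[l]]$dense,
                                      lc$dense, lc$c_in)
    dx_in <- dbk$dx
    if (isTRUE(cfg$texton$enabled)) dx_in <- dx_in * lc$tex_mask
    level_grads[[l]] <- list(dense = dbk$grads, pc = list(w = cb$dw, b = cb$db))
    dfmap_next <- if (l > 1L) dx_in else NULL
  }
  list(grads = list(levels = level_grads, heads = head_grads,
                    decoder = dec_g$grads),
       loss = loss,
       parts = list(margin = margin_terms, reconstruction = recon_term))
}

#' Predict class labels
#'
#' The score of each class is the Euclidean length of its concatenated
#' class capsule (all four heads, 54D under the default widths); the label is
#' the argmax, ties broken by lowest class index.
#'
#' @param model a trained model.
#' @param x input batch (B, H, W, C) or single image, values in `[0, 1]`.
#' @param batch_size evaluation chunk size.
#' @return A list: `labels` (0-based integer vector), `scores`
#'   (B x n_classes matrix).
#' @export
capsnet_predict <- function(model, x, batch_size = 100L) {
  if (length(dim(x)) == 3L) x <- aperm(array(x, c(dim(x), 1L)), c(4, 1, 2, 3))
  B <- dim(x)[1]
  scores <- matrix(0, B, model$config$n_classes)
  for (start in seq.int(1L, B, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, B)
    fw <- capsnet_forward(model, x[idx, , , , drop = FALSE], training = FALSE)
    scores[idx, ] <- fw$scores
  }
  list(labels = max.col(scores, ties.method = "first") - 1L, scores = scores)
}

#' Count trainable parameters
#'
#' @param model a built model.
#' @return Total number of trainable scalars (integer-valued numeric), with a
#'   per-component breakdown data.frame attached as attribute `"breakdown"`.
#' @export
count_parameters <- function(model) {
  p <- model$params
  comp <- c(
    stats::setNames(lapply(1:3, function(l) p$levels[[l]]$dense),
                    paste0("level", 1:3, "_dense")),
    stats::setNames(lapply(1:3, function(l) p$levels[[l]]$pc),
                    paste0("level", 1:3, "_pc")),
    stats::setNames(p$heads, paste0("head", 1:4)),
    list(decoder = p$decoder)
  )
  counts <- vapply(comp, tree_sum, numeric(1))
  total <- sum(counts)
  attr(total, "breakdown") <- data.frame(component = names(counts),
                                         parameters = unname(counts))
  total
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS file with the configuration embedded.
#'
#' @param model a model.
#' @param path file path.
#' @return `capsnet_save` returns `path` invisibly; `capsnet_load` returns
#'   the model.
#' @export
capsnet_save <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname capsnet_save
#' @export
capsnet_load <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "capsnet_model"))
  m
}
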