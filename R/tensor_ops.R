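# Minimal batched tensor layers used by the capsule network: 2D convolution
# (im2col + BLAS matmul), batch normalization, ReLU, fully connected layers,
# and Adam.  Feature maps are arrays of shape (B, H, W, C); batch index first
# (fastest-varying) so im2col rows are (b, h', w') blocks.

# ---- convolution -----------------------------------------------------------

# Lower the (k, k, Cin, Cout) weight array to a (k*k*Cin, Cout) matrix in the
# same slot order that conv_im2col produces: (ki, kj) row-major, Cin fastest
# within each offset.
conv_weight_matrix <- function(w) {
  k <- dim(w)[1]; Cin <- dim(w)[3]; Cout <- dim(w)[4]
  wm <- matrix(0, k * k * Cin, Cout)
  for (ki in 0:(k - 1)) {
    for (kj in 0:(k - 1)) {
      slot <- (ki * k + kj) * Cin + seq_len(Cin)
      wm[slot, ] <- matrix(w[ki + 1, kj + 1, , ], Cin, Cout)
    }
  }
  wm
}

conv_weight_unmatrix <- function(wm, k, Cin, Cout) {
  w <- array(0, dim = c(k, k, Cin, Cout))
  for (ki in 0:(k - 1)) {
    for (kj in 0:(k - 1)) {
      slot <- (ki * k + kj) * Cin + seq_len(Cin)
      w[ki + 1, kj + 1, , ] <- array(wm[slot, ], c(Cin, Cout))
    }
  }
  w
}

pad_spatial <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, dim = c(d[1], d[2] + 2 * pad, d[3] + 2 * pad, d[4]))
  xp[, pad + seq_len(d[2]), pad + seq_len(d[3]), ] <- x
  xp
}

conv_im2col <- function(xp, k, stride, Ho, Wo) {
  d <- dim(xp)
  Cin <- d[4]
  cols <- array(0, dim = c(d[1], Ho, Wo, k * k * Cin))
  for (ki in 0:(k - 1)) {
    rows <- seq.int(1L + ki, by = stride, length.out = Ho)
    for (kj in 0:(k - 1)) {
      cc <- seq.int(1L + kj, by = stride, length.out = Wo)
      slot <- (ki * k + kj) * Cin + seq_len(Cin)
      cols[, , , slot] <- xp[, rows, cc, , drop = FALSE]
    }
  }
  dim(cols) <- c(d[1] * Ho * Wo, k * k * Cin)
  cols
}

# x: (B, H, W, Cin); w: (k, k, Cin, Cout); returns list(out, cache?).
conv2d_forward <- function(x, w, b, stride = 1L, pad = 0L, keep_cache = FALSE) {
  d <- dim(x); k <- dim(w)[1]; Cout <- dim(w)[4]
  stopifnot(dim(w)[3] == d[4])
  Ho <- (d[2] + 2 * pad - k) %/% stride + 1L
  Wo <- (d[3] + 2 * pad - k) %/% stride + 1L
  if (Ho < 1L || Wo < 1L) stop("kernel larger than (padded) input")
  xp <- pad_spatial(x, pad)
  cols <- conv_im2col(xp, k, stride, Ho, Wo)
  wm <- conv_weight_matrix(w)
  out <- cols %*% wm
  out <- out + rep(b, each = nrow(out))
  dim(out) <- c(d[1], Ho, Wo, Cout)
  cache <- NULL
  if (keep_cache) {
    cache <- list(cols = cols, wm = wm, k = k, stride = stride, pad = pad,
                  xdim = d, odim = c(d[1], Ho, Wo, Cout))
  }
  list(out = out, cache = cache)
}

conv2d_backward <- function(dout, cache) {
  od <- cache$odim; d <- cache$xdim
  k <- cache$k; stride <- cache$stride; pad <- cache$pad
  Cin <- d[4]; Ho <- od[2]; Wo <- od[3]
  dim(dout) <- c(od[1] * Ho * Wo, od[4])
  dwm <- crossprod(cache$cols, dout)
  db <- colSums(dout)
  dcols <- tcrossprod(dout, cache$wm)
  dim(dcols) <- c(od[1], Ho, Wo, k * k * Cin)
  dxp <- array(0, dim = c(d[1], d[2] + 2 * pad, d[3] + 2 * pad, Cin))
  for (ki in 0:(k - 1)) {
    rows <- seq.int(1L + ki, by = stride, length.out = Ho)
    for (kj in 0:(k - 1)) {
      cc <- seq.int(1L + kj, by = stride, length.out = Wo)
      slot <- (ki * k + kj) * Cin + seq_len(Cin)
      dxp[, rows, cc, ] <- dxp[, rows, cc, , drop = FALSE] +
        dcols[, , , slot, drop = FALSE]
    }
  }
  dx <- if (pad > 0L) dxp[, pad + seq_len(d[2]), pad + seq_len(d[3]), , drop = FALSE] else dxp
  list(dx = dx, dw = conv_weight_unmatrix(dwm, k, Cin, od[4]), db = db)
}

# ---- batch normalization ---------------------------------------------------

BN_EPS <- 1e-5

# x: (B, H, W, C).  state: list(mean, var) running statistics.  In training
# mode batch statistics are used and the running values updated in place
# (returned); in eval mode the running values are used.
batchnorm_forward <- function(x, gamma, beta, state, training = FALSE,
                              momentum = 0.9, keep_cache = FALSE) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(prod(d[1:3]), d[4])
  if (training) {
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = nrow(xm))
    v <- colMeans(xc * xc)
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * v
  } else {
    mu <- state$mean
    v <- state$var
    xc <- xm - rep(mu, each = nrow(xm))
  }
  inv_std <- 1 / sqrt(v + BN_EPS)
  xhat <- xc * rep(inv_std, each = nrow(xm))
  y <- xhat * rep(gamma, each = nrow(xm)) + rep(beta, each = nrow(xm))
  dim(y) <- d
  cache <- NULL
  if (keep_cache) cache <- list(xhat = xhat, inv_std = inv_std, gamma = gamma, d = d)
  list(out = y, state = state, cache = cache)
}

batchnorm_backward <- function(dout, cache) {
  d <- cache$d
  n <- prod(d[1:3])
  dim(dout) <- c(n, d[4])
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- dout * rep(cache$gamma, each = n)
  t1 <- colSums(dxhat)
  t2 <- colSums(dxhat * cache$xhat)
  dx <- (dxhat - rep(t1 / n, each = n) - cache$xhat * rep(t2 / n, each = n)) *
    rep(cache$inv_std, each = n)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- elementwise + fully connected ----------------------------------------

relu_forward <- function(x) list(out = pmax(x, 0), mask = x > 0)
relu_backward <- function(dout, mask) dout * mask

sigmoid <- function(x) 1 / (1 + exp(-x))

fc_forward <- function(x, w, b) x %*% w + rep(b, each = nrow(x))
# returns list(dx, dw, db)
fc_backward <- function(dout, x, w) {
  list(dx = tcrossprod(dout, w), dw = crossprod(x, dout), db = colSums(dout))
}

# ---- parameter-tree utilities and Adam ------------------------------------

# Apply f leaf-wise over parallel nested lists of numeric arrays.
tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- mapply(tree_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    return(out)
  }
  f(a, b)
}

tree_map <- function(a, f) {
  if (is.list(a)) return(lapply(a, tree_map, f = f))
  f(a)
}

tree_sum <- function(a, f = length) {
  if (is.list(a)) return(sum(vapply(a, tree_sum, numeric(1), f = f)))
  f(a)
}

adam_init <- function(params) {
  list(m = tree_map(params, function(p) p * 0),
       v = tree_map(params, function(p) p * 0),
       t = 0L)
}

# One Adam update; returns list(params, state).
adam_step <- function(params, grads, opt, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  opt$m <- tree_map2(opt$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  opt$v <- tree_map2(opt$v, grads, function(v, g) beta2 * v + (1 - beta2) * g * g)
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  step <- tree_map2(opt$m, opt$v, function(m, v) {
    lr * (m / bc1) / (sqrt(v / bc2) + eps)
  })
  params <- tree_map2(params, step, function(p, s) p - s)
  list(params = params, opt = opt)
}
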