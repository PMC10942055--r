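# Capsule primitives: squash nonlinearity, votes, dynamic routing-by-agreement,
# margin loss, and the primary/class capsule layers.
#
# A capsule is a vector of neurons; its Euclidean length encodes the
# probability that an entity is present and its direction the entity's pose.

SQUASH_EPS <- 1e-9

#' Squash nonlinearity
#'
#' `v = (||s||^2 / (1 + ||s||^2)) * s / ||s||`, applied per capsule.  The norm
#' is stabilized as `sqrt(sum(s^2) + 1e-9)` so the zero vector maps to zero.
#' Output lengths lie in `[0, 1)` and the direction of `s` is preserved.
#'
#' @param s a numeric vector (one capsule) or a matrix of capsules in rows.
#' @return Same shape as `s`.
#' @examples
#' sqrt(sum(squash(c(3, 4))^2))  # 25/26
#' @export
squash <- function(s) {
  if (!all(is.finite(s))) stop("non-finite input to squash()")
  if (is.null(dim(s))) {
    n2 <- sum(s * s)
    return(s * (n2 / (1 + n2) / sqrt(n2 + SQUASH_EPS)))
  }
  n2 <- rowSums(s * s)
  s * (n2 / (1 + n2) / sqrt(n2 + SQUASH_EPS))
}

# Backward of squash for capsules in rows: given s (N x D) and upstream
# dL/dv (N x D), returns dL/ds.  With n = ||s||, v = s * f(n),
# f(n) = n/(1+n^2):  dL/ds = f * dv + (f'(n)/n) * (s . dv) * s,
# f'(n) = (1 - n^2)/(1 + n^2)^2.  Norms use the same stabilizer as forward.
squash_backward <- function(s, dv) {
  n2 <- rowSums(s * s)
  n <- sqrt(n2 + SQUASH_EPS)
  f <- n / (1 + n2)
  fp <- (1 - n2) / (1 + n2)^2
  sdv <- rowSums(s * dv)
  dv * f + s * (fp / n * sdv)
}

#' Compute votes from lower capsules
#'
#' Each lower capsule `i` casts a vote for each upper capsule `j` through its
#' own transformation matrix: `vote[i, j, ] = u[i, ] %*% W[i, j, , ]`.
#'
#' @param u an N x D_in matrix of lower-capsule activity vectors.
#' @param weights an N x J x D_in x D_out array of transformation matrices.
#' @return An N x J x D_out array of votes.
#' @export
compute_votes <- function(u, weights) {
  stopifnot(is.matrix(u), length(dim(weights)) == 4L)
  N <- nrow(u); Din <- ncol(u)
  dw <- dim(weights)
  if (dw[1] != N || dw[3] != Din) {
    stop(sprintf("weight shape (%s) does not match %d capsules of dim %d",
                 paste(dw, collapse = "x"), N, Din))
  }
  J <- dw[2]; Dout <- dw[4]
  votes <- array(0, dim = c(N, J, Dout))
  for (d_in in seq_len(Din)) {
    # votes[i, j, d] += u[i, d_in] * W[i, j, d_in, d], vectorized over (i,j,d)
    votes <- votes + as.vector(u[, d_in]) * array(weights[, , d_in, ], dim = c(N, J, Dout))
  }
  votes
}

#' Dynamic routing-by-agreement
#'
#' Iteratively assigns coupling coefficients between lower and upper capsules.
#' Logits `b_ij` start at zero; each iteration computes
#' `c_i = softmax(b_i)` over the upper capsules, the weighted vote sums
#' `s_j = sum_i c_ij * vote_ij`, the outputs `v_j = squash(s_j)`, and (in the
#' default `"inloop"` mode) the agreement update `b_ij <- b_ij + v_j . vote_ij`
#' after every iteration.  `mode = "printed"` instead performs the agreement
#' update only once, after the iteration loop, leaving the couplings uniform
#' throughout.
#'
#' @param votes an N x J x D array of votes (see [compute_votes()]).
#' @param r number of routing iterations (>= 1), default 3.
#' @param mode `"inloop"` (default) or `"printed"`.
#' @return A list: `v` (J x D matrix of output capsules), `state` (list with
#'   `logits` and `couplings`, both N x J, and `iterations`).
#' @export
dynamic_routing <- function(votes, r = 3L, mode = c("inloop", "printed")) {
  mode <- match.arg(mode)
  stopifnot(length(dim(votes)) == 3L)
  if (r < 1L) stop("routing iterations r must be >= 1")
  N <- dim(votes)[1]; J <- dim(votes)[2]; D <- dim(votes)[3]
  b <- matrix(0, N, J)
  vm <- matrix(votes, N, J * D)  # columns (j, d) with j fastest
  v <- matrix(0, J, D)
  cc <- matrix(1 / J, N, J)
  for (it in seq_len(r)) {
    cc <- softmax_rows(b)
    s <- matrix(colSums(vm * cc[, rep(seq_len(J), D)]), J, D)
    v <- squash(s)
    if (mode == "inloop") b <- b + agreement(vm, v, N, J, D)
  }
  if (mode == "printed") b <- b + agreement(vm, v, N, J, D)
  list(v = v, state = list(logits = b, couplings = cc, iterations = r))
}

softmax_rows <- function(b) {
  e <- exp(b - apply(b, 1, max))
  e / rowSums(e)
}

# agreement a_ij = v_j . vote_ij for votes in (j,d)-column layout:
# vm is (N, J*D) with column index j + J*(d-1); v is (J, D).  A caller that
# already has the row-expanded v (one row per vm row) passes it as `vexp`.
agreement <- function(vm, v, N, J, D, vexp = NULL) {
  if (is.null(vexp)) vexp <- matrix(rep(as.vector(v), each = N), N, J * D)
  w <- vm * vexp
  a <- matrix(0, N, J)
  for (d in seq_len(D)) a <- a + w[, (d - 1L) * J + seq_len(J), drop = FALSE]
  a
}

#' Margin loss
#'
#' Per-class hinge-squared loss on class-capsule lengths:
#' `L = sum_k [ T_k * max(0, m+ - ||v_k||)^2
#'            + lambda * (1 - T_k) * max(0, ||v_k|| - m-)^2 ]`.
#'
#' @param lengths class-capsule lengths: a K-vector or a B x K matrix.
#' @param targets one-hot targets, same shape as `lengths`.
#' @param m_plus,m_minus hinge thresholds, defaults 0.9 and 0.1.
#' @param lambda down-weighting of absent classes, default 0.5.
#' @return The per-sample loss: a scalar for a vector input, a length-B
#'   vector for a matrix input.
#' @export
margin_loss <- function(lengths, targets, m_plus = 0.9, m_minus = 0.1, lambda = 0.5) {
  stopifnot(m_minus > 0, m_plus > m_minus, m_plus <= 1, lambda > 0)
  vec <- is.null(dim(lengths))
  L <- rbind(lengths); Tk <- rbind(targets)
  if (!all(dim(L) == dim(Tk))) stop("lengths and targets differ in shape")
  if (!all(Tk %in% c(0, 1)) || !all(rowSums(Tk) == 1)) {
    stop("targets must be one-hot")
  }
  per <- Tk * pmax(0, m_plus - L)^2 + lambda * (1 - Tk) * pmax(0, L - m_minus)^2
  out <- rowSums(per)
  if (vec) out[[1]] else out
}

# d(margin loss)/d(lengths) for B x K inputs (per-sample loss, no batch mean)
margin_loss_backward <- function(lengths, targets, m_plus = 0.9, m_minus = 0.1,
                                 lambda = 0.5) {
  -2 * targets * pmax(0, m_plus - lengths) +
    2 * lambda * (1 - targets) * pmax(0, lengths - m_minus)
}

#' Primary-capsule layer (single feature map)
#'
#' One unpadded convolution producing `n_types * dim` channels, reshaped into
#' a grid of `H' * W' * n_types` capsules of dimension `dim` and squashed per
#' capsule, with `H' = floor((H - kernel)/stride) + 1`.
#'
#' @param fmap an H x W x C numeric array.
#' @param n_types number of capsule types per grid cell (e.g. 12).
#' @param dim capsule dimension (e.g. 8).
#' @param kernel,stride convolution kernel size and stride (no padding).
#' @param weights optional `kernel x kernel x C x (n_types*dim)` array
#'   (random-normal, sd 0.01, when omitted); `bias` optional length
#'   `n_types*dim` vector (zeros when omitted).
#' @param bias see `weights`.
#' @return A list: `caps` (an `(H'*W'*n_types) x dim` matrix of squashed
#'   capsules), `fmap_view` (the squashed tensor re-laid-out as an
#'   `H' x W' x (n_types*dim)` feature map, what feeds the next level), and
#'   `grid` = c(H', W', n_types).
#' @export
primary_capsule_forward <- function(fmap, n_types, dim, kernel, stride,
                                    weights = NULL, bias = NULL) {
  caps_dim <- dim
  if (is.matrix(fmap)) base::dim(fmap) <- c(base::dim(fmap), 1L)
  d <- base::dim(fmap)
  if (kernel > d[1] || kernel > d[2]) {
    stop(sprintf("kernel %d larger than input %dx%d", kernel, d[1], d[2]))
  }
  C <- d[3]; Ch <- n_types * caps_dim
  if (is.null(weights)) {
    weights <- array(stats::rnorm(kernel^2 * C * Ch, sd = 0.01),
                     dim = c(kernel, kernel, C, Ch))
  }
  if (is.null(bias)) bias <- numeric(Ch)
  x <- aperm(array(fmap, c(d, 1L)), c(4, 1, 2, 3))  # (1, H, W, C)
  conv <- conv2d_forward(x, weights, bias, stride = stride, pad = 0L)
  Hp <- base::dim(conv$out)[2]; Wp <- base::dim(conv$out)[3]
  # channel index ch = d + caps_dim*(type-1); capsule index i over (h, w, type)
  arr <- array(conv$out[1, , , ], c(Hp, Wp, caps_dim, n_types))
  u <- matrix(aperm(arr, c(1, 2, 4, 3)), Hp * Wp * n_types, caps_dim)
  u <- squash(u)
  back <- aperm(array(u, c(Hp, Wp, n_types, caps_dim)), c(1, 2, 4, 3))
  list(caps = u,
       fmap_view = array(back, c(Hp, Wp, Ch)),
       grid = c(Hp, Wp, n_types))
}

#' Class-capsule layer (single sample)
#'
#' Computes votes from the lower capsules and runs dynamic routing, yielding
#' one capsule per class.
#'
#' @param caps an N x D_in matrix of lower capsules.
#' @param n_classes number of classes J.
#' @param out_dim output capsule dimension.
#' @param r routing iterations.
#' @param weights optional N x J x D_in x out_dim array (random-normal,
#'   sd 0.01, when omitted).
#' @return A list as from [dynamic_routing()]: `v` (n_classes x out_dim) and
#'   `state`.
#' @export
class_capsule_forward <- function(caps, n_classes, out_dim, r = 3L, weights = NULL) {
  stopifnot(is.matrix(caps))
  if (is.null(weights)) {
    weights <- array(stats::rnorm(nrow(caps) * n_classes * ncol(caps) * out_dim,
                                  sd = 0.01),
                     dim = c(nrow(caps), n_classes, ncol(caps), out_dim))
  }
  dynamic_routing(compute_votes(caps, weights), r = r)
}
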