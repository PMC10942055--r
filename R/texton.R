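# Six-texton detection on 2x2 grids.
#
# A texton here is a 2x2 pixel grid (corners V1 = top-left, V2 = top-right,
# V3 = bottom-left, V4 = bottom-right) in which a designated pair of pixels
# share the same value.  Six pair geometries are used; the last two (vertical
# right, horizontal bottom) extend the classical four-texton set.

#' The six texton types
#'
#' Returns the table of texton types: each type names the pair of 2x2 grid
#' corners that must be equal for the texton to fire.  Corners are numbered
#' V1 = top-left, V2 = top-right, V3 = bottom-left, V4 = bottom-right.
#' Types are tested in the order T1..T6; T5 (vertical right: V2 = V4) and
#' T6 (horizontal bottom: V3 = V4) are the two added beyond the classical
#' four-texton set.
#'
#' @return A data.frame with columns `type` ("T1".."T6"), `a`, `b`
#'   (the 1-based corner indices of the compared pair).
#' @export
texton_types <- function() {
  data.frame(
    type = paste0("T", 1:6),
    a = c(1L, 2L, 1L, 1L, 2L, 3L),
    b = c(2L, 3L, 3L, 4L, 4L, 4L),
    stringsAsFactors = FALSE
  )
}

#' Classify a single 2x2 grid
#'
#' Tests the six corner pairs in the fixed order T1..T6 and returns the first
#' type whose pair of values is equal, making the classification mutually
#' exclusive per grid (an if/else-if chain).  A grid with no equal designated
#' pair yields `NA`.
#'
#' @param v1,v2,v3,v4 the four corner values (top-left, top-right,
#'   bottom-left, bottom-right).
#' @return `"T1"`..`"T6"`, or `NA_character_` when no pair is equal.
#' @examples
#' texton_classify_grid(5, 5, 1, 2)  # "T1"
#' texton_classify_grid(1, 2, 3, 4)  # NA
#' @export
texton_classify_grid <- function(v1, v2, v3, v4) {
  vals <- c(v1, v2, v3, v4)
  tt <- texton_types()
  for (k in seq_len(nrow(tt))) {
    if (vals[tt$a[k]] == vals[tt$b[k]]) return(tt$type[k])
  }
  NA_character_
}

# Batched texton mask over an array of shape (B, H, W, C) of discrete values.
# Returns a logical array of the same shape: TRUE where the pixel belongs to
# at least one fired 2x2 grid.  `textons` is an integer subset of 1:6.
# Overlapping grids combine by logical OR; with whole-grid keeping this is
# observationally equivalent to the first-match if/else-if chain.
texton_mask_nd <- function(x, step = 1L, textons = 1:6) {
  d <- dim(x)
  H <- d[2]; W <- d[3]
  mask <- array(FALSE, dim = d)
  if (H < 2L || W < 2L) {
    warning("image smaller than 2x2: empty texton mask")
    return(mask)
  }
  ai <- seq.int(1L, H - 1L, by = step)  # 2x2 anchors, clamped in bounds
  aj <- seq.int(1L, W - 1L, by = step)
  v1 <- x[, ai, aj, , drop = FALSE]
  v2 <- x[, ai, aj + 1L, , drop = FALSE]
  v3 <- x[, ai + 1L, aj, , drop = FALSE]
  v4 <- x[, ai + 1L, aj + 1L, , drop = FALSE]
  pairs <- list(list(v1, v2), list(v2, v3), list(v1, v3),
                list(v1, v4), list(v2, v4), list(v3, v4))
  fire <- array(FALSE, dim = dim(v1))
  for (k in textons) fire <- fire | (pairs[[k]][[1]] == pairs[[k]][[2]])
  # a fired anchor keeps all four grid positions
  mask[, ai, aj, ]           <- mask[, ai, aj, , drop = FALSE] | fire
  mask[, ai, aj + 1L, ]      <- mask[, ai, aj + 1L, , drop = FALSE] | fire
  mask[, ai + 1L, aj, ]      <- mask[, ai + 1L, aj, , drop = FALSE] | fire
  mask[, ai + 1L, aj + 1L, ] <- mask[, ai + 1L, aj + 1L, , drop = FALSE] | fire
  mask
}

#' Texton detection on an integer image
#'
#' Scans 2x2 grids anchored at every `step`-th row/column position (anchors
#' restricted so the grid stays in bounds), marks all four positions of every
#' grid whose designated pixel pair is equal (overlapping grids combine by
#' OR), and zeroes every unmarked pixel.  Marked pixels keep their original
#' values.
#'
#' @param image a 2D numeric matrix of discrete levels.
#' @param step scan step in pixels, 1 or 2.
#' @param textons integer subset of 1:6 selecting the texton types to use.
#' @return An object of class `texton_image`: a list with `values` (the
#'   masked image), `mask` (logical matrix), and `step`.
#' @examples
#' img <- matrix(c(5, 2, 4, 5, 9, 6, 1, 1, 8), nrow = 3)  # rows 5,5,1/2,9,1/4,6,8
#' detect_textons(img)$values
#' @export
detect_textons <- function(image, step = 1L, textons = 1:6) {
  stopifnot(is.matrix(image), step %in% c(1L, 2L))
  if (length(textons) == 0L || !all(textons %in% 1:6)) {
    stop("`textons` must be a non-empty subset of 1:6")
  }
  x <- array(image, dim = c(1L, nrow(image), ncol(image), 1L))
  m <- texton_mask_nd(x, step = as.integer(step), textons = sort(unique(as.integer(textons))))
  mask <- matrix(m[1L, , , 1L], nrow = nrow(image))
  structure(list(values = image * mask, mask = mask, step = as.integer(step)),
            class = "texton_image")
}

#' @export
print.texton_image <- function(x, ...) {
  cat(sprintf("texton image %dx%d, step %d, %.1f%% of pixels kept\n",
              nrow(x$values), ncol(x$values), x$step, 100 * mean(x$mask)))
  invisible(x)
}

# Per-channel uniform quantization of one channel slab (any numeric array)
# to `levels` bins over its min-max range; a constant slab maps to bin 0.
quantize_uniform <- function(v, levels) {
  rng <- range(v)
  if (rng[1] == rng[2]) return(array(0L, dim = dim(v) %||% length(v)))
  q <- floor((v - rng[1]) / (rng[2] - rng[1]) * levels)
  q[q >= levels] <- levels - 1L
  q
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Texton layer for real-valued feature maps
#'
#' Extends texton detection to continuous activations: each channel is
#' independently quantized to `levels` uniform bins over its own min-max
#' range (a constant channel maps everywhere to bin 0, so it is fully
#' detected), the six-texton detector is run on the quantized grid, and the
#' resulting boolean mask multiplies the ORIGINAL real values.  In a network
#' the mask is a constant of the forward pass (straight-through): downstream
#' gradients are zero exactly at masked-out positions.
#'
#' @param fmap an H x W x C numeric array (or H x W matrix, taken as C = 1).
#' @param levels number of quantization bins (>= 2).
#' @param step scan step, 1 or 2.
#' @param textons integer subset of 1:6.
#' @return A numeric array of the same shape, with `mask` (logical array)
#'   attached as an attribute.
#' @export
apply_texton_layer <- function(fmap, levels = 256L, step = 1L, textons = 1:6) {
  if (is.matrix(fmap)) dim(fmap) <- c(dim(fmap), 1L)
  stopifnot(length(dim(fmap)) == 3L, levels >= 2L)
  if (!all(is.finite(fmap))) {
    bad <- which(apply(fmap, 3, function(ch) any(!is.finite(ch))))
    stop("non-finite values in channel(s): ", paste(bad, collapse = ", "))
  }
  x <- aperm(array(fmap, dim = c(dim(fmap), 1L)), c(4, 1, 2, 3))  # (1,H,W,C)
  mask <- texton_mask_batch(x, levels = levels, step = step, textons = textons)
  mask3 <- array(mask[1L, , , ], dim = dim(fmap))
  out <- fmap * mask3
  attr(out, "mask") <- mask3
  out
}

# Batched quantize-then-detect over (B, H, W, C): quantization is per sample
# and per channel.  Used by apply_texton_layer and by the in-network layers.
texton_mask_batch <- function(x, levels = 256L, step = 1L, textons = 1:6) {
  d <- dim(x)
  q <- array(0L, dim = d)
  for (b in seq_len(d[1])) {
    for (ch in seq_len(d[4])) {
      q[b, , , ch] <- quantize_uniform(x[b, , , ch], levels)
    }
  }
  texton_mask_nd(q, step = as.integer(step), textons = textons)
}
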