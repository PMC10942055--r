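# Joint training: the four class-capsule heads are trained under an
# unweighted sum of their margin losses (each head's gradient path is
# disjoint up to its primary capsules, which realizes independent per-head
# back-propagation) plus a down-weighted sum-squared reconstruction error.
# Optimizer: Adam.  The best model by validation accuracy is checkpointed.

#' Training configuration
#'
#' @param lr Adam learning rate (default 0.001).
#' @param batch_size samples per batch; the study protocol uses batches
#'   between 50 and 100 (default 64).
#' @param epochs number of epochs.
#' @param seed integer seed controlling shuffling (and any augmentation).
#' @param checkpoint_dir directory for the best-model checkpoint and the
#'   JSON-lines training log; `NULL` disables checkpointing.
#' @param verbose print per-epoch progress.
#' @return A list of class `train_config`.
#' @export
train_config <- function(lr = 1e-3, batch_size = 64L, epochs = 10L, seed = 0L,
                         checkpoint_dir = NULL, verbose = FALSE) {
  stopifnot(batch_size >= 1L, epochs >= 1L, lr > 0)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 checkpoint_dir = checkpoint_dir, verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Total training loss
#'
#' The sum over the four heads of the batch-mean margin loss on that head's
#' class-capsule lengths, plus `alpha` times the batch-mean sum-squared
#' reconstruction error.
#'
#' @param out a [capsnet_forward()] result.
#' @param targets B x n_classes one-hot matrix.
#' @param x the input batch the reconstruction is compared against.
#' @param loss_params list(m_plus, m_minus, lambda, alpha).
#' @return The scalar loss, with attribute `"parts"` giving the four margin
#'   terms and the reconstruction term.
#' @export
total_loss <- function(out, targets, x,
                       loss_params = list(m_plus = 0.9, m_minus = 0.1,
                                          lambda = 0.5, alpha = 5e-4)) {
  if (length(dim(x)) == 3L) x <- aperm(array(x, c(dim(x), 1L)), c(4, 1, 2, 3))
  B <- nrow(targets)
  margins <- vapply(out$head_lengths, function(len) {
    mean(margin_loss(len, targets, loss_params$m_plus, loss_params$m_minus,
                     loss_params$lambda))
  }, numeric(1))
  err <- out$reconstruction - matrix(x, B, length(x) / B)
  rec <- loss_params$alpha * mean(rowSums(err * err))
  structure(sum(margins) + rec,
            parts = list(margin = margins, reconstruction = rec))
}

one_hot <- function(labels, n_classes) {
  m <- matrix(0, length(labels), n_classes)
  m[cbind(seq_along(labels), labels + 1L)] <- 1
  m
}

#' Train a model
#'
#' Mini-batch Adam training under the summed per-head margin losses and
#' reconstruction regularization.  Runs are reproducible given the seed
#' (single-threaded mode).  A checkpoint is written whenever validation
#' accuracy improves; training aborts with a diagnostic on a non-finite loss.
#'
#' @param model a [capsnet_build()] model.
#' @param train_set,val_set datasets as returned by the data module: lists
#'   with `images` (n, H, W, C array, 8-bit values 0..255) and `labels`
#'   (0-based integers).
#' @param cfg a [train_config()].
#' @return A list: `model` (final weights), `best_model`, `history`
#'   (data.frame of per-epoch train/val loss and accuracy),
#'   `checkpoint_path` (or NULL).
#' @export
train_model <- function(model, train_set, val_set, cfg = train_config()) {
  stopifnot(length(train_set$labels) > 0L, length(val_set$labels) > 0L)
  set.seed(cfg$seed)
  J <- model$config$n_classes
  xtr <- train_set$images / 255
  xva <- val_set$images / 255
  ytr <- as.integer(train_set$labels)
  yva <- as.integer(val_set$labels)
  n <- length(ytr)
  opt <- adam_init(model$params)
  history <- data.frame()
  best_acc <- -Inf
  best_model <- NULL
  ckpt <- NULL
  log_path <- NULL
  if (!is.null(cfg$checkpoint_dir)) {
    dir.create(cfg$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
    ckpt <- file.path(cfg$checkpoint_dir, "best_model.rds")
    log_path <- file.path(cfg$checkpoint_dir, "training_log.jsonl")
    if (file.exists(log_path)) unlink(log_path)
  }
  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    ep_loss <- 0
    ep_correct <- 0L
    for (start in seq.int(1L, n, by = cfg$batch_size)) {
      idx <- perm[start:min(start + cfg$batch_size - 1L, n)]
      xb <- xtr[idx, , , , drop = FALSE]
      yb <- one_hot(ytr[idx], J)
      fwd <- capsnet_forward(model, xb, mask_labels = yb, training = TRUE,
                             keep_cache = TRUE)
      model$state <- fwd$state
      bwd <- capsnet_backward(model, fwd, yb)
      if (!is.finite(bwd$loss)) {
        stop(sprintf("non-finite loss at epoch %d (batch starting %d); aborting",
                     epoch, start))
      }
      upd <- adam_step(model$params, bwd$grads, opt, lr = cfg$lr)
      model$params <- upd$params
      opt <- upd$opt
      ep_loss <- ep_loss + bwd$loss * length(idx)
      ep_correct <- ep_correct + sum(max.col(fwd$scores, ties.method = "first") - 1L == ytr[idx])
    }
    val <- evaluate_split(model, xva, yva)
    row <- data.frame(epoch = epoch, train_loss = ep_loss / n,
                      train_acc = ep_correct / n,
                      val_loss = val$loss, val_acc = val$acc)
    history <- rbind(history, row)
    if (cfg$verbose) {
      message(sprintf("epoch %d: train loss %.4f acc %.3f | val loss %.4f acc %.3f",
                      epoch, row$train_loss, row$train_acc, row$val_loss, row$val_acc))
    }
    if (!is.null(log_path)) {
      cat(jsonlite::toJSON(as.list(row), auto_unbox = TRUE), "\n",
          file = log_path, append = TRUE, sep = "")
    }
    if (val$acc > best_acc) {
      best_acc <- val$acc
      best_model <- model
      if (!is.null(ckpt)) capsnet_save(model, ckpt)
    }
  }
  list(model = model, best_model = best_model, history = history,
       checkpoint_path = ckpt)
}

# Loss and accuracy on a scaled (already /255) split, eval mode.
evaluate_split <- function(model, x, y, batch_size = 100L) {
  J <- model$config$n_classes
  n <- length(y)
  tot_loss <- 0
  correct <- 0L
  lp <- model$config$loss
  for (start in seq.int(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    xb <- x[idx, , , , drop = FALSE]
    yb <- one_hot(y[idx], J)
    fwd <- capsnet_forward(model, xb, training = FALSE)
    l <- total_loss(fwd, yb, xb, lp)
    tot_loss <- tot_loss + as.numeric(l) * length(idx)
    correct <- correct + sum(max.col(fwd$scores, ties.method = "first") - 1L == y[idx])
  }
  list(loss = tot_loss / n, acc = correct / n)
}
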