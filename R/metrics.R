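# Confusion-matrix construction and per-class (one-vs-rest) diagnostics:
# accuracy, precision, sensitivity (recall), specificity, plus ROC and
# precision-recall curves with their areas.

#' Confusion matrix and per-class counts
#'
#' Rows are actual classes, columns predicted.  One-vs-rest TP/FP/TN/FN
#' counts are derived per class; for every class TP + FP + TN + FN equals the
#' total sample count.
#'
#' @param y_true,y_pred 0-based integer labels in `[0, n_classes)`.
#' @param n_classes number of classes.
#' @return A list of class `confusion_counts`: `matrix` (n_classes x
#'   n_classes, dimnames 0-based), `counts` (data.frame with class, tp, fp,
#'   tn, fn), `n` (total samples).
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes) {
  stopifnot(length(y_true) == length(y_pred))
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (any(y_true < 0L | y_true >= n_classes) || any(y_pred < 0L | y_pred >= n_classes)) {
    stop("labels out of range [0, n_classes)")
  }
  lev <- 0:(n_classes - 1L)
  m <- table(factor(y_true, levels = lev), factor(y_pred, levels = lev))
  m <- unclass(matrix(m, n_classes, n_classes, dimnames = list(actual = lev, predicted = lev)))
  n <- length(y_true)
  tp <- diag(m)
  fn <- rowSums(m) - tp
  fp <- colSums(m) - tp
  tn <- n - tp - fn - fp
  structure(list(matrix = m,
                 counts = data.frame(class = lev, tp = as.integer(tp),
                                     fp = as.integer(fp), tn = as.integer(tn),
                                     fn = as.integer(fn)),
                 n = n),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("confusion matrix (rows = actual, cols = predicted):\n")
  print(x$matrix)
  invisible(x)
}

#' Per-class metrics from confusion counts
#'
#' Computes, one-vs-rest per class:
#' accuracy = (TP+TN)/(TP+FP+TN+FN), precision = TP/(TP+FP),
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP).
#' A metric with a zero denominator is reported as `NA` (undefined), not 0.
#'
#' @param counts a `confusion_counts` object, or a data.frame with columns
#'   tp, fp, tn, fn (one row per class) such as the count columns printed in
#'   a publication table.
#' @return A data.frame with class, the four counts, `accuracy` (as a
#'   percentage), `precision`, `sensitivity`, `specificity`.  Values are at
#'   full precision; see [format_metrics()] for table-style rounding.
#' @examples
#' per_class_metrics(data.frame(tp = 287, fp = 6, tn = 1005, fn = 13))
#' @export
per_class_metrics <- function(counts) {
  df <- if (inherits(counts, "confusion_counts")) counts$counts else counts
  stopifnot(all(c("tp", "fp", "tn", "fn") %in% names(df)))
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  tot <- df$tp + df$fp + df$tn + df$fn
  out <- df
  out$accuracy <- 100 * safe_div(df$tp + df$tn, tot)
  out$precision <- safe_div(df$tp, df$tp + df$fp)
  out$sensitivity <- safe_div(df$tp, df$tp + df$fn)
  out$specificity <- safe_div(df$tn, df$tn + df$fp)
  out
}

# Half-up rounding (round() in R rounds half to even, which does not match
# how diagnostic tables are conventionally printed).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format per-class metrics table-style
#'
#' Rounds the ratio metrics half-up to 4 decimals and the percentage accuracy
#' to 2 decimals, the convention of printed diagnostic tables.
#'
#' @param metrics a data.frame from [per_class_metrics()].
#' @return The data.frame with rounded metric columns.
#' @export
format_metrics <- function(metrics) {
  for (col in c("precision", "sensitivity", "specificity")) {
    metrics[[col]] <- round_half_up(metrics[[col]], 4)
  }
  metrics$accuracy <- round_half_up(metrics$accuracy, 2)
  metrics
}

#' ROC and precision-recall curves
#'
#' One-vs-rest per class: sweeps thresholds over the unique scores, computes
#' ROC points (FPR, TPR) with trapezoidal area, and PR points with the
#' standard step interpolation (area = sum over recall increments of the
#' precision at each threshold).
#'
#' @param scores an n x n_classes matrix of class scores (higher = more
#'   confident), e.g. concatenated capsule lengths.
#' @param y_true 0-based integer labels.
#' @return A list per class (named "0", "1", ...), each with `roc`
#'   (data.frame fpr/tpr), `pr` (data.frame recall/precision), `auroc`,
#'   `auprc`; classes absent from `y_true` get `NULL`.  Macro averages over
#'   the defined classes are attached as attributes `macro_auroc` and
#'   `macro_auprc`.
#' @export
roc_pr_curves <- function(scores, y_true) {
  stopifnot(is.matrix(scores), nrow(scores) == length(y_true), all(is.finite(scores)))
  K <- ncol(scores)
  out <- vector("list", K)
  names(out) <- as.character(0:(K - 1L))
  for (k in seq_len(K)) {
    pos <- as.integer(y_true == (k - 1L))
    if (sum(pos) == 0L) next
    out[[k]] <- binary_curves(scores[, k], pos)
  }
  def <- !vapply(out, is.null, logical(1))
  attr(out, "macro_auroc") <- mean(vapply(out[def], `[[`, numeric(1), "auroc"))
  attr(out, "macro_auprc") <- mean(vapply(out[def], `[[`, numeric(1), "auprc"))
  out
}

binary_curves <- function(score, pos) {
  n_pos <- sum(pos)
  n_neg <- sum(1 - pos)
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; p <- pos[ord]
  # cumulative counts at each unique-score threshold ("predict positive if
  # score >= t"), plus the all-negative point
  last <- cumsum(rep(1L, length(s)))[!duplicated(s, fromLast = TRUE)]
  tp <- cumsum(p)[last]
  fp <- last - tp
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, if (n_neg > 0) fp / n_neg else rep(0, length(fp)))
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  auprc <- sum(diff(c(0, rec)) * prec)
  list(roc = data.frame(fpr = fpr, tpr = tpr),
       pr = data.frame(recall = c(0, rec), precision = c(prec[1], prec)),
       auroc = auroc, auprc = auprc)
}

#' Write an evaluation report
#'
#' Writes the per-class metrics CSV, a confusion-matrix heatmap PNG, and
#' per-class ROC/PR curve PNGs into a directory.
#'
#' @param cm a `confusion_counts` object.
#' @param curves optional result of [roc_pr_curves()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(cm, curves = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  metrics <- format_metrics(per_class_metrics(cm))
  utils::write.csv(metrics, file.path(dir, "per_class_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(cm$matrix), file.path(dir, "confusion_matrix.csv"))
  grDevices::png(file.path(dir, "confusion_matrix.png"), width = 480, height = 480)
  graphics::image(t(cm$matrix)[, nrow(cm$matrix):1], axes = FALSE,
                  main = "Confusion matrix", col = grDevices::hcl.colors(25, "Blues", rev = TRUE))
  grDevices::dev.off()
  if (!is.null(curves)) {
    grDevices::png(file.path(dir, "roc_pr.png"), width = 960, height = 480)
    graphics::par(mfrow = c(1, 2))
    graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 1), xlab = "FPR",
                   ylab = "TPR", main = "ROC (one-vs-rest)")
    graphics::abline(0, 1, lty = 2, col = "grey")
    for (k in seq_along(curves)) {
      if (!is.null(curves[[k]])) graphics::lines(curves[[k]]$roc$fpr, curves[[k]]$roc$tpr, col = k)
    }
    graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 1), xlab = "Recall",
                   ylab = "Precision", main = "Precision-recall")
    for (k in seq_along(curves)) {
      if (!is.null(curves[[k]])) graphics::lines(curves[[k]]$pr$recall, curves[[k]]$pr$precision, col = k)
    }
    grDevices::dev.off()
  }
  invisible(dir)
}
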