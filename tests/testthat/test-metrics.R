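test_that("confusion matrices tally actual x predicted and conserve totals", {
  # perfect prediction: diagonal, no FP/FN
  cm <- confusion_matrix(c(0, 1, 2, 1), c(0, 1, 2, 1), 3)
  expect_equal(diag(cm$matrix), c(`0` = 1, `1` = 2, `2` = 1))
  expect_true(all(cm$counts$fp == 0) && all(cm$counts$fn == 0))
  # 3-class toy against a hand tally: true (0,0,1,1,2,2), pred (0,1,1,2,2,0)
  cm2 <- confusion_matrix(c(0, 0, 1, 1, 2, 2), c(0, 1, 1, 2, 2, 0), 3)
  expect_equal(unname(cm2$matrix),
               matrix(c(1, 1, 0, 0, 1, 1, 1, 0, 1), 3, byrow = TRUE))
  expect_equal(cm2$counts$tp, c(1, 1, 1))
  expect_equal(cm2$counts$fp, c(1, 1, 1))
  expect_equal(cm2$counts$fn, c(1, 1, 1))
  expect_equal(cm2$counts$tn, c(3, 3, 3))
  # every class conserves the total
  with(cm2$counts, expect_true(all(tp + fp + tn + fn == 6)))
  expect_error(confusion_matrix(c(0, 3), c(0, 1), 3), "out of range")
})

test_that("binary class counts mirror each other one-vs-rest", {
  # a binary confusion matrix with class-0 counts TP=461 FP=44 TN=1042 FN=35
  # implies the swapped counts for class 1
  y_true <- c(rep(0, 461 + 35), rep(1, 1042 + 44))
  y_pred <- c(rep(0, 461), rep(1, 35), rep(1, 1042), rep(0, 44))
  cm <- confusion_matrix(y_true, y_pred, 2)
  expect_equal(unname(unlist(cm$counts[1, c("tp", "fp", "tn", "fn")])),
               c(461, 44, 1042, 35))
  expect_equal(unname(unlist(cm$counts[2, c("tp", "fp", "tn", "fn")])),
               c(1042, 35, 461, 44))
  m <- per_class_metrics(cm)
  # sensitivity of one class equals specificity of the other, and the
  # per-class accuracy is shared
  expect_equal(m$sensitivity[1], m$specificity[2])
  expect_equal(m$sensitivity[2], m$specificity[1])
  expect_equal(m$accuracy[1], m$accuracy[2])
})

test_that("per-class metrics reproduce the one-vs-rest formulas", {
  m <- per_class_metrics(data.frame(tp = 287, fp = 6, tn = 1005, fn = 13))
  expect_equal(m$precision, 287 / 293)
  expect_equal(m$sensitivity, 287 / 300)
  expect_equal(m$specificity, 1005 / 1011)
  expect_equal(m$accuracy, 100 * 1292 / 1311)
  fm <- format_metrics(m)
  expect_equal(fm$precision, 0.9795)
  expect_equal(fm$sensitivity, 0.9567)
  expect_equal(fm$specificity, 0.9941)
  expect_equal(fm$accuracy, 98.55)
  # a heavily missed class
  expect_equal(format_metrics(per_class_metrics(
    data.frame(tp = 63, fp = 24, tn = 1062, fn = 433)))$sensitivity, 0.1270)
})

test_that("zero denominators yield undefined metrics, not zero", {
  m <- per_class_metrics(data.frame(tp = 0, fp = 0, tn = 10, fn = 0))
  expect_true(is.na(m$precision))
  expect_true(is.na(m$sensitivity))
  expect_equal(m$specificity, 1)
})

test_that("half-up rounding matches table conventions", {
  expect_equal(textoncaps:::round_half_up(0.99695, 2), 1.00)
  expect_equal(textoncaps:::round_half_up(99.695, 2), 99.70)  # round() would give 99.69
  expect_equal(textoncaps:::round_half_up(0.12345, 4), 0.1235)
})

test_that("ROC/PR sweep matches brute-force threshold enumeration", {
  # perfectly separating scores
  scores <- cbind(c(0.9, 0.8, 0.2, 0.1), c(0.1, 0.2, 0.8, 0.9))
  y <- c(0, 0, 1, 1)
  cv <- roc_pr_curves(scores, y)
  expect_equal(cv[["0"]]$auroc, 1)
  expect_equal(cv[["1"]]$auroc, 1)
  expect_equal(cv[["0"]]$auprc, 1)
  # label-independent scores sit on the chance line
  flat <- cbind(rep(0.5, 6), rep(0.5, 6))
  cv2 <- roc_pr_curves(flat, c(0, 1, 0, 1, 0, 1))
  expect_equal(cv2[["0"]]$auroc, 0.5)
  # 8-sample toy: exhaustive enumeration of thresholds
  set.seed(1)
  s <- runif(8)
  pos <- c(1, 0, 1, 1, 0, 0, 1, 0)
  got <- textoncaps:::binary_curves(s, pos)
  th <- sort(unique(s), decreasing = TRUE)
  pts <- t(vapply(th, function(t0) {
    pred <- s >= t0
    c(fpr = sum(pred & pos == 0) / sum(pos == 0),
      tpr = sum(pred & pos == 1) / sum(pos == 1))
  }, numeric(2)))
  pts <- rbind(c(0, 0), pts)
  auc_ref <- sum(diff(pts[, 1]) * (head(pts[, 2], -1) + tail(pts[, 2], -1)) / 2)
  expect_equal(got$auroc, auc_ref, tolerance = 1e-12)
})

test_that("ROC areas agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(2)
  s <- runif(50)
  pos <- rbinom(50, 1, plogis(3 * (s - 0.5)))
  got <- textoncaps:::binary_curves(s, pos)
  ref <- as.numeric(pROC::auc(pROC::roc(pos, s, quiet = TRUE, direction = "<")))
  expect_equal(got$auroc, ref, tolerance = 1e-10)
})

test_that("classes absent from the truth get undefined curves", {
  scores <- cbind(c(0.9, 0.1), c(0.1, 0.9), c(0.3, 0.3))
  cv <- roc_pr_curves(scores, c(0, 1))
  expect_null(cv[["2"]])
  expect_false(is.null(cv[["0"]]))
})

test_that("report writing emits the metrics CSV and plots", {
  dir <- tempfile()
  cm <- confusion_matrix(c(0, 0, 1, 1), c(0, 1, 1, 1), 2)
  cv <- roc_pr_curves(cbind(c(.9, .4, .2, .1), c(.1, .6, .8, .9)), c(0, 0, 1, 1))
  write_report(cm, cv, dir)
  expect_true(file.exists(file.path(dir, "per_class_metrics.csv")))
  expect_true(file.exists(file.path(dir, "confusion_matrix.png")))
  expect_true(file.exists(file.path(dir, "roc_pr.png")))
  got <- utils::read.csv(file.path(dir, "per_class_metrics.csv"))
  expect_equal(got$tp, cm$counts$tp)
  unlink(dir, recursive = TRUE)
})
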