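test_that("confusion matrix counts true/predicted pairs", {
  cm <- confusion_matrix(c("a", "b", "c"), c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(diag(cm$counts), c(a = 1L, b = 1L, c = 1L))
  expect_equal(sum(cm$counts) - sum(diag(cm$counts)), 0L)

  cm <- confusion_matrix(c(0, 0, 1, 1), c(0, 1, 1, 1), c(0, 1))
  expect_equal(unname(cm$counts), matrix(c(1L, 0L, 1L, 2L), 2))

  # conservation: totals equal the sample count
  set.seed(5)
  y <- sample(letters[1:4], 57, replace = TRUE)
  p <- sample(letters[1:4], 57, replace = TRUE)
  expect_equal(sum(confusion_matrix(y, p, letters[1:4])$counts), 57L)

  expect_error(confusion_matrix(c("a", "z"), c("a", "a"), c("a", "b")), "z")
  expect_error(confusion_matrix(c("a"), c("a", "b"), c("a", "b")), "length")
})

test_that("per-class precision/recall/F1 follow their definitions with the
           zero-denominator convention", {
  # precision == recall == p implies F1 == p (harmonic-mean fixed point)
  cm <- confusion_matrix(c(0, 0, 0, 1, 1, 1, 1, 1),
                         c(0, 0, 1, 0, 1, 1, 1, 1), c(0, 1))
  rep_ <- per_class_prf(cm)
  pc <- rep_$per_class
  i <- which(pc$class == "1")
  expect_equal(pc$precision[i], pc$recall[i])
  expect_equal(pc$f1[i], pc$precision[i])

  # class never predicted and never true -> all-zero row, not NaN
  cm <- confusion_matrix(c("a", "a"), c("a", "a"), c("a", "b"))
  pc <- per_class_prf(cm)$per_class
  expect_equal(pc[pc$class == "b", c("precision", "recall", "f1")],
               data.frame(precision = 0, recall = 0, f1 = 0,
                          row.names = 2L))
})

test_that("aggregate rows: micro pools counts, macro averages classes,
           weighted uses supports", {
  # degenerate single perfect class
  r <- aggregate_prf(per_class_prf(confusion_matrix("a", "a", "a")))
  expect_equal(unname(r$micro), c(1, 1, 1))
  expect_equal(unname(r$macro), c(1, 1, 1))
  expect_equal(unname(r$weighted), c(1, 1, 1))

  # equal supports make macro and weighted coincide
  y <- rep(c("a", "b"), each = 10)
  set.seed(8)
  p <- sample(c("a", "b"), 20, replace = TRUE)
  r <- aggregate_prf(per_class_prf(confusion_matrix(y, p, c("a", "b"))))
  expect_equal(r$macro, r$weighted)

  # micro identity: micro precision = micro recall = accuracy (single-label)
  expect_equal(r$micro[["precision"]], r$micro[["recall"]])
  expect_equal(r$micro[["precision"]], mean(y == p))

  r0 <- per_class_prf(confusion_matrix(character(0), character(0), "a"))
  expect_error(aggregate_prf(r0), "support")
})

test_that("ROC points: anchors, separation, tie collapse and pair-count
           agreement", {
  # perfect separation passes through (0, 1)
  roc <- roc_points(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)

  # all-tied scores collapse to the two diagonal endpoints
  roc <- roc_points(c(1, 0, 1, 0), rep(0.5, 4))
  expect_equal(nrow(roc), 2L)
  expect_equal(roc$fpr, c(0, 1))
  expect_equal(roc$tpr, c(0, 1))

  # 3 of 4 positive/negative pairs concordant -> AUC 0.75
  auc <- sadagrad:::trapezoid_auc(roc_points(c(1, 0, 1, 0),
                                             c(0.9, 0.8, 0.3, 0.2)))
  expect_equal(auc, 0.75)

  expect_error(roc_points(c(1, 1), c(0.2, 0.4)), "positive and one negative")
})

test_that("one-vs-rest AUC: perfect separation, tie convention, undefined
           classes", {
  y <- c("a", "a", "b", "b", "c", "c")
  S <- matrix(0, 6, 3, dimnames = list(NULL, NULL))
  S[cbind(1:6, rep(1:3, each = 2))] <- 1
  expect_equal(unname(auc_ovr(y, S, c("a", "b", "c"))), c(1, 1, 1))

  # constant scores give AUC 0.5 for every class
  expect_equal(unname(auc_ovr(y, matrix(0.3, 6, 3), c("a", "b", "c"))),
               rep(0.5, 3))

  # a class absent from y_true is flagged NA, not an error
  out <- auc_ovr(c("a", "a", "b"), matrix(rnorm(9), 3, 3), c("a", "b", "c"))
  expect_true(is.na(out[["c"]]))
  expect_false(anyNA(out[c("a", "b")]))
})

test_that("metrics agree with raw-count and pair-count oracles on random
           instances", {
  for (i in 1:60) {
    inst <- random_metric_instance(n = sample(10:120, 1),
                                   K = sample(2:8, 1), seed = 1000 + i)
    r <- aggregate_prf(per_class_prf(
      confusion_matrix(inst$y_true, inst$y_pred, inst$classes)))
    o <- oracle_prf(inst$y_true, inst$y_pred, inst$classes)
    expect_equal(r$per_class$precision, unname(o[, "precision"]),
                 tolerance = 1e-14)
    expect_equal(r$per_class$recall, unname(o[, "recall"]), tolerance = 1e-14)
    expect_equal(r$per_class$f1, unname(o[, "f1"]), tolerance = 1e-14)
    expect_equal(r$micro[["precision"]], mean(inst$y_true == inst$y_pred),
                 tolerance = 1e-14)
    auc <- auc_ovr(inst$y_true, inst$scores, inst$classes)
    for (k in inst$classes) {
      expect_equal(auc[[k]],
                   oracle_auc_pairs(as.integer(inst$y_true == k),
                                    inst$scores[, match(k, inst$classes)]),
                   tolerance = 1e-12)
    }
  }
})

test_that("metrics agree with the pROC and caret reference implementations", {
  skip_if_not_installed("pROC")
  skip_if_not_installed("caret")
  for (i in 1:5) {
    inst <- random_metric_instance(n = 80, K = 4, seed = 77 + i)
    auc <- auc_ovr(inst$y_true, inst$scores, inst$classes)
    for (k in inst$classes) {
      ref <- suppressMessages(pROC::auc(
        as.integer(inst$y_true == k),
        inst$scores[, match(k, inst$classes)],
        direction = "<", levels = c(0, 1)))
      expect_equal(auc[[k]], as.numeric(ref), tolerance = 1e-12)
    }
    r <- per_class_prf(confusion_matrix(inst$y_true, inst$y_pred,
                                        inst$classes))
    cc <- caret::confusionMatrix(
      factor(inst$y_pred, levels = inst$classes),
      factor(inst$y_true, levels = inst$classes))
    ref_prec <- cc$byClass[, "Pos Pred Value"]
    ref_rec <- cc$byClass[, "Sensitivity"]
    ref_prec[is.na(ref_prec)] <- 0
    expect_equal(r$per_class$precision, unname(ref_prec), tolerance = 1e-12)
    expect_equal(r$per_class$recall, unname(ref_rec), tolerance = 1e-12)
  }
})

test_that("metrics are invariant under consistent class permutation", {
  inst <- random_metric_instance(n = 90, K = 5, seed = 31)
  r1 <- aggregate_prf(per_class_prf(
    confusion_matrix(inst$y_true, inst$y_pred, inst$classes)))
  set.seed(1); perm <- sample(5)
  r2 <- aggregate_prf(per_class_prf(
    confusion_matrix(inst$y_true, inst$y_pred, inst$classes[perm])))
  m1 <- r1$per_class[match(inst$classes, r1$per_class$class), ]
  m2 <- r2$per_class[match(inst$classes, r2$per_class$class), ]
  rownames(m1) <- rownames(m2) <- NULL
  expect_equal(m1, m2)
  expect_equal(r1$micro, r2$micro)
  expect_equal(r1$macro, r2$macro)
  expect_equal(r1$weighted, r2$weighted)
})

test_that("class report CSV export round-trips the computed values", {
  inst <- random_metric_instance(n = 60, K = 3, seed = 99)
  r <- aggregate_prf(per_class_prf(
    confusion_matrix(inst$y_true, inst$y_pred, inst$classes)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_class_report_csv(r, path, digits = 6)
  back <- read.csv(path, check.names = FALSE)
  expect_equal(nrow(back), 3 + 3)
  expect_equal(back$Precision[1:3], round(r$per_class$precision, 6))
  expect_equal(back$Support[4], r$total_support)
  expect_equal(back$`F1-score`[5], round(r$macro[["f1"]], 6))
})
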