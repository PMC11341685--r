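#' Multiclass confusion matrix
#'
#' Rows are true classes, columns predicted classes, in the order given by
#' `class_names`.
#'
#' @param y_true,y_pred label vectors of equal length; every label must occur
#'   in `class_names`.
#' @param class_names the K class labels fixing row/column order.
#' @return an object of class `confusion` holding the K x K integer `counts`
#'   and `class_names`.
#' @export
confusion_matrix <- function(y_true, y_pred, class_names) {
  if (length(y_true) != length(y_pred))
    stop("`y_true` and `y_pred` must have equal length")
  class_names <- as.character(class_names)
  if (anyDuplicated(class_names)) stop("`class_names` must be unique")
  bad <- setdiff(unique(c(as.character(y_true), as.character(y_pred))),
                 class_names)
  if (length(bad) > 0L)
    stop("unknown label(s) not in `class_names`: ", paste(bad, collapse = ", "))
  ft <- factor(as.character(y_true), levels = class_names)
  fp <- factor(as.character(y_pred), levels = class_names)
  counts <- table(true = ft, predicted = fp)
  counts <- matrix(as.integer(counts), nrow = length(class_names),
                   dimnames = list(true = class_names,
                                   predicted = class_names))
  structure(list(counts = counts, class_names = class_names),
            class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  print(x$counts)
  invisible(x)
}

#' Per-class precision, recall, F1 and support
#'
#' For each class \eqn{c}: precision \eqn{TP/(TP+FP)}, recall
#' \eqn{TP/(TP+FN)}, and \eqn{F_1 = 2TP/(2TP+FP+FN)}; a zero denominator
#' yields 0 by convention (needed for degenerate runs where a class is never
#' predicted). Support is the number of true samples of the class.
#'
#' @param cm a [confusion_matrix()].
#' @return an object of class `class_report`: data frame `per_class` with
#'   columns `class, tp, fp, fn, precision, recall, f1, support`, plus
#'   `total_support`. Aggregate rows are filled by [aggregate_prf()].
#' @export
per_class_prf <- function(cm) {
  stopifnot(inherits(cm, "confusion"))
  tp <- diag(cm$counts)
  fp <- colSums(cm$counts) - tp
  fn <- rowSums(cm$counts) - tp
  support <- rowSums(cm$counts)
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  per_class <- data.frame(
    class = cm$class_names,
    tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
    precision = safe_div(tp, tp + fp),
    recall = safe_div(tp, tp + fn),
    f1 = safe_div(2 * tp, 2 * tp + fp + fn),
    support = as.integer(support),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(per_class = per_class,
                 total_support = sum(per_class$support),
                 micro = NULL, macro = NULL, weighted = NULL),
            class = "class_report")
}

#' Micro / macro / weighted aggregation
#'
#' Fills the three aggregate triples of a class report:
#' * micro -- pooled TP/FP/FN across classes; for single-label multiclass
#'   data micro precision = micro recall = micro F1 = overall accuracy;
#' * macro -- unweighted mean of the per-class triples (equal weight per
#'   class regardless of imbalance);
#' * weighted -- support-weighted mean of the per-class triples.
#'
#' @param report a `class_report` with the per-class part populated.
#' @return the report with `micro`, `macro`, `weighted` filled (each a named
#'   numeric vector `precision`, `recall`, `f1`).
#' @export
aggregate_prf <- function(report) {
  stopifnot(inherits(report, "class_report"))
  pc <- report$per_class
  if (report$total_support <= 0)
    stop("cannot aggregate a report with zero total support")
  triple <- function(p, r, f) c(precision = p, recall = r, f1 = f)
  tp <- sum(pc$tp); fp <- sum(pc$fp); fn <- sum(pc$fn)
  micro_p <- if (tp + fp > 0) tp / (tp + fp) else 0
  micro_r <- if (tp + fn > 0) tp / (tp + fn) else 0
  micro_f <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  report$micro <- triple(micro_p, micro_r, micro_f)
  report$macro <- triple(mean(pc$precision), mean(pc$recall), mean(pc$f1))
  w <- pc$support / report$total_support
  report$weighted <- triple(sum(w * pc$precision), sum(w * pc$recall),
                            sum(w * pc$f1))
  report
}

#' @export
print.class_report <- function(x, digits = 2, ...) {
  pc <- x$per_class
  out <- data.frame(Class = pc$class,
                    Precision = round(pc$precision, digits),
                    Recall = round(pc$recall, digits),
                    `F1-score` = round(pc$f1, digits),
                    Support = pc$support, check.names = FALSE)
  print(out, row.names = FALSE)
  for (nm in c("micro", "macro", "weighted")) {
    if (!is.null(x[[nm]]))
      cat(sprintf("%-16s %.2f  %.2f  %.2f  %d\n",
                  paste0(toupper(substring(nm, 1, 1)), substring(nm, 2),
                         " average"),
                  x[[nm]]["precision"], x[[nm]]["recall"], x[[nm]]["f1"],
                  x$total_support))
  }
  invisible(x)
}

#' ROC curve points for a binary problem
#'
#' Sweeps the decision threshold over the distinct scores in descending
#' order; tied scores collapse to a single threshold. The returned curve
#' starts at (0, 0) and ends at (1, 1).
#'
#' @param y_true_binary 0/1 vector with at least one positive and one
#'   negative.
#' @param scores numeric vector of classifier scores (higher = more
#'   positive).
#' @return data frame with columns `fpr`, `tpr`, `threshold` (the threshold
#'   of the (0,0) anchor is `Inf`).
#' @export
roc_points <- function(y_true_binary, scores) {
  y <- as.integer(y_true_binary)
  if (length(y) != length(scores)) stop("length mismatch")
  if (!all(y %in% c(0L, 1L))) stop("`y_true_binary` must be 0/1")
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC requires at least one positive and one negative sample")
  if (any(!is.finite(scores))) stop("scores must be finite")
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  # index of the last sample at each distinct threshold
  last <- which(c(diff(s) != 0, TRUE))
  ctp <- cumsum(y == 1L)[last]
  cfp <- cumsum(y == 0L)[last]
  data.frame(fpr = c(0, cfp / n_neg), tpr = c(0, ctp / n_pos),
             threshold = c(Inf, s[last]))
}

# Trapezoidal area under a (fpr, tpr) curve.
trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' One-vs-rest AUC per class
#'
#' For each class the class-k column of the score matrix is scored against
#' the binary indicator "true class == k"; the AUC is the trapezoidal area
#' under [roc_points()], which equals the tie-corrected concordant-pair
#' (Mann-Whitney) fraction. Classes with no positives or no negatives in
#' `y_true` get `NA` (flagged, not an error).
#'
#' @param y_true label vector.
#' @param score_matrix n x K numeric matrix of per-class scores (finite).
#' @param class_names K class labels naming the columns.
#' @return named numeric vector of per-class AUCs (NA where undefined).
#' @export
auc_ovr <- function(y_true, score_matrix, class_names) {
  class_names <- as.character(class_names)
  score_matrix <- as.matrix(score_matrix)
  if (nrow(score_matrix) != length(y_true) ||
      ncol(score_matrix) != length(class_names))
    stop("`score_matrix` must be n x K for n labels and K classes")
  if (any(!is.finite(score_matrix))) stop("scores must be finite")
  y <- as.character(y_true)
  out <- stats::setNames(rep(NA_real_, length(class_names)), class_names)
  for (k in seq_along(class_names)) {
    pos <- as.integer(y == class_names[k])
    if (sum(pos) == 0L || sum(pos) == length(pos)) next
    out[k] <- trapezoid_auc(roc_points(pos, score_matrix[, k]))
  }
  out
}

#' Write a class report as CSV
#'
#' One row per class plus the three aggregate rows, mirroring the usual
#' per-class metric table layout (Class, Precision, Recall, F1-score,
#' Support).
#'
#' @param report an aggregated `class_report`.
#' @param path output file path.
#' @param digits rounding applied to the metric columns (default 4).
#' @return `path`, invisibly.
#' @export
write_class_report_csv <- function(report, path, digits = 4) {
  stopifnot(inherits(report, "class_report"))
  if (is.null(report$micro)) report <- aggregate_prf(report)
  pc <- report$per_class
  rows <- data.frame(Class = pc$class,
                     Precision = round(pc$precision, digits),
                     Recall = round(pc$recall, digits),
                     `F1-score` = round(pc$f1, digits),
                     Support = pc$support, check.names = FALSE)
  agg <- function(nm, label) {
    data.frame(Class = label,
               Precision = round(report[[nm]][["precision"]], digits),
               Recall = round(report[[nm]][["recall"]], digits),
               `F1-score` = round(report[[nm]][["f1"]], digits),
               Support = report$total_support, check.names = FALSE)
  }
  rows <- rbind(rows, agg("micro", "Micro average"),
                agg("macro", "Macro average"),
                agg("weighted", "Weighted average"))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a class report to JSON
#'
#' @param report an aggregated `class_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_class_report_json <- function(report, path) {
  stopifnot(inherits(report, "class_report"))
  if (is.null(report$micro)) report <- aggregate_prf(report)
  jsonlite::write_json(
    list(per_class = report$per_class,
         micro = as.list(report$micro), macro = as.list(report$macro),
         weighted = as.list(report$weighted),
         total_support = report$total_support),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
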