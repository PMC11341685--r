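#' The eight colorectal tissue classes
#'
#' Class order used throughout the package for the synthetic benchmark and
#' the packaged metric-table fixtures: TUMOUR, STROMA, COMPLEX, LYMPHO,
#' DEBRIS, MUCOSA, ADIPOSE, EMPTY (indices 0-7).
#'
#' @return character vector of length 8.
#' @export
crc_class_names <- function() {
  c("TUMOUR", "STROMA", "COMPLEX", "LYMPHO", "DEBRIS", "MUCOSA",
    "ADIPOSE", "EMPTY")
}

#' Load a packaged per-class metric table
#'
#' The package ships the per-class precision/recall/F1/support values of the
#' published Adam and Adagrad evaluation tables for the eight-class
#' colorectal-tissue task (64 held-out samples each). The corresponding
#' SAdagrad table is deliberately not packaged: its per-class supports sum to
#' 50 while its aggregate rows claim 64 samples, an internal inconsistency
#' that makes the row set unusable as ground truth.
#'
#' @param table_id `"adam"` or `"adagrad"`.
#' @return a `class_report` whose `per_class` part holds the printed values
#'   verbatim (TP/FP/FN are `NA` until [recompute_report()] reconstructs
#'   them); the printed aggregate rows are attached as the
#'   `printed_aggregates` field for comparison.
#' @export
load_table_fixture <- function(table_id) {
  if (identical(table_id, "sadagrad"))
    stop("the SAdagrad table is not packaged: its per-class supports sum ",
         "to 50 but its aggregate rows claim 64 samples (internally ",
         "inconsistent)")
  if (!table_id %in% c("adam", "adagrad"))
    stop("unknown table id '", table_id, "'; available: \"adam\", \"adagrad\"")
  path <- system.file("extdata", paste0("table_", table_id, ".csv"),
                      package = "sadagrad", mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  cls <- raw[raw$row == "class", ]
  per_class <- data.frame(
    class = cls$class,
    tp = NA_integer_, fp = NA_integer_, fn = NA_integer_,
    precision = cls$precision, recall = cls$recall, f1 = cls$f1,
    support = as.integer(cls$support),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(per_class = per_class,
                 total_support = sum(per_class$support),
                 micro = NULL, macro = NULL, weighted = NULL,
                 printed_aggregates = raw[raw$row == "aggregate", -1]),
            class = "class_report")
}

#' Round half away from zero
#'
#' The rounding convention used when reproducing printed metric tables
#' (base R's `round()` rounds half to even). A tiny epsilon shields exact
#' halves from binary representation error.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  y <- abs(x) * p
  sign(x) * floor(y + 0.5 + 1e-12 * pmax(1, y)) / p
}

#' Recompute a printed metric table from its per-class rows
#'
#' Given only the printed per-class precision, recall and support values,
#' reconstructs the integer confusion counts
#' \eqn{TP_c = \mathrm{round}(recall_c \cdot support_c)},
#' \eqn{FN_c = support_c - TP_c},
#' \eqn{FP_c = \mathrm{round}(TP_c/precision_c) - TP_c},
#' recomputes every per-class F1 as \eqn{2TP/(2TP+FP+FN)}, and fills the
#' micro (pooled counts), macro (unweighted mean) and weighted
#' (support-weighted mean) aggregate rows. The macro/weighted precision and
#' recall average the printed per-class values; the F1 aggregates use the
#' exact recomputed F1. All reported metrics are rounded half away from zero
#' to `rounding` places.
#'
#' @param fixture a `class_report` with the per-class part populated (e.g.
#'   from [load_table_fixture()]).
#' @param rounding decimal places for the reported values (default 2, the
#'   precision the published tables print).
#' @return a `class_report` with integer counts, recomputed F1, and all
#'   aggregate rows filled and rounded.
#' @export
recompute_report <- function(fixture, rounding = 2) {
  stopifnot(inherits(fixture, "class_report"))
  pc <- fixture$per_class
  tp <- as.integer(round(pc$recall * pc$support))
  fn <- pc$support - tp
  fp <- ifelse(pc$precision > 0,
               as.integer(round(tp / pc$precision)) - tp,
               0L)
  f1_exact <- ifelse(2 * tp + fp + fn > 0,
                     2 * tp / (2 * tp + fp + fn), 0)
  out <- fixture
  out$per_class$tp <- tp
  out$per_class$fp <- as.integer(fp)
  out$per_class$fn <- as.integer(fn)
  out$per_class$f1 <- round_half_away(f1_exact, rounding)
  tot <- sum(pc$support)
  TP <- sum(tp); FP <- sum(fp); FN <- sum(fn)
  triple <- function(p, r, f)
    round_half_away(c(precision = p, recall = r, f1 = f), rounding)
  out$micro <- triple(TP / (TP + FP), TP / (TP + FN),
                      2 * TP / (2 * TP + FP + FN))
  out$macro <- triple(mean(pc$precision), mean(pc$recall), mean(f1_exact))
  w <- pc$support / tot
  out$weighted <- triple(sum(w * pc$precision), sum(w * pc$recall),
                         sum(w * f1_exact))
  out$total_support <- tot
  out
}
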