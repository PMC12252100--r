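# Confusion matrix and the five-metric suite with the published table
# conventions: per-class one-vs-rest precision/recall/F1/specificity, the
# per-class "accuracy" column equal to recall, and an aggregate ("Sum") row
# of macro means except for accuracy, which is the overall trace/total.

#' Round half away from zero
#'
#' The reported tables round halves upward; base `round()` rounds half to
#' even, so reported cells go through this helper.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 4) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Build a 5 x 5 confusion matrix
#'
#' Rows are true classes, columns predicted classes, both in the order
#' N, S, V, F, Q.
#'
#' @param true true labels (AAMI characters or factor).
#' @param pred predicted labels.
#' @return integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(true, pred) {
  true <- factor(as.character(true), levels = AAMI_CLASSES)
  pred <- factor(as.character(pred), levels = AAMI_CLASSES)
  if (length(true) != length(pred)) stopf("true and pred lengths differ")
  if (anyNA(true) || anyNA(pred)) stopf("labels must all be AAMI classes")
  cm <- table(true = true, pred = pred)
  structure(unclass(cm), class = c("confusion_matrix", "matrix"))
}

# one-vs-rest counts for class index i
ovr_counts <- function(cm, i) {
  tp <- cm[i, i]
  fn <- sum(cm[i, ]) - tp
  fp <- sum(cm[, i]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(tp = tp, fn = fn, fp = fp, tn = tn)
}

safe_ratio <- function(num, den) if (den == 0) 0 else num / den

#' Per-class metrics from a confusion matrix
#'
#' One-vs-rest TP/FP/TN/FN per class; precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, F1 their harmonic mean, specificity `TN/(TN+FP)`. The
#' per-class accuracy column equals recall (the published table convention,
#' which is nonstandard but matches every printed per-class row).
#' Zero-denominator cells are reported as 0 and flagged.
#'
#' @param cm a [confusion_matrix()].
#' @return data.frame with one row per class and a `zero_denominator` flag.
#' @export
per_class_metrics <- function(cm) {
  if (sum(cm) == 0) stopf("confusion matrix is empty")
  rows <- lapply(seq_along(AAMI_CLASSES), function(i) {
    ct <- ovr_counts(cm, i)
    recall <- safe_ratio(ct["tp"], ct["tp"] + ct["fn"])
    precision <- safe_ratio(ct["tp"], ct["tp"] + ct["fp"])
    f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
    specificity <- safe_ratio(ct["tn"], ct["tn"] + ct["fp"])
    data.frame(class = AAMI_CLASSES[i],
               accuracy = unname(recall), # table convention: accuracy = recall
               f1 = unname(f1), recall = unname(recall),
               precision = unname(precision), specificity = unname(specificity),
               support = unname(ct["tp"] + ct["fn"]),
               zero_denominator = (ct["tp"] + ct["fn"] == 0) ||
                 (ct["tp"] + ct["fp"] == 0) || (ct["tn"] + ct["fp"] == 0))
  })
  do.call(rbind, rows)
}

#' Aggregate ("Sum") row of a metrics report
#'
#' Macro (unweighted) means of the per-class F1, recall, precision and
#' specificity, each rounded half-up to 4 decimals; the accuracy cell is the
#' overall accuracy `trace(cm) / total`, not a macro mean — the only
#' convention that reproduces the published summary rows.
#'
#' @param report a [per_class_metrics()] data.frame (or any data.frame with
#'   `f1`, `recall`, `precision`, `specificity` columns).
#' @param cm the [confusion_matrix()] the report came from, or `NULL` to
#'   omit the overall-accuracy cell.
#' @param digits rounding for reported cells.
#' @return one-row data.frame.
#' @export
aggregate_metrics <- function(report, cm = NULL, digits = 4) {
  out <- data.frame(class = "Sum",
                    accuracy = if (is.null(cm)) NA_real_ else
                      round_half_up(sum(diag(cm)) / sum(cm), digits),
                    f1 = round_half_up(mean(report$f1), digits),
                    recall = round_half_up(mean(report$recall), digits),
                    precision = round_half_up(mean(report$precision), digits),
                    specificity = round_half_up(mean(report$specificity), digits))
  out
}

#' Full metrics report in the published table layout
#'
#' @param cm a [confusion_matrix()].
#' @param digits rounding for reported cells.
#' @return data.frame with five per-class rows plus the `Sum` aggregate row,
#'   of class `metrics_report`; the unrounded per-class table is kept in
#'   attribute `raw`.
#' @export
metrics_report <- function(cm, digits = 4) {
  pc <- per_class_metrics(cm)
  agg <- aggregate_metrics(pc, cm, digits)
  shown <- pc[, c("class", "accuracy", "f1", "recall", "precision", "specificity")]
  shown[, -1] <- lapply(shown[, -1], round_half_up, digits = digits)
  out <- rbind(shown, agg)
  rownames(out) <- NULL
  structure(out, raw = pc, cm = cm, class = c("metrics_report", "data.frame"))
}

#' Macro F1 from a confusion matrix
#' @param cm a [confusion_matrix()].
#' @return unweighted mean of the per-class F1 scores.
#' @export
macro_f1 <- function(cm) mean(per_class_metrics(cm)$f1)
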