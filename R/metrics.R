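#' Confusion matrix of true vs predicted labels
#'
#' Rows are true labels, columns predicted labels, both over the union of
#' the observed label sets so that `"unknown"` and `"unassigned"` count as
#' ordinary labels (errors unless true).
#'
#' @param truth,pred label vectors named by cell id (or unnamed and
#'   aligned). Must cover the same cells.
#' @return an integer matrix with aligned dimnames.
#' @export
confusionMatrix <- function(truth, pred) {
  if (!is.null(names(truth)) && !is.null(names(pred))) {
    if (!setequal(names(truth), names(pred)))
      stop("truth and prediction cover different cell sets")
    pred <- pred[names(truth)]
  } else if (length(truth) != length(pred)) {
    stop("truth and prediction have different lengths")
  }
  levels <- sort(union(unique(truth), unique(pred)))
  t_f <- factor(truth, levels = levels)
  p_f <- factor(pred, levels = levels)
  unclass(table(true = t_f, predicted = p_f))
}

#' Multiclass evaluation metrics from a confusion matrix
#'
#' Computes the four standard annotation metrics. With \eqn{TP_t},
#' \eqn{FP_t}, \eqn{FN_t} the per-type counts, \eqn{Row_t}, \eqn{Col_t}
#' the marginals of the T x T matrix and n the number of cells:
#' \itemize{
#'   \item accuracy \eqn{= \sum_t TP_t / n};
#'   \item balanced accuracy = mean over types of
#'     \eqn{Recall_t = TP_t / (TP_t + FN_t)};
#'   \item macro F1 = harmonic mean of the macro-averaged precision and
#'     the macro-averaged recall (note: not the mean of per-class F1
#'     scores; set `macroF1 = "mean_of_f1"` for that variant);
#'   \item multiclass MCC
#'     \eqn{= (n\sum_t TP_t - \sum_t Col_t Row_t) /
#'       \sqrt{(n^2 - \sum_t Col_t^2)(n^2 - \sum_t Row_t^2)}}.
#' }
#' A type never present in truth contributes recall 0, one never predicted
#' contributes precision 0, and a zero MCC denominator yields MCC 0; all
#' three conventions are logged rather than silent.
#'
#' @param cm confusion matrix from [confusionMatrix()] (rows = true).
#' @param macroF1 `"harmonic_of_means"` (default) or `"mean_of_f1"`.
#' @return named numeric: `accuracy`, `balanced_accuracy`, `macro_f1`,
#'   `mcc`.
#' @export
evaluateAnnotation <- function(cm,
                               macroF1 = c("harmonic_of_means",
                                           "mean_of_f1")) {
  macroF1 <- match.arg(macroF1)
  stopifnot(nrow(cm) == ncol(cm), sum(cm) > 0)
  n <- sum(cm)
  tp <- diag(cm)
  row_t <- rowSums(cm)   # TP + FN
  col_t <- colSums(cm)   # TP + FP

  recall <- ifelse(row_t > 0, tp / row_t, 0)
  if (any(row_t == 0))
    acam_log("type(s) absent from truth given recall 0: ",
             paste(rownames(cm)[row_t == 0], collapse = ", "),
             stage = "metrics")
  precision <- ifelse(col_t > 0, tp / col_t, 0)
  if (any(col_t == 0))
    acam_log("type(s) never predicted given precision 0: ",
             paste(rownames(cm)[col_t == 0], collapse = ", "),
             stage = "metrics")

  avg_p <- mean(precision)
  avg_r <- mean(recall)
  f1 <- if (macroF1 == "harmonic_of_means") {
    if (avg_p + avg_r == 0) 0 else 2 * avg_p * avg_r / (avg_p + avg_r)
  } else {
    per_class <- ifelse(precision + recall > 0,
                        2 * precision * recall / (precision + recall), 0)
    mean(per_class)
  }

  mcc_num <- sum(tp) * n - sum(col_t * row_t)
  mcc_den <- sqrt(n^2 - sum(col_t^2)) * sqrt(n^2 - sum(row_t^2))
  mcc <- if (mcc_den == 0) {
    acam_log("MCC denominator zero; reporting 0", stage = "metrics")
    0
  } else mcc_num / mcc_den

  c(accuracy = sum(tp) / n,
    balanced_accuracy = avg_r,
    macro_f1 = f1,
    mcc = mcc)
}
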