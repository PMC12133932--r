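#' Per-class confusion counts for a multiclass labeling
#'
#' @param y_true,y_pred integer labels in `[0, K)`, equal length.
#' @param K number of classes; inferred from the data when `NULL`.
#' @return a `confusion_counts`: list with per-class vectors `tp`, `fp`,
#'   `fn`, `tn`, plus `K` and `total`.
#' @export
confusion_counts <- function(y_true, y_pred, K = NULL) {
  if (length(y_true) != length(y_pred) || !length(y_true))
    stopf("value error: y_true and y_pred must be equal, non-zero length")
  if (is.null(K)) K <- max(y_true, y_pred) + 1L
  if (any(y_true < 0 | y_true >= K | y_pred < 0 | y_pred >= K))
    stopf("value error: label outside [0, K)")
  total <- length(y_true)
  tp <- fp <- fn <- tn <- integer(K)
  for (k in seq_len(K) - 1L) {
    tp[k + 1L] <- sum(y_true == k & y_pred == k)
    fp[k + 1L] <- sum(y_true != k & y_pred == k)
    fn[k + 1L] <- sum(y_true == k & y_pred != k)
    tn[k + 1L] <- total - tp[k + 1L] - fp[k + 1L] - fn[k + 1L]
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 K = as.integer(K), total = total),
            class = "confusion_counts")
}

#' Multiclass accuracy and macro-averaged precision/recall/F1
#'
#' Accuracy is the share of correctly predicted samples (for the multiclass
#' one-vs-rest counts this equals the binary-style
#' `(TP+TN)/(TP+TN+FP+FN)` applied per class, which is constant across
#' classes). Macro metrics average the per-class precision
#' `TP_k/(TP_k+FP_k)`, recall `TP_k/(TP_k+FN_k)` and their harmonic mean
#' over all `K` classes; classes with a zero denominator contribute 0 (with
#' a warning), which keeps the macros defined under extreme class imbalance.
#'
#' @inheritParams confusion_counts
#' @return a `metric_report`: list with `acc`, `macro_f1`,
#'   `macro_precision`, `macro_recall` in `[0, 1]` and the underlying
#'   `counts`.
#' @export
compute_metrics <- function(y_true, y_pred, K = NULL) {
  cc <- confusion_counts(y_true, y_pred, K)
  acc <- sum(y_true == y_pred) / cc$total
  pden <- cc$tp + cc$fp
  rden <- cc$tp + cc$fn
  if (any(pden == 0) || any(rden == 0))
    warning("class with zero precision or recall denominator contributes 0",
            call. = FALSE)
  prec <- ifelse(pden > 0, cc$tp / pden, 0)
  rec <- ifelse(rden > 0, cc$tp / rden, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(list(acc = acc,
                 macro_f1 = mean(f1),
                 macro_precision = mean(prec),
                 macro_recall = mean(rec),
                 counts = cc),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("ACC %.4f  Macro-F1 %.4f  Macro-P %.4f  Macro-R %.4f\n",
              x$acc, x$macro_f1, x$macro_precision, x$macro_recall))
  invisible(x)
}
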