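# Evaluation: confusion matrices, macro classification metrics, and the BCS
# tolerance accuracies that reward near-misses between adjacent score levels.

#' Confusion matrix
#'
#' Rows are actual labels, columns predicted labels (entry `(a, p)` counts
#' samples with actual class `a` predicted as `p`).
#'
#' @param y_true,y_pred equal-length vectors of 0-based class indices.
#' @param K class count.
#' @return `K x K` integer matrix.
#' @export
confusion_matrix <- function(y_true, y_pred, K = 5L) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  if (any(c(y_true, y_pred) < 0) || any(c(y_true, y_pred) > K - 1) ||
      any(c(y_true, y_pred) %% 1 != 0))
    stop("class indices must be integers in 0..K-1")
  cm <- matrix(0L, K, K,
               dimnames = list(actual = 0:(K - 1), predicted = 0:(K - 1)))
  for (i in seq_along(y_true))
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  cm
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy is `trace / total`. Per-class precision is `diag / column sum`,
#' recall `diag / row sum`, F1 their harmonic mean, with the 0/0 -> 0
#' convention; precision, recall and F1 are macro-averaged over classes. All
#' metrics are percentages rounded to 2 decimals.
#'
#' @param cm confusion matrix from [confusion_matrix()].
#' @return list with `accuracy`, `macro_precision`, `macro_recall`,
#'   `macro_f1`.
#' @export
classification_report <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  dg <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, dg / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, dg / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(accuracy = round(100 * sum(dg) / total, 2),
       macro_precision = round(100 * mean(prec), 2),
       macro_recall = round(100 * mean(rec), 2),
       macro_f1 = round(100 * mean(f1), 2))
}

#' BCS tolerance accuracy
#'
#' Percentage of predictions whose BCS value lies within `tol` of the true
#' value (absolute difference, with a 1e-9 epsilon so 0.25-step float
#' arithmetic is robust). A tolerance of 0.25 admits adjacent classes.
#'
#' @param true_scores,pred_scores equal-length vectors of BCS values (from
#'   the five-value set 3.25 ... 4.25).
#' @param tol nonnegative tolerance.
#' @return percentage in `[0, 100]`.
#' @export
tolerance_accuracy <- function(true_scores, pred_scores, tol) {
  if (length(true_scores) != length(pred_scores))
    stop("score vectors must have equal length")
  if (tol < 0) stop("tol must be >= 0")
  check_scores <- function(s)
    if (any(vapply(s, function(v) min(abs(v - bcs_levels())), numeric(1)) > 1e-9))
      stop("scores must belong to the five-value BCS set")
  check_scores(true_scores); check_scores(pred_scores)
  100 * mean(abs(pred_scores - true_scores) <= tol + 1e-9)
}

#' Evaluate a model on a dataset
#'
#' @param model a `bcs_model` (or `bcs_fit`).
#' @param data list with `x` and `y` as in [train_model()].
#' @return an `eval_report`: confusion matrix, accuracy, macro
#'   precision/recall/F1, and tolerance accuracies at 0.25 and 0.5.
#' @export
evaluate_model <- function(model, data) {
  if (inherits(model, "bcs_fit")) model <- model$model
  pred <- max.col(batched_logits(model, data$x), ties.method = "first") - 1L
  cm <- confusion_matrix(data$y, pred, model$num_classes)
  rep <- classification_report(cm)
  lv <- bcs_levels()
  structure(c(rep, list(
    tolerance_accuracy_025 = tolerance_accuracy(lv[data$y + 1], lv[pred + 1], 0.25),
    tolerance_accuracy_05 = tolerance_accuracy(lv[data$y + 1], lv[pred + 1], 0.5),
    confusion = cm, n = length(data$y))), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> n =", x$n, "\n")
  cat(sprintf("  accuracy %.2f%%  macro P %.2f%%  R %.2f%%  F1 %.2f%%\n",
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1))
  cat(sprintf("  BCS +/-0.25: %.2f%%   +/-0.5: %.2f%%\n",
              x$tolerance_accuracy_025, x$tolerance_accuracy_05))
  print(x$confusion)
  invisible(x)
}
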