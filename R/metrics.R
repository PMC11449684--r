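#' Multiclass confusion matrix
#'
#' `counts[i, j]` is the number of samples whose true class is `i` and
#' predicted class is `j` (labels are integers in `1..K`).
#'
#' @param y_true,y_pred Integer vectors of equal length with values in
#'   `1..K` (factors are accepted and converted).
#' @param k Number of classes; defaults to the largest label seen.
#' @param class_names Optional class names for dimnames.
#' @return A `confusion_matrix` object: an integer `K x K` matrix with
#'   rows = true class, columns = predicted class.
#' @export
confusion <- function(y_true, y_pred, k = NULL, class_names = NULL) {
  if (is.factor(y_true)) y_true <- as.integer(y_true)
  if (is.factor(y_pred)) y_pred <- as.integer(y_pred)
  stopifnot(length(y_true) == length(y_pred))
  if (is.null(k)) k <- max(y_true, y_pred)
  if (any(c(y_true, y_pred) < 1) || any(c(y_true, y_pred) > k))
    stop("labels must lie in 1..", k, call. = FALSE)
  cm <- matrix(0L, k, k)
  for (i in seq_along(y_true))
    cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1L
  if (is.null(class_names)) class_names <- as.character(seq_len(k))
  dimnames(cm) <- list(true = class_names, predicted = class_names)
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' One-vs-rest counts and metrics for a single class
#'
#' Reduces the confusion matrix to the binary problem "class `k` vs the
#' rest" and computes precision `TP / (TP + FP)` and recall (sensitivity)
#' `TP / (TP + FN)`.  A zero denominator yields `NA` (undefined, not 0).
#'
#' @param cm A [confusion()] matrix.
#' @param k Class index.
#' @return List with `tp`, `fp`, `fn`, `tn`, `precision`, `recall`.
#' @export
per_class <- function(cm, k) {
  stopifnot(inherits(cm, "confusion_matrix"), k >= 1, k <= nrow(cm))
  tp <- cm[k, k]
  fn <- sum(cm[k, ]) - tp
  fp <- sum(cm[, k]) - tp
  tn <- sum(cm) - tp - fn - fp
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

#' Overall accuracy of a confusion matrix
#'
#' `(TP + TN) / (TP + TN + FP + FN)` over all classes, i.e.
#' `trace / total`.
#'
#' @param cm A [confusion()] matrix.
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"), sum(cm) > 0)
  sum(diag(cm)) / sum(cm)
}

#' F1 score (harmonic mean of precision and recall)
#'
#' `2 * P * R / (P + R)`; `NA` when `P + R` is zero or either input is
#' undefined.
#'
#' @param precision,recall Values in `[0, 1]`.
#' @return F1 in `[0, 1]` or `NA`.
#' @export
f1_score <- function(precision, recall) {
  if (is.na(precision) || is.na(recall)) return(NA_real_)
  if (precision + recall == 0) return(NA_real_)
  2 * precision * recall / (precision + recall)
}

#' Macro-averaged F1 over classes
#'
#' Unweighted mean of per-class F1 scores over the classes whose F1 is
#' defined.
#'
#' @param cm A [confusion()] matrix.
#' @return Macro F1 in `[0, 1]`.
#' @export
macro_f1 <- function(cm) {
  f1s <- vapply(seq_len(nrow(cm)), function(k) {
    p <- per_class(cm, k)
    f1_score(p$precision, p$recall)
  }, numeric(1))
  mean(f1s, na.rm = TRUE)
}

#' Per-class metrics table
#'
#' One row per class with one-vs-rest counts, precision, recall and F1.
#'
#' @param cm A [confusion()] matrix.
#' @return Data frame with columns `class`, `support`, `tp`, `fp`, `fn`,
#'   `tn`, `precision`, `recall`, `f1`.
#' @export
metrics_table <- function(cm) {
  rows <- lapply(seq_len(nrow(cm)), function(k) {
    p <- per_class(cm, k)
    data.frame(class = rownames(cm)[k], support = sum(cm[k, ]),
               tp = p$tp, fp = p$fp, fn = p$fn, tn = p$tn,
               precision = p$precision, recall = p$recall,
               f1 = f1_score(p$precision, p$recall))
  })
  do.call(rbind, rows)
}

#' Format a proportion as a percentage string
#'
#' One decimal place with round-half-up (so 84.666...% prints as
#' `"84.7"`, and 0.9 prints as `"90"` -- trailing `.0` is dropped).
#'
#' @param p Proportion in `[0, 1]`.
#' @param digits Decimal places (default 1).
#' @return Character scalar (without the `%` sign).
#' @export
format_pct <- function(p, digits = 1) {
  v <- floor(p * 100 * 10^digits + 0.5) / 10^digits  # round half up
  s <- formatC(v, format = "f", digits = digits)
  sub("\\.0+$", "", s)
}

#' ROC curve and AUC for binary scores
#'
#' Sweeps a threshold over the unique score values (tied scores are
#' grouped at a single threshold), producing the step curve from (0, 0)
#' to (1, 1), and integrates it by the trapezoidal rule.  With tied
#' scores the trapezoids make the AUC equal to the tie-corrected,
#' normalized Mann-Whitney U statistic.
#'
#' @param scores Numeric vector (higher means more positive).
#' @param labels Logical or 0/1 vector; must contain both classes.
#' @return List of class `roc_curve` with `fpr`, `tpr` (non-decreasing,
#'   from (0,0) to (1,1)), `thresholds`, and `auc` in `[0, 1]`.
#' @export
roc_and_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("both a positive and a negative label are required", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  # group tied scores: cumulative counts at each distinct threshold
  last_of_group <- c(diff(s) != 0, TRUE)
  tp <- cumsum(y)[last_of_group]
  fp <- cumsum(!y)[last_of_group]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr,
                 thresholds = c(Inf, s[last_of_group]), auc = auc),
            class = "roc_curve")
}

#' One-vs-rest ROC/AUC for every class
#'
#' @param probs `N x K` score matrix (e.g. softmax outputs).
#' @param labels Integer true labels in `1..K`.
#' @return List of K [roc_and_auc()] results, one per class.
#' @export
multiclass_roc <- function(probs, labels) {
  stopifnot(is.matrix(probs), nrow(probs) == length(labels))
  lapply(seq_len(ncol(probs)), function(k)
    roc_and_auc(probs[, k], labels == k))
}
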