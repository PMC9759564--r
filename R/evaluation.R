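#' Confusion matrix for a binary diagnosis
#'
#' Follows the clinical convention used throughout the package:
#' malignant (0) is the negative class, benign (1) the positive class, so
#' `tn` counts correctly identified malignant records.
#'
#' @param y_true,y_pred equal-length 0/1 vectors.
#' @return an object of class `"confusion_matrix"` with counts `tn`,
#'   `fp`, `fn`, `tp`.
#' @examples
#' confusion(c(0, 0, 1, 1), c(0, 1, 1, 1))
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have the same length")
  if (length(y_true) < 1L) stop("need at least one prediction")
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1)))
    stop("labels must be coded 0/1")
  confusion_matrix(tn = sum(y_true == 0 & y_pred == 0),
                   fp = sum(y_true == 0 & y_pred == 1),
                   fn = sum(y_true == 1 & y_pred == 0),
                   tp = sum(y_true == 1 & y_pred == 1))
}

#' @rdname confusion
#' @param tn,fp,fn,tp non-negative counts.
#' @export
confusion_matrix <- function(tn, fp, fn, tp) {
  counts <- c(tn = tn, fp = fp, fn = fn, tp = tp)
  if (any(counts < 0) || sum(counts) < 1) stop("invalid confusion counts")
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tn, x$fp, x$fn, x$tp), 2L, byrow = TRUE,
              dimnames = list(c("real (0) malignant", "real (1) benign"),
                              c("pred 0", "pred 1")))
  print(m)
  invisible(x)
}

#' Diagnostic metrics from a confusion matrix
#'
#' Sensitivity `tp/(tp+fn)` is the proportion of positive (benign)
#' records correctly identified, specificity `tn/(tn+fp)` the proportion
#' of negative (malignant) records correctly identified; F1 is the
#' harmonic mean of precision `tp/(tp+fp)` and sensitivity, and accuracy
#' is `(tp+tn)/total`.  A zero denominator raises an explicit error
#' rather than silently reporting 0.
#'
#' @param cm a [confusion_matrix()].
#' @return an object of class `"eval_report"` with the four metrics as
#'   proportions in `[0, 1]` plus the matrix itself.
#' @export
eval_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$tp + cm$fn == 0) stop("sensitivity undefined: no positive records")
  if (cm$tn + cm$fp == 0) stop("specificity undefined: no negative records")
  if (cm$tp + cm$fp == 0) stop("F1 undefined: no positive predictions")
  total <- cm$tn + cm$fp + cm$fn + cm$tp
  sens <- cm$tp / (cm$tp + cm$fn)
  spec <- cm$tn / (cm$tn + cm$fp)
  prec <- cm$tp / (cm$tp + cm$fp)
  structure(list(accuracy = (cm$tp + cm$tn) / total,
                 sensitivity = sens, specificity = spec,
                 precision = prec,
                 f1 = 2 * prec * sens / (prec + sens),
                 matrix = cm),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> accuracy %.2f  sensitivity %.2f  ",
                     "specificity %.2f  F1 %.2f\n"),
              x$accuracy, x$sensitivity, x$specificity, x$f1))
  invisible(x)
}

#' Best/average summary over repeated evaluation attempts
#'
#' @param reports non-empty list of [eval_metrics()] reports, one per
#'   attempt.
#' @return list with `best` and `average` named vectors (proportions) for
#'   accuracy, sensitivity, specificity and F1, plus `percent`, the same
#'   rendered as percentages rounded to 2 decimals.
#' @export
summarize_reports <- function(reports) {
  if (length(reports) < 1L) stop("need at least one report")
  pull <- function(metric)
    vapply(reports, function(r) r[[metric]], numeric(1L))
  metrics <- c("accuracy", "sensitivity", "specificity", "f1")
  best <- vapply(metrics, function(m) max(pull(m)), numeric(1L))
  avg <- vapply(metrics, function(m) mean(pull(m)), numeric(1L))
  list(best = best, average = avg,
       percent = list(best = round(100 * best, 2),
                      average = round(100 * avg, 2)))
}
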