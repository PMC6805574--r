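# Patient-level and image-level evaluation.  The positive class is
# "malignant" throughout; metrics whose denominator vanishes are reported
# as NA (missing), never as 0.

#' Patient-level recognition rate
#'
#' Per patient, the patient score is `PS = N_rec / N_P` (correctly
#' classified images over that patient's test images); the patient-level
#' rate is the unweighted mean of the scores: `PL = sum(PS) / N_patient`.
#'
#' @param predictions data frame with columns `patient_id`, `true_label`,
#'   `pred_label`.
#' @return list with `PL` and a `patient_scores` data frame
#'   (`patient_id`, `N_P`, `N_rec`, `PS`).
#' @export
patient_level <- function(predictions) {
  if (!nrow(predictions)) stop("empty prediction table")
  ok <- predictions$true_label == predictions$pred_label
  agg <- aggregate(ok, by = list(patient_id = predictions$patient_id),
                   FUN = function(v) c(n = length(v), rec = sum(v)))
  ps <- data.frame(patient_id = agg$patient_id,
                   N_P = agg$x[, "n"], N_rec = agg$x[, "rec"])
  ps$PS <- ps$N_rec / ps$N_P
  list(PL = mean(ps$PS), patient_scores = ps)
}

#' Image-level recognition rate
#'
#' `IL = N_rec / N_all` pooled over all test images.
#'
#' @param predictions data frame with `true_label`, `pred_label`.
#' @return the image-level accuracy.
#' @export
image_level <- function(predictions) {
  if (!nrow(predictions)) stop("empty prediction table")
  mean(predictions$true_label == predictions$pred_label)
}

#' Confusion counts for a two-class prediction table
#'
#' @param true,pred label vectors.
#' @param positive name of the positive class (default `"malignant"`).
#' @return object of class `eval_counts`: list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(true, pred, positive = "malignant") {
  tp <- sum(true == positive & pred == positive)
  tn <- sum(true != positive & pred != positive)
  fp <- sum(true != positive & pred == positive)
  fn <- sum(true == positive & pred != positive)
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn), class = "eval_counts")
}

#' @export
print.eval_counts <- function(x, ...) {
  cat(sprintf("eval counts: TP=%d TN=%d FP=%d FN=%d\n", x$TP, x$TN, x$FP,
              x$FN))
  invisible(x)
}

#' Positive predictive value
#'
#' `PPV = TP / (TP + FP)`; `NA` when no positives were predicted.
#'
#' @param counts an [confusion_counts()] result.
#' @return numeric scalar or `NA`.
#' @export
ppv <- function(counts) {
  if (counts$TP + counts$FP == 0) return(NA_real_)
  counts$TP / (counts$TP + counts$FP)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(Acc - Acc_r) / (1 - Acc_r)` where `Acc_r`
#' is the marginal-product chance agreement
#' `p_pred_pos * p_true_pos + p_pred_neg * p_true_neg` from the observed
#' table.  `NA` when `Acc_r = 1`.
#'
#' @param counts an [confusion_counts()] result.
#' @return numeric scalar in `[-1, 1]` or `NA`.
#' @export
kappa <- function(counts) {
  n <- counts$TP + counts$TN + counts$FP + counts$FN
  if (n == 0) stop("empty contingency table")
  acc <- (counts$TP + counts$TN) / n
  p_true_pos <- (counts$TP + counts$FN) / n
  p_pred_pos <- (counts$TP + counts$FP) / n
  acc_r <- p_pred_pos * p_true_pos + (1 - p_pred_pos) * (1 - p_true_pos)
  if (abs(1 - acc_r) < 1e-12) return(NA_real_)
  (acc - acc_r) / (1 - acc_r)
}

#' F1 score, precision and recall
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`, `F1` their harmonic
#' mean; each is `NA` when its denominator vanishes.
#'
#' @param counts an [confusion_counts()] result.
#' @return named numeric vector `c(F1, precision, recall)`.
#' @export
f1_precision_recall <- function(counts) {
  precision <- if (counts$TP + counts$FP > 0)
    counts$TP / (counts$TP + counts$FP) else NA_real_
  recall <- if (counts$TP + counts$FN > 0)
    counts$TP / (counts$TP + counts$FN) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  c(F1 = f1, precision = precision, recall = recall)
}

#' ROC curve points and area
#'
#' Sweeps a decision threshold over the unique scores (higher score = more
#' positive) and returns the (FPR, TPR) points plus the trapezoid-rule area.
#'
#' @param scores numeric scores for the positive class.
#' @param labels logical or 0/1 vector (or class names, compared against
#'   `positive`).
#' @param positive positive class name, used when `labels` is character.
#' @return list with `points` (data frame `FPR`, `TPR`) and `auc`.
#' @export
roc_points <- function(scores, labels, positive = "malignant") {
  if (is.character(labels) || is.factor(labels))
    labels <- as.character(labels) == positive
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("ROC needs at least one positive and one negative")
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) sum(scores >= t & labels) / n_pos, 0)
  fpr <- vapply(th, function(t) sum(scores >= t & !labels) / n_neg, 0)
  pts <- data.frame(FPR = c(0, fpr, 1), TPR = c(0, tpr, 1))
  auc <- sum(diff(pts$FPR) * (head(pts$TPR, -1) + pts$TPR[-1]) / 2)
  list(points = pts, auc = auc)
}

#' Full metrics report from a prediction table
#'
#' Computes PL, IL, PPV, Cohen's kappa, F1 / precision / recall and the ROC
#' area from a prediction CSV (as written by [save_predictions()]).
#'
#' @param predictions data frame with `patient_id`, `true_label`,
#'   `pred_label` and (for the ROC) `P_malignant`.
#' @param positive positive class (default `"malignant"`).
#' @return named list of metrics.
#' @export
metrics_report <- function(predictions, positive = "malignant") {
  counts <- confusion_counts(predictions$true_label, predictions$pred_label,
                             positive)
  fpr <- f1_precision_recall(counts)
  auc <- if (!is.null(predictions$P_malignant) &&
             length(unique(predictions$true_label)) == 2L)
    roc_points(predictions$P_malignant, predictions$true_label,
               positive)$auc else NA_real_
  list(PL = patient_level(predictions)$PL,
       IL = image_level(predictions),
       PPV = ppv(counts), Kappa = kappa(counts),
       F1 = unname(fpr["F1"]), precision = unname(fpr["precision"]),
       recall = unname(fpr["recall"]), ROC_AUC = auc,
       counts = counts)
}

#' Write a metrics report as JSON
#' @param report a [metrics_report()] result.
#' @param path output JSON path.
#' @export
save_metrics_report <- function(report, path) {
  report$counts <- unclass(report$counts)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
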