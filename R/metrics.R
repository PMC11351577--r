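#' Three-class confusion matrix
#'
#' @param truth,pred Equal-length label vectors over
#'   normal/benign/malignant.
#' @param levels Class ordering (default [lesion_classes()]).
#' @return A 3x3 integer matrix, rows = true class, columns = predicted.
#' @export
confusion_3class <- function(truth, pred, levels = lesion_classes()) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) != length(pred)) {
    abort_validation("truth and pred must have equal length")
  }
  bad <- setdiff(unique(c(truth, pred)), levels)
  if (length(bad)) {
    abort_validation(sprintf("unknown labels: %s", paste(bad, collapse = ", ")))
  }
  m <- table(factor(truth, levels = levels), factor(pred, levels = levels))
  out <- matrix(as.integer(m), nrow = length(levels),
                dimnames = list(true = levels, predicted = levels))
  out
}

#' One-vs-rest collapse of a multi-class confusion matrix
#'
#' Reduces the 3x3 matrix to binary counts for a designated positive class:
#' TP = correctly predicted positives, FN = positives predicted as any other
#' class, FP = others predicted positive, TN = the remainder.
#'
#' @param matrix3 Square confusion matrix with dimnames.
#' @param positive Positive class name (default `"malignant"`).
#' @return A `confusion_counts` list with fields `TP`, `TN`, `FP`, `FN`.
#' @export
collapse_binary <- function(matrix3, positive = "malignant") {
  if (!positive %in% rownames(matrix3)) {
    abort_validation(sprintf("positive class '%s' not among matrix classes", positive))
  }
  i <- which(rownames(matrix3) == positive)
  tp <- matrix3[i, i]
  fn <- sum(matrix3[i, ]) - tp
  fp <- sum(matrix3[, i]) - tp
  tn <- sum(matrix3) - tp - fn - fp
  confusion_counts(tp, tn, fp, fn)
}

#' Binary confusion counts
#'
#' @param TP,TN,FP,FN Nonnegative counts.
#' @return A `confusion_counts` list.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0)) abort_validation("confusion counts must be nonnegative")
  structure(as.list(counts), class = "confusion_counts")
}

#' Full metric report from binary confusion counts
#'
#' Accuracy, sensitivity (recall), specificity, precision and F1 as
#' percentages, plus the Matthews correlation coefficient in `[-1, 1]`.
#' Undefined 0/0 ratios are reported as 0 and flagged in the
#' `zero_division` column rather than erroring, so batch evaluation stays
#' total.
#'
#' @param counts A `confusion_counts`, or `TP` given counts individually.
#' @param TN,FP,FN Counts when not passing a `confusion_counts`.
#' @return A one-row tibble: accuracy, sensitivity, specificity, precision,
#'   f1 (percent), mcc, zero_division flag.
#' @export
compute_metrics <- function(counts, TN = NULL, FP = NULL, FN = NULL) {
  if (!inherits(counts, "confusion_counts")) {
    counts <- confusion_counts(counts, TN, FP, FN)
  }
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  total <- tp + tn + fp + fn
  if (total <= 0) abort_validation("total count must be positive")
  flag <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) { flag <<- TRUE; 0 } else num / den
  }
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  prec <- safe_div(tp, tp + fp)
  f1 <- if (prec + sens == 0) { flag <- TRUE; 0 } else 2 * prec * sens / (prec + sens)
  mcc_den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) { flag <- TRUE; 0 } else {
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den
  }
  tibble(
    accuracy = 100 * (tp + tn) / total,
    sensitivity = 100 * sens,
    specificity = 100 * spec,
    precision = 100 * prec,
    f1 = 100 * f1,
    mcc = mcc,
    zero_division = flag
  )
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the unique score values as thresholds (ties grouped), computing
#' the true-positive rate against the false-positive rate, and integrates
#' the curve by the trapezoidal rule.
#'
#' @param truth Binary labels: logical, 0/1, or labels equal to `positive`.
#' @param scores Positive-class scores.
#' @param positive Positive label when `truth` is not logical/numeric.
#' @return A `qlung_roc` list: `points` tibble (`threshold`, `fpr`, `tpr`)
#'   and `auc`.
#' @export
roc_auc <- function(truth, scores, positive = "malignant") {
  if (is.character(truth) || is.factor(truth)) {
    truth <- as.character(truth) == positive
  }
  truth <- as.logical(truth)
  if (length(truth) != length(scores)) {
    abort_validation("truth and scores must have equal length")
  }
  np <- sum(truth); nn <- sum(!truth)
  if (np == 0 || nn == 0) {
    abort_validation("ROC needs both classes present")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & truth) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !truth) / nn, numeric(1))
  pts <- tibble(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  if (pts$fpr[nrow(pts)] < 1 || pts$tpr[nrow(pts)] < 1) {
    pts <- bind_rows(pts, tibble(threshold = -Inf, fpr = 1, tpr = 1))
  }
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, n_pos = np, n_neg = nn),
            class = "qlung_roc")
}

#' @export
print.qlung_roc <- function(x, ...) {
  cat(sprintf("<qlung_roc> AUC %.4f (%d positives, %d negatives, %d points)\n",
              x$auc, x$n_pos, x$n_neg, nrow(x$points)))
  invisible(x)
}

#' Evaluate a trained model on paired feature tables
#'
#' Computes predictions, the 3x3 confusion matrix, one-vs-rest collapsed
#' counts, the full metric report and the positive-class ROC.
#'
#' @param model A `qlung_model`.
#' @param cxr,ct Labelled per-modality feature tibbles.
#' @param positive_class One-vs-rest positive class (default `"malignant"`).
#' @return A `qlung_eval` list: `predictions`, `confusion`, `counts`,
#'   `metrics`, `roc`, `auc_per_class`.
#' @export
evaluate_model <- function(model, cxr, ct, positive_class = "malignant") {
  if (!"label" %in% names(cxr) || any(is.na(cxr$label))) {
    abort_validation("evaluation requires labelled feature tables")
  }
  preds <- predict(model, cxr, ct)
  conf <- confusion_3class(preds$label, preds$pred)
  counts <- collapse_binary(conf, positive = positive_class)
  metrics <- compute_metrics(counts)
  roc <- tryCatch(
    roc_auc(preds$label, preds[[paste0("p_", positive_class)]],
            positive = positive_class),
    error = function(e) NULL)
  auc_per_class <- purrr::map_dbl(setNames(model$label_levels,
                                           model$label_levels), function(cl) {
    tryCatch(roc_auc(preds$label, preds[[paste0("p_", cl)]],
                     positive = cl)$auc,
             error = function(e) NA_real_)
  })
  structure(
    list(predictions = preds, confusion = conf, counts = counts,
         metrics = metrics, roc = roc, auc_per_class = auc_per_class,
         positive_class = positive_class),
    class = "qlung_eval"
  )
}

#' @export
print.qlung_eval <- function(x, ...) {
  cat(sprintf("<qlung_eval> positive class: %s\n", x$positive_class))
  print(x$confusion)
  m <- x$metrics
  cat(sprintf("accuracy %.2f%% | sensitivity %.2f%% | specificity %.2f%% | precision %.2f%% | F1 %.2f%% | MCC %.3f\n",
              m$accuracy, m$sensitivity, m$specificity, m$precision, m$f1, m$mcc))
  if (!is.null(x$roc)) cat(sprintf("AUC (%s vs rest): %.4f\n",
                                   x$positive_class, x$roc$auc))
  invisible(x)
}
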