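#' Confusion counts at a score threshold
#'
#' A sample is called positive when its score is greater than or equal to
#' the threshold (equality counts as positive).
#'
#' @param scores Numeric score vector.
#' @param labels Binary labels (0/1 or logical), same length.
#' @param threshold Decision threshold, default 0.5.
#' @return A `kcr_confusion`: list with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels must have the same length")
  }
  if (length(scores) == 0L) stop("empty input")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary (0/1)")
  pred <- scores >= threshold
  structure(
    list(tp = sum(pred & labels == 1L), tn = sum(!pred & labels == 0L),
         fp = sum(pred & labels == 0L), fn = sum(!pred & labels == 1L)),
    class = "kcr_confusion"
  )
}

#' Sensitivity, specificity, accuracy and MCC from confusion counts
#'
#' `Sn = TP / (TP + FN)`, `Sp = TN / (TN + FP)`,
#' `Acc = (TP + TN) / (TP + TN + FP + FN)`,
#' `MCC = (TP * TN - FP * FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' A metric whose denominator is empty (no positives for Sn, no negatives
#' for Sp) is `NA`; MCC returns 0 when its denominator is 0 (the usual
#' convention for a degenerate margin).
#'
#' @param counts A [confusion()] result or a list with `tp`, `tn`, `fp`,
#'   `fn`.
#' @return Named list with `sn`, `sp`, `acc`, `mcc`.
#' @export
metrics_from_confusion <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  total <- tp + tn + fp + fn
  if (total == 0) stop("all confusion counts are zero")
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / total
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  list(sn = sn, sp = sp, acc = acc, mcc = mcc)
}

#' ROC curve and AUC
#'
#' The ROC curve is built by sweeping the threshold over the unique scores
#' (tied scores move as one group); the AUC is the trapezoidal area under
#' it, which with this tie handling equals the probability that a random
#' positive outscores a random negative, ties counting one half.
#'
#' @param scores Numeric score vector.
#' @param labels Binary labels (0/1 or logical); both classes must be
#'   present.
#' @return List with `roc` (data frame `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary (0/1)")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC needs both classes present (got ", n_pos, " positives, ",
         n_neg, " negatives)")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  cum_tp <- cumsum(l == 1L)
  cum_fp <- cumsum(l == 0L)
  last <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie group
  tpr <- c(0, cum_tp[last] / n_pos)
  fpr <- c(0, cum_fp[last] / n_neg)
  thr <- c(Inf, s[last])
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr, threshold = thr), auc = auc)
}

#' Full metric report from scores and labels
#'
#' @param scores Numeric score vector (e.g. positive-class probabilities).
#' @param labels Binary labels (0/1 or logical).
#' @param threshold Decision threshold for the confusion-matrix metrics,
#'   default 0.5 (AUC is threshold-free).
#' @return A `kcr_metrics`: list with `sn`, `sp`, `acc`, `mcc`, `auc`,
#'   `n_pos`, `n_neg`, the `confusion` counts and the `roc` points.
#' @export
evaluate <- function(scores, labels, threshold = 0.5) {
  cm <- confusion(scores, labels, threshold)
  m <- metrics_from_confusion(cm)
  r <- roc_auc(scores, labels)
  structure(
    c(m, list(auc = r$auc, n_pos = cm$tp + cm$fn, n_neg = cm$tn + cm$fp,
              threshold = threshold, confusion = cm, roc = r$roc)),
    class = "kcr_metrics"
  )
}

#' @export
as.data.frame.kcr_metrics <- function(x, ...) {
  data.frame(sn = x$sn, sp = x$sp, acc = x$acc, mcc = x$mcc, auc = x$auc,
             n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @export
print.kcr_metrics <- function(x, ...) {
  cat(sprintf("<kcr_metrics> n = %d+ / %d-  (threshold %.2f)\n",
              x$n_pos, x$n_neg, x$threshold))
  cat(sprintf("  Sn %.4f  Sp %.4f  Acc %.4f  MCC %.4f  AUC %.4f\n",
              x$sn, x$sp, x$acc, x$mcc, x$auc))
  invisible(x)
}

#' Write a metric report to CSV / JSON and ROC points to CSV
#'
#' @param metrics A `kcr_metrics`.
#' @param prefix Output path prefix; writes `<prefix>.csv`,
#'   `<prefix>.json` and `<prefix>_roc.csv`.
#' @return The paths, invisibly.
#' @export
write_metrics <- function(metrics, prefix) {
  csv <- paste0(prefix, ".csv")
  js <- paste0(prefix, ".json")
  roc <- paste0(prefix, "_roc.csv")
  utils::write.csv(as.data.frame(metrics), csv, row.names = FALSE)
  jsonlite::write_json(
    c(as.list(as.data.frame(metrics)),
      list(confusion = metrics$confusion[c("tp", "tn", "fp", "fn")])),
    js, auto_unbox = TRUE, digits = NA)
  utils::write.csv(metrics$roc, roc, row.names = FALSE)
  invisible(c(csv, js, roc))
}
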