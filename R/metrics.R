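# Confusion-matrix metrics and ROC/AUC used by the evaluation harness.

#' Binary confusion counts
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param positive_label The label treated as positive (warned about if it
#'   never occurs in `y_true`).
#' @return Object of class `confusion_counts` with `tp`, `fp`, `tn`, `fn`
#'   and the positive label.
#' @export
confusion <- function(y_true, y_pred, positive_label) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!positive_label %in% y_true) {
    warning("positive label '", positive_label, "' absent from y_true")
  }
  tp_ <- sum(y_true == positive_label & y_pred == positive_label)
  fp_ <- sum(y_true != positive_label & y_pred == positive_label)
  tn_ <- sum(y_true != positive_label & y_pred != positive_label)
  fn_ <- sum(y_true == positive_label & y_pred != positive_label)
  structure(list(tp = tp_, fp = fp_, tn = tn_, fn = fn_,
                 positive_label = positive_label),
            class = "confusion_counts")
}

safe_ratio <- function(num, den) {
  if (den == 0) list(value = 0, undefined = TRUE)
  else list(value = num / den, undefined = FALSE)
}

#' Classification metrics from confusion counts
#'
#' Computes accuracy, sensitivity (recall), specificity, precision,
#' F-measure, Matthews correlation coefficient, negative predictive value,
#' false positive rate and false negative rate from the four counts.
#' Ratios with a zero denominator are reported as 0 and listed in the
#' `undefined` attribute rather than raising (tiny test sets routinely
#' produce empty cells).
#'
#' @param c A `confusion_counts` object.
#' @return Object of class `metrics_report`: a named list of the nine
#'   metrics plus `counts` and `undefined` (character vector of
#'   zero-denominator metrics).
#' @export
compute_metrics <- function(c) {
  tp <- c$tp; fp <- c$fp; tn <- c$tn; fn <- c$fn
  und <- character(0)
  take <- function(name, num, den) {
    r <- safe_ratio(num, den)
    if (r$undefined) und <<- c(und, name)
    r$value
  }
  sens <- take("sensitivity", tp, tp + fn)
  spec <- take("specificity", tn, tn + fp)
  prec <- take("precision", tp, tp + fp)
  npv <- take("npv", tn, tn + fn)
  fnr <- take("fnr", fn, fn + tp)
  fpr <- take("fpr", fp, fp + tn)
  f1 <- take("f_measure", 2 * prec * sens, prec + sens)
  acc <- take("accuracy", tp + tn, tp + fp + fn + tn)
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) { und <- c(und, "mcc"); 0 }
         else (tn * tp - fn * fp) / mcc_den
  structure(list(accuracy = acc, sensitivity = sens, specificity = spec,
                 precision = prec, f_measure = f1, mcc = mcc, npv = npv,
                 fpr = fpr, fnr = fnr, counts = c, undefined = und),
            class = "metrics_report")
}

#' Multiclass metrics: one-vs-rest per class plus macro average
#'
#' @param y_true,y_pred Label vectors.
#' @return List with `per_class` (list of `metrics_report`), `macro`
#'   (named means over classes), and plain `accuracy`.
#' @export
multiclass_metrics <- function(y_true, y_pred) {
  classes <- sort(unique(as.character(y_true)))
  per <- lapply(classes, function(cl) compute_metrics(confusion(y_true, y_pred, cl)))
  names(per) <- classes
  keys <- c("accuracy", "sensitivity", "specificity", "precision",
            "f_measure", "mcc", "npv", "fpr", "fnr")
  macro <- vapply(keys, function(k) mean(vapply(per, `[[`, numeric(1), k)),
                  numeric(1))
  list(per_class = per, macro = macro,
       accuracy = mean(as.character(y_true) == as.character(y_pred)))
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps thresholds over the unique score values and integrates the
#' resulting (FPR, TPR) points by the trapezoidal rule, which equals the
#' pairwise concordance probability with ties counted 1/2.
#'
#' @param y_true Label vector with exactly two classes present.
#' @param positive_scores Numeric score for the positive class, higher
#'   meaning more positive.
#' @param positive_label The positive label; defaults to the last sorted
#'   class.
#' @return List with `curve` (data.frame of threshold, fpr, tpr) and
#'   `auc`.
#' @export
roc_auc <- function(y_true, positive_scores, positive_label = NULL) {
  y_true <- as.character(y_true)
  if (!all(is.finite(positive_scores))) stop("scores must be finite")
  classes <- sort(unique(y_true))
  if (length(classes) != 2) stop("exactly two classes required")
  if (is.null(positive_label)) positive_label <- classes[2]
  pos <- y_true == positive_label
  thr <- c(Inf, sort(unique(positive_scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(positive_scores >= t & pos) / sum(pos),
                numeric(1))
  fpr <- vapply(thr, function(t) sum(positive_scores >= t & !pos) / sum(!pos),
                numeric(1))
  # close the curve at (1, 1)
  if (utils::tail(fpr, 1) < 1 || utils::tail(tpr, 1) < 1) {
    fpr <- c(fpr, 1); tpr <- c(tpr, 1); thr <- c(thr, -Inf)
  }
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}
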