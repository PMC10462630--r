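#' Confusion counts for a binary classifier
#'
#' Integer counts are primary; the fractional forms (each count divided by
#' the size of its truth class) are derived views, so the downstream metric
#' ratios are identical whether computed from counts or fractions.
#'
#' @param y_true,y_pred Logical vectors of equal length (>= 1).
#' @return A `confusion_counts` object: `tp`, `tn`, `fp`, `fn` plus rate
#'   fields `tp_rate`, `tn_rate`, `fp_rate`, `fn_rate` (NA when the
#'   corresponding class is absent).
#' @export
#' @examples
#' confusion(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, FALSE, TRUE))
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) abort("lengths differ.")
  if (length(y_true) < 1L) abort("need at least one observation.")
  y_true <- as.logical(y_true); y_pred <- as.logical(y_pred)
  tp <- sum(y_true & y_pred); fn <- sum(y_true & !y_pred)
  tn <- sum(!y_true & !y_pred); fp <- sum(!y_true & y_pred)
  np <- tp + fn; nn <- tn + fp
  structure(
    list(tp = tp, tn = tn, fp = fp, fn = fn,
         tp_rate = if (np > 0) tp / np else NA_real_,
         fn_rate = if (np > 0) fn / np else NA_real_,
         tn_rate = if (nn > 0) tn / nn else NA_real_,
         fp_rate = if (nn > 0) fp / nn else NA_real_),
    class = "confusion_counts"
  )
}

#' Binary classification metrics
#'
#' Sensitivity `TPR = tp/(tp+fn)`, specificity `TNR = tn/(tn+fp)`,
#' `PPV = tp/(tp+fp)`, `NPV = tn/(tn+fn)`, `ACC = (tp+tn)/n` and
#' `F1 = 2 tp / (2 tp + fp + fn)`. Undefined denominators yield `NA`, never
#' a silent 0; the one documented limit convention is `F1 = 0` when
#' `tp = 0` but `fp + fn > 0`.
#'
#' @param counts A [confusion()] result.
#' @return One-row tibble with `tpr`, `tnr`, `ppv`, `npv`, `acc`, `f1`.
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  tibble::tibble(
    tpr = rat(tp, tp + fn), tnr = rat(tn, tn + fp),
    ppv = rat(tp, tp + fp), npv = rat(tn, tn + fn),
    acc = rat(tp + tn, tp + tn + fp + fn), f1 = f1
  )
}

#' ROC-AUC by Mann-Whitney pair counting
#'
#' Equals `(wins + 0.5 * ties) / (n_pos * n_neg)` over all positive/negative
#' score pairs — the probability that a random positive outscores a random
#' negative. Computed via the rank formulation, which handles ties exactly.
#'
#' @param scores Numeric scores.
#' @param y_true Logical truth; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE))  # 0.75
roc_auc <- function(scores, y_true) {
  y_true <- as.logical(y_true)
  if (length(scores) != length(y_true)) abort("lengths differ.")
  n_pos <- sum(y_true); n_neg <- sum(!y_true)
  if (n_pos == 0L || n_neg == 0L) abort("both classes must be present.")
  r <- rank(scores, ties.method = "average")
  (sum(r[y_true]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Youden-optimal decision threshold from the ROC curve
#'
#' Enumerates the observed scores as candidate thresholds (prediction rule
#' `score >= threshold`) and returns the one maximizing Youden's
#' `J = TPR - FPR`; ties are broken toward the lower threshold.
#'
#' @inheritParams roc_auc
#' @return The selected threshold (one of the observed scores).
#' @export
select_threshold <- function(scores, y_true) {
  y_true <- as.logical(y_true)
  n_pos <- sum(y_true); n_neg <- sum(!y_true)
  if (n_pos == 0L || n_neg == 0L) abort("both classes must be present.")
  cand <- sort(unique(scores))
  j <- vapply(cand, function(th) {
    pred <- scores >= th
    sum(pred & y_true) / n_pos - sum(pred & !y_true) / n_neg
  }, numeric(1))
  cand[which.max(j)]  # which.max takes the first (lowest) maximizer
}

#' Evaluate a fitted classifier on a labeled image set
#'
#' Scores the images, selects the decision threshold from the ROC curve on
#' the same set (or uses a supplied one), and reports the full metric panel.
#'
#' @param fit An `ecg_fit`.
#' @param images Labeled `ecg_image`s.
#' @param threshold Optional fixed decision threshold; default Youden.
#' @return One-row tibble: condition, domain mix, n, threshold, roc_auc and
#'   the [classification_metrics()] columns.
#' @export
evaluate_model <- function(fit, images, threshold = NULL) {
  y <- labels_for(images, fit$condition)
  scores <- predict_scores(fit$params, fit$config, images)
  th <- threshold %||% select_threshold(scores, y)
  cm <- classification_metrics(confusion(y, scores >= th))
  dplyr::bind_cols(
    tibble::tibble(condition = fit$condition, mode = fit$mode,
                   n = length(y), threshold = th,
                   roc_auc = roc_auc(scores, y)),
    cm
  )
}
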