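#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a training run
#'
#' @param x An `ecg_fit`.
#' @param ... Unused.
#' @return The per-epoch history tibble: `epoch`, `train_loss`, `val_loss`,
#'   `val_auc`, `domain_acc`, `lambda_end`, `n_domain_updates`,
#'   `checkpoint`.
#' @export
tidy.ecg_fit <- function(x, ...) x$history

#' @rdname tidy.ecg_fit
#' @return `glance()`: one-row summary with mode, condition, epochs run,
#'   best validation AUC, checkpoint epoch and whether any checkpoint was
#'   accepted.
#' @export
glance.ecg_fit <- function(x, ...) {
  tibble::tibble(
    mode = x$mode, condition = x$condition, n_epochs = nrow(x$history),
    best_val_auc = max(x$history$val_auc),
    checkpoint_epoch = x$checkpoint_epoch %||% NA_integer_,
    checkpointed = !isTRUE(x$no_checkpoint)
  )
}

#' Plot training curves
#'
#' Validation ROC-AUC, domain accuracy (with the 40-60% checkpoint window)
#' and losses across epochs.
#'
#' @param object An `ecg_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ecg_fit <- function(object, ...) {
  h <- object$history |>
    dplyr::select("epoch", "val_auc", "domain_acc", "train_loss", "val_loss") |>
    tidyr::pivot_longer(-"epoch", names_to = "metric", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::geom_hline(
      data = tibble::tibble(metric = "domain_acc", y = c(0.4, 0.6)),
      ggplot2::aes(yintercept = .data$y), linetype = "dashed", colour = "grey50"
    ) +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = sprintf("%s training (%s)", object$mode,
                                  object$condition)) +
    ggplot2::theme_minimal()
}

#' @export
tidy.confusion_counts <- function(x, ...) {
  tibble::tibble(tp = x$tp, tn = x$tn, fp = x$fp, fn = x$fn,
                 tp_rate = x$tp_rate, tn_rate = x$tn_rate,
                 fp_rate = x$fp_rate, fn_rate = x$fn_rate)
}

#' ROC curve points and plot
#'
#' @param scores Numeric classifier scores.
#' @param y_true Logical truth.
#' @return `roc_points()`: tibble of (threshold, fpr, tpr) sorted by fpr;
#'   `plot_roc()`: a ggplot of the curve annotated with the AUC.
#' @export
roc_points <- function(scores, y_true) {
  y_true <- as.logical(y_true)
  cand <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n_pos <- sum(y_true); n_neg <- sum(!y_true)
  purrr::map_dfr(cand, function(th) {
    pred <- scores >= th
    tibble::tibble(threshold = th,
                   fpr = sum(pred & !y_true) / n_neg,
                   tpr = sum(pred & y_true) / n_pos)
  })
}

#' @rdname roc_points
#' @export
plot_roc <- function(scores, y_true) {
  pts <- roc_points(scores, y_true)
  auc <- roc_auc(scores, y_true)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = sprintf("ROC-AUC = %.3f", auc)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
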