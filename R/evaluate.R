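#' Evaluate classifier scores against known labels
#'
#' Computes the confusion matrix at `threshold`, the derived precision,
#' recall and F-score, the ROC AUC (trapezoid over the ROC curve, with
#' tied scores handled as a single operating point — numerically identical
#' to the pairwise-concordance statistic), and the PR AUC by the
#' step-wise average-precision convention (trapezoidal interpolation is
#' biased for PR curves). With a single class present the AUCs are
#' undefined and reported as `NA`.
#'
#' @param scores Numeric vector of predicted probabilities in `[0, 1]`.
#' @param labels Matching vector of true labels
#'   (`"positive"`/`"negative"`, `"bound"`/`"unbound"`, logical or 0/1).
#' @param threshold Decision threshold for the confusion counts
#'   (default 0.5; scores >= threshold are called positive).
#' @return An object of class `eval_report` with fields `precision`,
#'   `recall`, `f_score`, `roc_auc`, `pr_auc`, `tp`, `fp`, `tn`, `fn`,
#'   `n`, `threshold`. [tidy()] returns the metrics long, [glance()] one
#'   row wide, [autoplot()] the ROC curve.
#' @export
evaluate_predictions <- function(scores, labels, threshold = 0.5) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y)) {
    abort("`scores` and `labels` differ in length.")
  }
  if (anyNA(scores) || any(scores < 0 | scores > 1)) {
    abort("Scores must be probabilities in [0, 1].")
  }
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f_score <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  one_class <- length(unique(y)) < 2
  structure(
    list(precision = precision, recall = recall, f_score = f_score,
         roc_auc = if (one_class) NA_real_ else roc_auc_trapezoid(scores, y),
         pr_auc = if (one_class) NA_real_ else average_precision(scores, y),
         tp = tp, fp = fp, tn = tn, fn = fn, n = length(y),
         threshold = threshold, scores = scores, labels = y),
    class = "eval_report"
  )
}

# ROC AUC by trapezoid over the (FPR, TPR) curve built on unique score
# cut-points; ties collapse to one point, so the result equals the
# concordance probability with ties counted 1/2.
roc_auc_trapezoid <- function(scores, y) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  last <- cumsum(rle(s)$lengths)           # end index of each tie group
  tp <- cumsum(yy)[last]
  fp <- cumsum(1 - yy)[last]
  tpr <- c(0, tp / sum(y))
  fpr <- c(0, fp / sum(1 - y))
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

# Average precision: sum over score cut-points of (recall step) * precision.
average_precision <- function(scores, y) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(yy)[last]
  npred <- last
  prec <- tp / npred
  rec <- tp / sum(y)
  sum(diff(c(0, rec)) * prec)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    paste0("<eval_report: n=%d  precision=%.3f  recall=%.3f  F=%.3f  ",
           "ROC-AUC=%s  PR-AUC=%s>\n"),
    x$n, x$precision, x$recall, x$f_score,
    ifelse(is.na(x$roc_auc), "NA", sprintf("%.3f", x$roc_auc)),
    ifelse(is.na(x$pr_auc), "NA", sprintf("%.3f", x$pr_auc))))
  invisible(x)
}

#' @rdname evaluate_predictions
#' @param x,object An `eval_report`.
#' @param ... Unused.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) {
  tibble(
    metric = c("precision", "recall", "f_score", "roc_auc", "pr_auc",
               "tp", "fp", "tn", "fn"),
    value = c(x$precision, x$recall, x$f_score, x$roc_auc, x$pr_auc,
              x$tp, x$fp, x$tn, x$fn)
  )
}

#' @rdname evaluate_predictions
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble(precision = x$precision, recall = x$recall, f_score = x$f_score,
         roc_auc = x$roc_auc, pr_auc = x$pr_auc, n = x$n,
         threshold = x$threshold)
}

#' @rdname evaluate_predictions
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  ord <- order(object$scores, decreasing = TRUE)
  yy <- object$labels[ord]
  s <- object$scores[ord]
  last <- cumsum(rle(s)$lengths)
  df <- tibble(
    fpr = c(0, cumsum(1 - yy)[last] / max(1, sum(1 - yy))),
    tpr = c(0, cumsum(yy)[last] / max(1, sum(yy)))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "False positive rate", y = "True positive rate") +
    ggplot2::theme_minimal()
}
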