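#' Fisher exact significance of a rule
#'
#' Tests whether instances satisfying the rule's premise are enriched for the
#' rule's consequence class, on the 2x2 table (premise satisfied x class
#' membership) with fixed margins. The default is the one-sided enrichment
#' test, matching the per-class orientation in which the tested class is the
#' rule's own consequence; `alternative = "two.sided"` is available.
#'
#' @param rule A [rule()].
#' @param dataset A [cohort_dataset()] with a binary outcome.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return The exact p-value; degenerate margins (empty coverage or a single
#'   outcome class) give 1.
#' @export
fisher_rule_test <- function(rule, dataset, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(unique(dataset$outcome)) > 2L)
    stop("Fisher rule test requires a binary outcome")
  ct <- confusion_counts(rule, dataset)
  m <- rbind(c(ct$TP, ct$FN), c(ct$FP, ct$TN))
  stats::fisher.test(m, alternative = alternative)$p.value
}

#' Performance of a classifier on a labeled dataset
#'
#' Predictions follow the highest-covering policy of [classify()]. With good
#' outcome as the positive class: accuracy = correct/n, recall = TP/positives,
#' precision = TP/predicted-positive, specificity = TN/negatives,
#' NPV = TN/predicted-negative. Not-classified (NC) predictions are counted
#' separately; by default they score as errors, which keeps the headline
#' metrics conservative, and `exclude_nc = TRUE` drops them instead.
#'
#' @param classifier A calibrated [rule_classifier()].
#' @param dataset A labeled [cohort_dataset()].
#' @param positive Label of the positive class.
#' @param exclude_nc Drop NC-predicted instances from the metrics
#'   (default FALSE).
#' @return A list of class `performance_report`: the five metrics, the
#'   confusion counts they derive from, `n`, `n_nc`, and `undefined` naming
#'   any zero-denominator metric (reported as 0).
#' @export
performance_metrics <- function(classifier, dataset, positive,
                                exclude_nc = FALSE) {
  pred <- predict(classifier, dataset)
  truth <- dataset$outcome
  n_nc <- sum(pred == "NC")
  if (exclude_nc) {
    keep <- pred != "NC"
    pred <- pred[keep]; truth <- truth[keep]
  }
  n <- length(pred)
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  tn <- sum(pred != positive & pred != "NC" & truth != positive)
  fn_pred <- sum(pred != positive & pred != "NC" & truth == positive)
  undef <- character(0L)
  div <- function(num, den, label) {
    if (den == 0) { undef <<- c(undef, label); 0 } else num / den
  }
  res <- list(
    accuracy    = div(sum(pred == truth), n, "accuracy"),
    recall      = div(tp, sum(truth == positive), "recall"),
    precision   = div(tp, tp + fp, "precision"),
    specificity = div(tn, sum(truth != positive), "specificity"),
    npv         = div(tn, tn + fn_pred, "npv"),
    counts = list(TP = tp, FP = fp, TN = tn, FN = sum(truth == positive) - tp),
    n = n, n_nc = n_nc, positive = positive, undefined = undef)
  class(res) <- "performance_report"
  res
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf(paste0("accuracy %.3f  recall %.3f  precision %.3f  ",
                     "specificity %.3f  NPV %.3f  (n=%d, NC=%d, positive=%s)\n"),
              x$accuracy, x$recall, x$precision, x$specificity, x$npv,
              x$n, x$n_nc, x$positive))
  invisible(x)
}
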