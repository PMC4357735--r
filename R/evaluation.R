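#' ROC curve and AUC
#'
#' Curve over all distinct score thresholds (ties grouped into a single
#' step); AUC by the trapezoidal rule, which equals the Mann-Whitney
#' statistic with ties counted half.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels logical/0-1/factor truth; `bound` or `TRUE`/`1` marks a
#'   positive.
#' @return list of class `roc_result`: `thresholds`, `fpr`, `tpr`, `auc`.
#'   The curve starts at (0, 0) and ends at (1, 1) exactly.
#' @export
roc_curve <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (!any(y) || all(y))
    stop("ROC needs both classes present", call. = FALSE)
  P <- sum(y); N <- sum(!y)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- y[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)  # end of each tie group
  thresholds <- s[last]
  tpr <- c(0, tp[last] / P)
  fpr <- c(0, fp[last] / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = thresholds, fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f over %d threshold(s)\n", x$auc,
              length(x$thresholds)))
  invisible(x)
}

#' Precision-recall curve and average precision
#'
#' Step-function (non-interpolated) average precision:
#' `AP = sum_k (R_k - R_{k-1}) P_k` over the distinct-threshold steps.
#'
#' @inheritParams roc_curve
#' @return list of class `pr_result`: `thresholds`, `recall`, `precision`,
#'   `average_precision`.
#' @export
pr_curve <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (!any(y))
    stop("precision-recall needs at least one positive", call. = FALSE)
  P <- sum(y)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- y[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y)
  k <- seq_along(y)
  last <- !duplicated(grp, fromLast = TRUE)
  recall <- tp[last] / P
  precision <- tp[last] / k[last]
  ap <- sum(diff(c(0, recall)) * precision)
  structure(list(thresholds = s[last], recall = recall,
                 precision = precision, average_precision = ap),
            class = "pr_result")
}

#' @export
print.pr_result <- function(x, ...) {
  cat(sprintf("PR: average precision = %.4f over %d threshold(s)\n",
              x$average_precision, length(x$thresholds)))
  invisible(x)
}

as_binary_labels <- function(labels) {
  if (is.factor(labels) || is.character(labels)) {
    as.character(labels) == "bound"
  } else {
    as.logical(labels)
  }
}

#' Repeated random-split evaluation of the full pipeline
#'
#' For each replicate: split the labelled candidates in half, run the
#' training half through methylation-model fitting, feature assembly and
#' forest training, predict on the held-out half, and record the ROC AUC
#' against the gold-standard labels.
#'
#' @param bundle a synthetic dataset bundle from [simulate_dataset()] (or
#'   an equivalent list of pipeline inputs).
#' @param n_reps number of repeated splits (default 10).
#' @param seeds integer seeds, one per replicate; defaults to
#'   `seq_len(n_reps)`.
#' @param ... passed on to [run_train()] (e.g. `n_trees`, `contexts`).
#' @return list with `auc` (per-replicate vector), `mean`, `sd`.
#' @export
repeated_split_evaluation <- function(bundle, n_reps = 10, seeds = NULL,
                                      ...) {
  stopifnot(n_reps >= 1)
  if (is.null(seeds)) seeds <- seq_len(n_reps)
  stopifnot(length(seeds) == n_reps)
  aucs <- vapply(seeds, function(s) {
    fit <- run_train(bundle, seed = s, ...)
    pred <- run_predict(fit$model, bundle, sites = fit$test_sites)
    truth <- fit$test_sites$label
    roc_curve(pred$prob_bound, truth)$auc
  }, 0)
  list(auc = aucs, mean = mean(aucs), sd = stats::sd(aucs))
}
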