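# Performance metrics: ROC AUC (Mann-Whitney form), TPR/TNR at a fixed
# decision threshold, balanced error rate, and permutation feature
# importance.

check_binary_labels <- function(labels) {
  if (!all(labels %in% c(0, 1))) stop_ts("labels must be binary 0/1")
  if (length(unique(labels)) < 2L)
    stop_ts("both outcome classes must be present")
}

#' True-positive and true-negative rates at a threshold
#'
#' A prediction is positive iff the probability is `>= threshold` (a tie at
#' the threshold counts as positive).
#'
#' @param probs probability vector.
#' @param labels 0/1 vector of the same length.
#' @param threshold decision cut (default 0.5).
#' @return named vector `c(tpr, tnr)`.
#' @export
confusion_at_threshold <- function(probs, labels, threshold = 0.5) {
  stopifnot(length(probs) == length(labels))
  check_binary_labels(labels)
  pred <- probs >= threshold
  c(tpr = sum(pred & labels == 1) / sum(labels == 1),
    tnr = sum(!pred & labels == 0) / sum(labels == 0))
}

#' Balanced error rate
#'
#' `BER = 1 - 0.5 * (TPR + TNR)`; equals 0 for a perfect classifier and 0.5
#' for a chance-level one, regardless of class imbalance.
#'
#' @param tpr,tnr rates in `[0, 1]`.
#' @return the balanced error rate.
#' @export
balanced_error_rate <- function(tpr, tnr) {
  if (!is_prob(tpr, open = FALSE) || !is_prob(tnr, open = FALSE))
    stop_ts("tpr and tnr must lie in [0, 1]")
  unname(1 - 0.5 * (tpr + tnr))
}

#' ROC AUC (Mann-Whitney pair statistic)
#'
#' The fraction of (positive, negative) pairs in which the positive case
#' receives the larger probability, ties counted one half. Computed via
#' average ranks, which is exactly the pair statistic.
#'
#' @param probs probability (or score) vector.
#' @param labels 0/1 vector of the same length.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(probs, labels) {
  stopifnot(length(probs) == length(labels))
  check_binary_labels(labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  r <- rank(probs, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate a fitted model on the test split
#'
#' @param fit a `fit_result`.
#' @param fm the full `feature_matrix`.
#' @param split a `split_plan`; metrics use the test rows.
#' @param threshold decision threshold (default 0.5).
#' @return an object of class `metric_set`: `roc_auc`, `tpr`, `tnr`, `ber`,
#'   `threshold`, `n_pos`, `n_neg`.
#' @export
evaluate_fit <- function(fit, fm, split, threshold = 0.5) {
  idx <- split$test_idx
  probs <- fit$predict(fm$values[idx, , drop = FALSE])
  labels <- fm$outcome[idx]
  rates <- confusion_at_threshold(probs, labels, threshold)
  structure(list(roc_auc = roc_auc(probs, labels),
                 tpr = unname(rates["tpr"]), tnr = unname(rates["tnr"]),
                 ber = balanced_error_rate(rates["tpr"], rates["tnr"]),
                 threshold = threshold,
                 n_pos = sum(labels == 1), n_neg = sum(labels == 0)),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("AUC %.3f | BER %.3f (TPR %.3f, TNR %.3f) @ %.2f [%d+/%d-]\n",
              x$roc_auc, x$ber, x$tpr, x$tnr, x$threshold, x$n_pos, x$n_neg))
  invisible(x)
}

#' Permutation feature importance
#'
#' Importance of a feature is the mean (over seeded repeats) increase in the
#' mean squared error between labels and predicted probabilities when that
#' feature's column is randomly permuted across rows, holding all other
#' features fixed. A feature the model ignores has importance exactly zero.
#'
#' @param fit a `fit_result`.
#' @param fm a `feature_matrix` (rows to evaluate on).
#' @param labels 0/1 labels for those rows.
#' @param feature feature name; must be in the fit's feature set.
#' @param n_repeats permutation repeats (default 10).
#' @param seed integer seed.
#' @param rows optional row indices of `fm` to use (default all).
#' @return scalar importance (permuted MSE minus baseline MSE).
#' @export
permutation_importance <- function(fit, fm, labels, feature,
                                   n_repeats = 10L, seed = 1L, rows = NULL) {
  if (!feature %in% fit$features)
    stop_ts("feature '%s' is not in the fitted model", feature)
  m <- if (inherits(fm, "feature_matrix")) fm$values else fm
  if (!is.null(rows)) { m <- m[rows, , drop = FALSE]; labels <- labels[rows] }
  base_mse <- mean((labels - fit$predict(m))^2)
  withr::with_seed(seed, {
    mean(vapply(seq_len(n_repeats), function(r) {
      mp <- m
      mp[, feature] <- mp[sample(nrow(mp)), feature]
      mean((labels - fit$predict(mp))^2)
    }, 0)) - base_mse
  })
}

#' Rank all fitted features by permutation importance
#'
#' @inheritParams permutation_importance
#' @return data.frame of features sorted by decreasing importance.
#' @export
permutation_importance_table <- function(fit, fm, labels, n_repeats = 10L,
                                         seed = 1L, rows = NULL) {
  imp <- vapply(fit$features, function(f)
    permutation_importance(fit, fm, labels, f, n_repeats = n_repeats,
                           seed = child_seed(seed, match(f, fit$features)),
                           rows = rows), 0)
  out <- data.frame(feature = fit$features, importance = unname(imp),
                    stringsAsFactors = FALSE)
  out[order(-out$importance, out$feature, method = "radix"), , drop = FALSE]
}
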