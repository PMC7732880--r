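# Model fitting: unregularized logistic regression, lasso selection, ridge
# refit. Penalties are chosen by cross-validated ROC AUC on the split plan's
# folds; the final fit uses the full training split at the chosen penalty.

#' Default penalty grid
#'
#' 50 values log-spaced over `[1e-4, 1e4]`, in decreasing order (the
#' warm-start order used by the coordinate-descent path).
#' @param n_lambda grid size.
#' @param range lambda range.
#' @return decreasing numeric vector.
#' @export
default_penalty_grid <- function(n_lambda = 50L, range = c(1e-4, 1e4)) {
  10^seq(log10(range[2]), log10(range[1]), length.out = n_lambda)
}

new_fit_result <- function(model_kind, penalty, intercept, coefficients,
                           predict_fn, features, training_meta = list()) {
  structure(list(model_kind = model_kind, penalty = penalty,
                 intercept = intercept, coefficients = coefficients,
                 features = features, predict = predict_fn,
                 training_meta = training_meta),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: %s (%d features%s)\n", x$model_kind,
              length(x$features),
              if (is.na(x$penalty)) "" else sprintf(", lambda = %.4g", x$penalty)))
  invisible(x)
}

#' Predicted probabilities from a fitted model
#' @param object a `fit_result`.
#' @param newdata a `feature_matrix` or numeric matrix with named columns.
#' @param ... unused.
#' @return probability vector in `[0, 1]`.
#' @export
predict.fit_result <- function(object, newdata, ...) {
  m <- if (inherits(newdata, "feature_matrix")) newdata$values else newdata
  object$predict(m)
}

linear_predict_fn <- function(intercept, coefficients) {
  beta <- ifelse(is.na(coefficients), 0, coefficients)
  feats <- names(coefficients)
  function(m) {
    missing <- setdiff(feats, colnames(m))
    if (length(missing))
      stop_ts("prediction matrix lacks feature(s): %s",
              paste(head(missing, 5), collapse = ", "))
    as.vector(plogis(intercept + m[, feats, drop = FALSE] %*% beta))
  }
}

train_xy <- function(fm, split) {
  x <- fm$values[split$train_idx, , drop = FALSE]
  y <- fm$outcome[split$train_idx]
  if (length(unique(y)) < 2L)
    stop_ts("training outcome has a single class")
  list(x = x, y = y)
}

#' Fit an unregularized (traditional) logistic regression
#'
#' Maximum-likelihood logistic fit of all supplied features on the training
#' rows, with no penalty and no cross-validation. This model is deliberately
#' exposed to overfitting and multicollinearity in wide data: it is the
#' baseline the regularized pipeline is compared against. Non-convergence
#' and aliased (rank-deficient) coefficients are recorded in
#' `training_meta`, not raised; aliased coefficients are treated as zero at
#' prediction time.
#'
#' @param fm a `feature_matrix`.
#' @param split a `split_plan`.
#' @return a `fit_result` with `model_kind = "traditional"`.
#' @export
fit_traditional_logistic <- function(fm, split) {
  d <- train_xy(fm, split)
  xmat <- cbind(`(Intercept)` = 1, d$x)
  fit <- withCallingHandlers(
    glm.fit(xmat, d$y, family = binomial()),
    warning = function(w) invokeRestart("muffleWarning"))
  co <- fit$coefficients
  intercept <- unname(co[1])
  beta <- co[-1]
  new_fit_result(
    "traditional", penalty = 0, intercept = intercept, coefficients = beta,
    predict_fn = linear_predict_fn(intercept, beta),
    features = fm$feature_names,
    training_meta = list(converged = fit$converged,
                         n_aliased = sum(is.na(beta)),
                         iterations = fit$iter))
}

# CV-by-AUC penalized fit shared by the lasso and ridge stages. With a
# single-value grid the cross-validation is skipped and the model is fit at
# that penalty directly (augmented internally with larger values for
# warm-start stability, then evaluated exactly at the requested value).
#
# AUC is rank-based, so the CV curve is often exactly tied over a wide
# lambda range; the tie direction matters. The selection stage (lasso)
# prefers the largest tied lambda (the sparsest model), the estimation
# stage (ridge) the smallest (least shrinkage bias, so predicted
# probabilities stay usable at a fixed decision threshold).
fit_penalized <- function(fm, split, penalty_grid, alpha, model_kind,
                          tie_break = c("largest", "smallest")) {
  tie_break <- match.arg(tie_break)
  if (!length(penalty_grid) || any(penalty_grid < 0))
    stop_ts("penalty grid must be nonempty with lambda >= 0")
  d <- train_xy(fm, split)
  # glmnet needs >= 2 columns; pad a degenerate single-feature problem with
  # an all-zero column (penalized coefficient is exactly 0, so inert)
  if (ncol(d$x) == 1L)
    d$x <- cbind(d$x, `.zero_pad` = 0)
  grid <- sort(unique(as.double(penalty_grid)), decreasing = TRUE)

  if (length(grid) == 1L) {
    lam <- grid
    path <- sort(unique(c(lam, lam + 10^seq(1, -2))), decreasing = TRUE)
    g <- glmnet::glmnet(d$x, d$y, family = "binomial", alpha = alpha,
                        lambda = path, standardize = FALSE, thresh = 1e-12,
                        maxit = 10^6)
    co <- coef(g, s = lam, exact = TRUE, x = d$x, y = d$y,
               family = "binomial", alpha = alpha, standardize = FALSE,
               thresh = 1e-12, maxit = 10^6)
    cv_auc <- NA_real_
  } else {
    cv <- glmnet::cv.glmnet(d$x, d$y, family = "binomial", alpha = alpha,
                            lambda = grid, foldid = split$foldid,
                            type.measure = "auc", standardize = FALSE,
                            maxit = 10^6)
    tied <- cv$lambda[cv$cvm >= max(cv$cvm, na.rm = TRUE) - 1e-12]
    lam <- if (tie_break == "largest") max(tied) else min(tied)
    co <- coef(cv, s = lam)
    cv_auc <- max(cv$cvm, na.rm = TRUE)
  }
  co <- as.matrix(co)[, 1]
  intercept <- unname(co["(Intercept)"])
  beta <- co[setdiff(names(co), "(Intercept)")]
  beta <- beta[fm$feature_names]  # original column order
  names(beta) <- fm$feature_names
  new_fit_result(
    model_kind, penalty = lam, intercept = intercept, coefficients = beta,
    predict_fn = linear_predict_fn(intercept, beta),
    features = fm$feature_names,
    training_meta = list(alpha = alpha, cv_auc = cv_auc,
                         grid_size = length(grid), k = split$k))
}

#' Fit the lasso (L1) logistic selection stage
#'
#' The penalty is chosen to maximize the mean cross-validated ROC AUC over
#' the split plan's folds; the final model is refit on the full training
#' split at that penalty. The L1 penalty can force coefficients exactly to
#' zero, which is what makes this stage a feature selector.
#'
#' @param fm a `feature_matrix`.
#' @param split a `split_plan`.
#' @param penalty_grid candidate lambda values; a single value skips CV.
#' @return a `fit_result` with `model_kind = "lasso"`.
#' @export
fit_lasso <- function(fm, split, penalty_grid = default_penalty_grid()) {
  fit_penalized(fm, split, penalty_grid, alpha = 1, model_kind = "lasso",
                tie_break = "largest")
}

#' Fit the ridge (L2) logistic refit stage
#'
#' Refit restricted to a feature subset (normally the lasso's nonzero set).
#' The L2 penalty shrinks coefficients towards zero but never exactly to
#' zero, giving a dense, interpretable coefficient profile over the
#' selected features. Penalty selection is by cross-validated ROC AUC.
#'
#' @param fm a `feature_matrix` (will be restricted to `features` if given).
#' @param split a `split_plan`.
#' @param penalty_grid candidate lambda values; a single value skips CV.
#' @param features optional feature subset; default uses all of `fm`.
#' @return a `fit_result` with `model_kind = "ridge"`.
#' @export
fit_ridge <- function(fm, split, penalty_grid = default_penalty_grid(),
                      features = NULL) {
  if (!is.null(features)) {
    if (!length(features)) stop_ts("ridge feature subset is empty")
    fm <- subset_features(fm, features)
  }
  if (!ncol(fm$values)) stop_ts("ridge feature subset is empty")
  fit_penalized(fm, split, penalty_grid, alpha = 0, model_kind = "ridge",
                tie_break = "smallest")
}

#' Nonzero-coefficient features of a lasso fit
#'
#' @param fit a `fit_result` with `model_kind = "lasso"`.
#' @param tol zero tolerance on `|coefficient|`.
#' @return feature names with `|coef| > tol`, in the fit's feature order.
#' @export
select_nonzero <- function(fit, tol = 1e-8) {
  stopifnot(inherits(fit, "fit_result"))
  if (fit$model_kind != "lasso")
    stop_ts("select_nonzero expects a lasso fit, got '%s'", fit$model_kind)
  beta <- fit$coefficients
  names(beta)[!is.na(beta) & abs(beta) > tol]
}

#' Intercept-only fallback fit
#'
#' Used when the lasso selects no features: predicts the training prevalence
#' for every row (a terminal condition for the iterative engine, and the
#' correct null model for evaluation).
#' @param fm a `feature_matrix`.
#' @param split a `split_plan`.
#' @return a `fit_result` with empty coefficients.
#' @export
fit_intercept_only <- function(fm, split) {
  p <- mean(fm$outcome[split$train_idx])
  intercept <- stats::qlogis(min(max(p, 1e-12), 1 - 1e-12))
  new_fit_result("ridge", penalty = Inf, intercept = intercept,
                 coefficients = stats::setNames(numeric(), character()),
                 predict_fn = function(m) rep(plogis(intercept), nrow(m)),
                 features = character(),
                 training_meta = list(intercept_only = TRUE))
}
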