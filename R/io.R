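# Serialization helpers for the intermediate pipeline objects.

#' Write a feature matrix as CSV plus a JSON sidecar
#'
#' The CSV holds the numeric matrix with the outcome as its last column; the
#' sidecar records feature names, the variable-to-feature map, and any
#' normalization constants, which is enough to re-apply the identical
#' transform to new data.
#'
#' @param fm a `feature_matrix`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.meta.json`.
#' @export
write_feature_matrix_csv <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- as.data.frame(fm$values, check.names = FALSE)
  df$child_marriage <- fm$outcome
  utils::write.csv(df, path, row.names = FALSE)
  var_map <- split(fm$feature_info$feature, fm$feature_info$variable)
  write_stable_json(list(
    feature_names = fm$feature_names,
    variable_features = var_map,
    normalization = lapply(fm$normalization %||% list(), as.list)),
    paste0(path, ".meta.json"))
  invisible(path)
}

#' Serialize a fitted model to JSON
#'
#' Linear fits store their coefficients, intercept and penalty; the neural
#' network stores its architecture and a weight checksum (weights themselves
#' live in memory only — the fit is cheap to reproduce from the recorded
#' seed).
#'
#' @param fit a `fit_result`.
#' @param path JSON path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  body <- list(model_kind = fit$model_kind, penalty = fit$penalty,
               intercept = fit$intercept,
               coefficients = if (!is.null(fit$coefficients))
                 as.list(fit$coefficients),
               features = fit$features,
               training_meta = fit$training_meta)
  write_stable_json(body, path)
}
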