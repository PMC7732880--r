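# Preprocessing: variable screening, one-hot encoding, train-statistics
# normalization, and the fixed train/test split with CV fold assignments.

#' Screen out non-analytic variables
#'
#' Removes columns whose names match any of the given glob patterns
#' (identifier variables, interview dates, and similar columns that are not
#' meaningful predictors). The outcome column may never be screened.
#'
#' @param table survey data.frame.
#' @param exclusion_patterns character vector of glob patterns
#'   (e.g. `"*_id"`).
#' @param outcome outcome column name (default `"child_marriage"`).
#' @return the table without the matched columns; removed names are attached
#'   as attribute `"removed"`.
#' @export
screen_variables <- function(table, exclusion_patterns,
                             outcome = "child_marriage") {
  if (!outcome %in% names(table))
    stop_ts("outcome column '%s' not present", outcome)
  removed <- character()
  for (pat in exclusion_patterns) {
    hits <- grep(utils::glob2rx(pat), names(table), value = TRUE)
    if (outcome %in% hits)
      stop_ts("pattern '%s' matches the outcome column", pat)
    removed <- union(removed, hits)
  }
  out <- table[, setdiff(names(table), removed), drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' One-hot encode a survey table
#'
#' Every observed level of every categorical variable becomes its own binary
#' column named `"variable: level"`; no reference level is dropped, because
#' complementary levels are interpreted as separate predictors and the
#' downstream models are regularized. Continuous columns pass through under
#' their own names. Missing categorical values become an explicit
#' `"missing"` level. A categorical column with a single observed level is
#' kept (with a warning) and flagged constant so callers can drop it.
#'
#' @param table survey data.frame including the outcome column.
#' @param outcome outcome column name.
#' @return an object of class `feature_matrix`: list with `values`
#'   (numeric matrix, one row per respondent), `feature_names`, `outcome`
#'   (0/1 integer vector), and `feature_info` (data.frame: feature,
#'   variable, level, kind, constant).
#' @export
one_hot_encode <- function(table, outcome = "child_marriage") {
  if (!outcome %in% names(table))
    stop_ts("outcome column '%s' not present", outcome)
  y <- table[[outcome]]
  if (!all(y %in% c(0, 1))) stop_ts("outcome must be binary 0/1")
  vars <- setdiff(names(table), outcome)
  if (!length(vars)) stop_ts("no predictor columns to encode")

  blocks <- list(); info <- list()
  for (v in vars) {
    x <- table[[v]]
    if (is.numeric(x)) {
      blocks[[v]] <- matrix(as.double(x), ncol = 1,
                            dimnames = list(NULL, v))
      info[[v]] <- data.frame(feature = v, variable = v, level = NA_character_,
                              kind = "continuous", constant = FALSE,
                              stringsAsFactors = FALSE)
    } else {
      x <- as.character(x)
      x[is.na(x)] <- "missing"
      levs <- sort(unique(x), method = "radix")
      if (length(levs) == 1L)
        warning(sprintf("variable '%s' has a single observed level", v),
                call. = FALSE)
      cols <- vapply(levs, function(lv) as.double(x == lv),
                     numeric(length(x)))
      cols <- matrix(cols, ncol = length(levs),
                     dimnames = list(NULL, feature_name(v, levs)))
      blocks[[v]] <- cols
      info[[v]] <- data.frame(feature = colnames(cols), variable = v,
                              level = levs, kind = "categorical",
                              constant = length(levs) == 1L,
                              stringsAsFactors = FALSE)
    }
  }
  values <- do.call(cbind, blocks)
  feature_info <- do.call(rbind, info)
  rownames(feature_info) <- NULL
  structure(list(values = values, feature_names = colnames(values),
                 outcome = as.integer(y), feature_info = feature_info,
                 normalization = NULL),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d respondents x %d features (prevalence %.3f)\n",
              nrow(x$values), ncol(x$values), mean(x$outcome)))
  invisible(x)
}

#' Restrict a feature matrix to a feature subset
#' @param fm a `feature_matrix`.
#' @param features feature names to keep (order preserved as given).
#' @return a `feature_matrix` on the subset.
#' @export
subset_features <- function(fm, features) {
  stopifnot(inherits(fm, "feature_matrix"))
  missing <- setdiff(features, fm$feature_names)
  if (length(missing))
    stop_ts("unknown feature(s): %s", paste(head(missing, 5), collapse = ", "))
  fm$values <- fm$values[, features, drop = FALSE]
  fm$feature_names <- features
  fm$feature_info <- fm$feature_info[match(features, fm$feature_info$feature), ]
  rownames(fm$feature_info) <- NULL
  fm
}

#' Decode a one-hot block back to the categorical column
#'
#' Argmax per row over the block's columns; exact round-trip when the
#' encoding had no missingness.
#' @param fm a `feature_matrix`.
#' @param variable categorical variable name.
#' @return character vector of levels.
#' @export
decode_one_hot <- function(fm, variable) {
  inf <- fm$feature_info
  rows <- inf$variable == variable & inf$kind == "categorical"
  if (!any(rows)) stop_ts("'%s' is not an encoded categorical", variable)
  block <- fm$values[, inf$feature[rows], drop = FALSE]
  inf$level[rows][max.col(block, ties.method = "first")]
}

#' Build the fixed train/test split with CV folds
#'
#' Randomly assigns `test_fraction` of the rows to the test set and
#' partitions the remaining training rows into `k` cross-validation folds.
#' When an outcome vector is supplied the assignment is stratified: rows are
#' shuffled within class and dealt round-robin, which keeps both the
#' test/train class balance and fold sizes within one of each other.
#'
#' @param n number of rows.
#' @param test_fraction proportion in (0, 1); default 0.20.
#' @param k number of folds (>= 2); default 5.
#' @param seed integer seed.
#' @param outcome optional 0/1 vector of length `n` for stratification.
#' @param stratify stratify on the outcome when it is supplied.
#' @return an object of class `split_plan` with `test_idx`, `train_idx`,
#'   `foldid` (parallel to `train_idx`), and the call parameters.
#' @export
make_split <- function(n, test_fraction = 0.2, k = 5L, seed,
                       outcome = NULL, stratify = TRUE) {
  if (!is_prob(test_fraction)) stop_ts("test_fraction must be in (0, 1)")
  if (!is_count(k, 2L)) stop_ts("k must be an integer >= 2")
  n_test <- round(n * test_fraction)
  n_train <- n - n_test
  if (n_train < k) stop_ts("k = %d exceeds the training size %d", k, n_train)

  withr::with_seed(seed, {
    use_strata <- stratify && !is.null(outcome)
    if (use_strata) {
      stopifnot(length(outcome) == n)
      classes <- sort(unique(outcome))
      by_class <- lapply(classes, function(cl) sample(which(outcome == cl)))
      # largest-remainder allocation of the exact test size across classes
      sizes <- lengths(by_class)
      exact <- sizes * test_fraction
      base <- floor(exact)
      extra <- order(-(exact - base))[seq_len(n_test - sum(base))]
      take <- base
      take[extra] <- take[extra] + 1L
      test_idx <- unlist(Map(function(ix, m) ix[seq_len(m)], by_class, take))
      train_ordered <- unlist(Map(function(ix, m) ix[-seq_len(m)],
                                  by_class, take))
      # round-robin fold labels over the class-ordered training rows keep
      # folds both size-balanced (within 1) and class-balanced
      train_idx <- train_ordered
      foldid <- rep_len(seq_len(k), length(train_ordered))
    } else {
      perm <- sample(n)
      test_idx <- perm[seq_len(n_test)]
      train_idx <- perm[-seq_len(n_test)]
      foldid <- rep_len(seq_len(k), length(train_idx))
    }
    test_idx <- sort(test_idx)
    o <- order(train_idx)
    structure(list(n = n, test_fraction = test_fraction, k = as.integer(k),
                   seed = seed, stratified = use_strata,
                   test_idx = test_idx, train_idx = train_idx[o],
                   foldid = foldid[o]),
              class = "split_plan")
  })
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("split_plan: %d rows -> %d train / %d test, %d folds (seed %s)\n",
              x$n, length(x$train_idx), length(x$test_idx), x$k,
              format(x$seed)))
  invisible(x)
}

#' Normalize continuous features using training statistics
#'
#' Z-scores each continuous column with the mean and population SD
#' (denominator n) computed on the training rows only; the identical
#' transform is applied to test rows, so no information leaks from the test
#' split. One-hot columns are left untouched.
#'
#' @param fm a `feature_matrix`.
#' @param split a `split_plan`.
#' @return the `feature_matrix` with transformed continuous columns and a
#'   `normalization` element recording the constants.
#' @export
normalize_continuous <- function(fm, split) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(split, "split_plan"))
  cont <- fm$feature_info$feature[fm$feature_info$kind == "continuous"]
  if (!length(cont)) return(fm)
  tr <- split$train_idx
  stats_tab <- lapply(cont, function(f) {
    x <- fm$values[tr, f]
    mu <- mean(x)
    sdev <- sqrt(mean((x - mu)^2))  # population SD
    if (sdev == 0)
      stop_ts("continuous feature '%s' is constant on the training split", f)
    c(mean = mu, sd = sdev)
  })
  names(stats_tab) <- cont
  for (f in cont) {
    fm$values[, f] <- (fm$values[, f] - stats_tab[[f]]["mean"]) /
      stats_tab[[f]]["sd"]
  }
  fm$normalization <- stats_tab
  fm
}

#' Serialize a split plan to JSON
#' @param split a `split_plan`.
#' @param path file path.
#' @export
write_split_json <- function(split, path) {
  write_stable_json(list(
    n = split$n, test_fraction = split$test_fraction, k = split$k,
    seed = split$seed, stratified = split$stratified,
    test_idx = split$test_idx, train_idx = split$train_idx,
    foldid = split$foldid), path)
}
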