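# Iterative thematic categorization: repeat lasso -> ridge -> knee ->
# evaluate rounds; qualify themes among the above-knee features, drop the
# dominant theme's features (a multi-theme feature survives until its last
# theme is removed), and stop when the test AUC falls below a floor, when a
# round selects no new features, or when no new theme has emerged for a
# fixed number of consecutive rounds.

UNCODED_LABEL <- "uncoded"

#' Engine configuration
#'
#' @param min_theme_fraction a theme qualifies in a round when its members
#'   among the above-knee features number at least
#'   `max(ceiling(min_theme_fraction * n_selected), min_theme_size)`
#'   (defaults 0.05 and 2).
#' @param min_theme_size absolute member-count floor for qualification
#'   (default 2: a theme is a group, a single feature never qualifies).
#' @param auc_floor stop when the round's test ROC AUC drops below this
#'   (default 0.75).
#' @param no_new_theme_patience stop after this many consecutive rounds
#'   without a new theme (default 3).
#' @param max_rounds safety cap (default 25).
#' @param seed integer seed; per-round model seeds are derived from it.
#' @param dominant_metric `"max_coefficient"` (default) picks the qualified
#'   theme holding the largest above-knee coefficient;
#'   `"coefficient_variance"` picks the theme whose member coefficients have
#'   the largest variance.
#' @param penalty_grid lambda grid for the per-round lasso and ridge fits.
#' @param smooth_window knee smoothing window.
#' @return an object of class `engine_config`.
#' @export
engine_config <- function(min_theme_fraction = 0.05, min_theme_size = 2L,
                          auc_floor = 0.75, no_new_theme_patience = 3L,
                          max_rounds = 25L, seed = 1L,
                          dominant_metric = c("max_coefficient",
                                              "coefficient_variance"),
                          penalty_grid = default_penalty_grid(),
                          smooth_window = 3L) {
  if (!is_prob(min_theme_fraction)) stop_ts("min_theme_fraction must be in (0,1)")
  if (!is_prob(auc_floor)) stop_ts("auc_floor must be in (0,1)")
  if (!is_count(no_new_theme_patience, 1L)) stop_ts("patience must be >= 1")
  if (!is_count(max_rounds, 1L)) stop_ts("max_rounds must be >= 1")
  structure(list(min_theme_fraction = min_theme_fraction,
                 min_theme_size = min_theme_size,
                 auc_floor = auc_floor,
                 no_new_theme_patience = as.integer(no_new_theme_patience),
                 max_rounds = as.integer(max_rounds), seed = seed,
                 dominant_metric = match.arg(dominant_metric),
                 penalty_grid = penalty_grid,
                 smooth_window = as.integer(smooth_window)),
            class = "engine_config")
}

codebook_themes_of <- function(codebook, feature) {
  th <- codebook[[feature]]
  if (is.null(th)) character() else as.character(th)
}

#' Qualify themes among the above-knee features
#'
#' A theme qualifies in a round when the number of its coded members among
#' the selected (above-knee) features reaches
#' `max(ceiling(min_fraction * n_selected), min_size)`. The fraction rule is
#' the 5%-of-selected-features criterion; the absolute floor `min_size`
#' (default 2) encodes that a theme is a *group* of features related to one
#' concept, so a single feature can never constitute a theme - at large
#' selection sizes the fraction rule alone is binding, at small ones the
#' floor is. Set `min_size = 1` for the pure fraction rule. A feature coded
#' to several themes counts towards each of them. Selected features without
#' a codebook entry are collected under the reserved `"uncoded"` label: they
#' are reported for human coding but are never removable and never count as
#' a theme.
#'
#' @param knee a `knee_result` (or any object with a `selected` field).
#' @param codebook a `theme_codebook` (named list feature -> theme labels).
#' @param min_fraction qualification fraction (default 0.05).
#' @param min_size absolute member-count floor (default 2).
#' @return list with `themes` (named list: qualified theme -> member
#'   features), `uncoded` (selected features without codebook entries),
#'   `threshold` (the member count required), and `members_all` (every
#'   theme's members among the selection, qualified or not).
#' @export
qualify_themes <- function(knee, codebook, min_fraction = 0.05,
                           min_size = 2L) {
  selected <- if (inherits(knee, "knee_result")) knee$selected else
    knee$selected %||% knee
  if (!length(selected)) stop_ts("empty above-knee selection")
  threshold <- max(as.integer(ceiling(min_fraction * length(selected))),
                   as.integer(min_size %||% 1L))
  members <- list(); uncoded <- character()
  for (f in selected) {
    themes <- codebook_themes_of(codebook, f)
    if (!length(themes)) {
      uncoded <- c(uncoded, f)
    } else {
      for (t in themes) members[[t]] <- c(members[[t]], f)
    }
  }
  qualified <- members[vapply(members, length, 0L) >= threshold]
  list(themes = qualified, uncoded = uncoded, threshold = threshold,
       members_all = members)
}

#' Dominant theme of a round
#'
#' The qualified theme containing the feature with the largest coefficient
#' on the sorted curve; ties are broken by larger summed member coefficient,
#' then lexicographically.
#'
#' @param knee a `knee_result`.
#' @param qualified named list of qualified themes -> member features (the
#'   `themes` element of [qualify_themes()]), or that function's full
#'   result.
#' @param metric `"max_coefficient"` (default) or `"coefficient_variance"`.
#' @return the dominant theme label.
#' @export
dominant_theme <- function(knee, qualified,
                           metric = c("max_coefficient",
                                      "coefficient_variance")) {
  metric <- match.arg(metric)
  if (!is.null(qualified$themes)) qualified <- qualified$themes
  qualified <- qualified[names(qualified) != UNCODED_LABEL]
  if (!length(qualified)) stop_ts("no qualified themes")
  coefs <- stats::setNames(knee$curve, knee$sorted_features)
  score <- vapply(qualified, function(members) {
    v <- coefs[members]
    if (metric == "max_coefficient") max(v) else
      if (length(v) > 1) stats::var(v) else 0
  }, 0)
  sums <- vapply(qualified, function(members) sum(coefs[members]), 0)
  o <- order(-score, -sums, names(qualified), method = "radix")
  names(qualified)[o[1]]
}

#' Drop a removed theme's features from the pool
#'
#' A feature leaves the pool only when every theme it is coded to has been
#' removed (including the theme being removed now); features coded to a
#' still-alive theme are retained, and uncoded features are never removed.
#'
#' @param pool character vector of features currently in the model pool.
#' @param theme theme label being removed this round.
#' @param codebook a `theme_codebook`.
#' @param removed_so_far themes removed in earlier rounds.
#' @return the reduced feature pool.
#' @export
drop_theme_features <- function(pool, theme, codebook,
                                removed_so_far = character()) {
  if (theme %in% removed_so_far)
    stop_ts("theme '%s' was already removed", theme)
  dead <- union(removed_so_far, theme)
  keep <- vapply(pool, function(f) {
    themes <- codebook_themes_of(codebook, f)
    if (!length(themes)) return(TRUE)  # uncoded: never removable
    !all(themes %in% dead)
  }, TRUE)
  pool[keep]
}

#' Stopping rules for the iterative engine
#'
#' Checked after each round's qualification, in this order:
#' (c) the round's test ROC AUC is below `cfg$auc_floor`
#' (`"auc_below_floor"`); (b) the round's above-knee set introduced no
#' feature unseen in prior rounds (`"no_new_features"`); (a) the last
#' `cfg$no_new_theme_patience` rounds each produced zero new themes
#' (`"no_new_themes"`).
#'
#' @param history list of iteration records, the current round last. Each
#'   record needs `knee$selected` and `new_themes`.
#' @param current_metrics the current round's `metric_set`.
#' @param cfg an `engine_config`.
#' @return list `(stop = flag, reason = label or NA)`.
#' @export
stopping_check <- function(history, current_metrics, cfg) {
  stopifnot(length(history) >= 1L)
  if (current_metrics$roc_auc < cfg$auc_floor)
    return(list(stop = TRUE, reason = "auc_below_floor"))
  cur <- history[[length(history)]]
  prior <- history[-length(history)]
  seen <- unique(unlist(lapply(prior, function(r) r$knee$selected)))
  if (length(prior) && !length(setdiff(cur$knee$selected, seen)))
    return(list(stop = TRUE, reason = "no_new_features"))
  p <- cfg$no_new_theme_patience
  if (length(history) >= p) {
    recent <- tail(history, p)
    if (all(vapply(recent, function(r) length(r$new_themes) == 0L, TRUE)))
      return(list(stop = TRUE, reason = "no_new_themes"))
  }
  list(stop = FALSE, reason = NA_character_)
}

#' Run the iterative thematic categorization
#'
#' Each round, on the current feature pool and the fixed train/test split:
#' fit the lasso, keep its nonzero features, refit them with the ridge,
#' select the above-knee features, evaluate on the test split, qualify
#' themes, detect new themes (themes qualifying now that never qualified
#' before), check the stopping rules, and - when continuing - remove the
#' dominant theme's features from the pool. Lasso and ridge penalties are
#' re-selected by cross-validation every round; per-round seeds advance
#' deterministically from `cfg$seed`. The split is never redrawn.
#'
#' @param fm the full `feature_matrix` (already normalized).
#' @param split a `split_plan`.
#' @param codebook a `theme_codebook`.
#' @param cfg an `engine_config`.
#' @return an object of class `run_report`: `iterations` (per-round
#'   records), `theme_table` (theme -> union of qualified members across
#'   rounds), `removed_order`, `stop_reason`, `split_checksum`, `config`.
#' @export
run_iterations <- function(fm, split, codebook, cfg = engine_config()) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(split, "split_plan"),
            inherits(cfg, "engine_config"))
  pool <- fm$feature_names
  if (!length(pool)) stop_ts("empty feature pool")
  removed <- character()
  ever_qualified <- character()
  theme_table <- list()
  history <- list()
  stop_reason <- "max_rounds"
  split_checksum <- index_checksum(split$test_idx)

  for (round in seq_len(cfg$max_rounds)) {
    fm_round <- subset_features(fm, pool)
    lasso <- fit_lasso(fm_round, split, penalty_grid = cfg$penalty_grid)
    nz <- select_nonzero(lasso)
    if (!length(nz)) {
      history[[round]] <- list(round = round, feature_pool = pool,
                               knee = NULL, metrics = NULL,
                               qualified_themes = list(),
                               uncoded = character(),
                               new_themes = character(),
                               removed_theme = NA_character_,
                               stop_reason = "no_features_selected",
                               split_checksum = split_checksum)
      stop_reason <- "no_features_selected"
      break
    }
    ridge <- fit_ridge(fm, split, penalty_grid = cfg$penalty_grid,
                       features = nz)
    knee <- withCallingHandlers(
      select_above_knee(ridge, smooth_window = cfg$smooth_window),
      warning = function(w) invokeRestart("muffleWarning"))
    metrics <- evaluate_fit(ridge, fm, split)
    qual <- qualify_themes(knee, codebook,
                           min_fraction = cfg$min_theme_fraction,
                           min_size = cfg$min_theme_size)
    new_themes <- setdiff(names(qual$themes), ever_qualified)
    ever_qualified <- union(ever_qualified, names(qual$themes))
    for (t in names(qual$themes))
      theme_table[[t]] <- sort(union(theme_table[[t]] %||% character(),
                                     qual$themes[[t]]), method = "radix")

    rec <- list(round = round, feature_pool = pool, knee = knee,
                metrics = metrics, qualified_themes = qual$themes,
                uncoded = qual$uncoded, qualification_threshold = qual$threshold,
                new_themes = new_themes, removed_theme = NA_character_,
                stop_reason = NA_character_, split_checksum = split_checksum,
                lasso_penalty = lasso$penalty, ridge_penalty = ridge$penalty)
    history[[round]] <- rec

    chk <- stopping_check(history, metrics, cfg)
    if (chk$stop) {
      history[[round]]$stop_reason <- chk$reason
      stop_reason <- chk$reason
      break
    }
    if (!length(qual$themes)) {
      history[[round]]$stop_reason <- "no_qualified_themes"
      stop_reason <- "no_qualified_themes"
      break
    }
    dom <- dominant_theme(knee, qual$themes, metric = cfg$dominant_metric)
    new_pool <- drop_theme_features(pool, dom, codebook, removed)
    removed <- c(removed, dom)
    history[[round]]$removed_theme <- dom
    if (!length(new_pool)) {
      history[[round]]$stop_reason <- "empty_pool"
      stop_reason <- "empty_pool"
      break
    }
    pool <- new_pool
  }

  structure(list(iterations = history, theme_table = theme_table,
                 removed_order = removed, stop_reason = stop_reason,
                 split_checksum = split_checksum, config = cfg),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report: %d rounds, stop = %s\n",
              length(x$iterations), x$stop_reason))
  for (r in x$iterations) {
    if (is.null(r$metrics)) {
      cat(sprintf("  round %d: lasso selected no features\n", r$round))
      next
    }
    cat(sprintf(
      "  round %d: pool %d | above-knee %d | AUC %.3f BER %.3f | new: %s | removed: %s\n",
      r$round, length(r$feature_pool), length(r$knee$selected),
      r$metrics$roc_auc, r$metrics$ber,
      if (length(r$new_themes)) paste(r$new_themes, collapse = ",") else "-",
      if (is.na(r$removed_theme)) "-" else r$removed_theme))
  }
  invisible(x)
}
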