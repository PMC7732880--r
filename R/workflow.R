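# End-to-end workflow: one call runs screening, encoding, the fixed split,
# the three model strategies (traditional logistic, lasso->ridge, lasso->
# neural network), test-split evaluation, knee selection, and the iterative
# thematic categorization, then writes all artifacts to a run directory.

#' Build a run configuration
#'
#' Either pass the in-memory objects (`table`, `codebook`) or file paths
#' (`data_path` CSV, `codebook_path` JSON). Paths are validated up front.
#'
#' @param table survey data.frame (alternative to `data_path`).
#' @param codebook `theme_codebook` (alternative to `codebook_path`).
#' @param data_path CSV path of the survey table.
#' @param codebook_path JSON codebook path.
#' @param out_dir output directory; `NULL` skips writing artifacts. When
#'   `timestamp_dir` is `TRUE` a timestamped subdirectory is created.
#' @param exclusion_patterns glob patterns for [screen_variables()].
#' @param outcome outcome column name.
#' @param test_fraction,k,stratify split options (see [make_split()]).
#' @param penalty_grid lambda grid for lasso and ridge.
#' @param nn an `nn_config` or `NULL` to skip the neural network.
#' @param engine an `engine_config` or `NULL` to use defaults.
#' @param seed mandatory global seed; stage seeds are derived from it.
#' @param timestamp_dir create a timestamped subdirectory of `out_dir`.
#' @return an object of class `run_config`.
#' @export
run_config <- function(table = NULL, codebook = NULL, data_path = NULL,
                       codebook_path = NULL, out_dir = NULL,
                       exclusion_patterns = character(),
                       outcome = "child_marriage", test_fraction = 0.2,
                       k = 5L, stratify = TRUE,
                       penalty_grid = default_penalty_grid(),
                       nn = nn_config(), engine = NULL, seed,
                       timestamp_dir = FALSE) {
  if (missing(seed)) stop_ts("a global seed is mandatory")
  if (is.null(table) && is.null(data_path))
    stop_ts("either 'table' or 'data_path' is required")
  if (!is.null(data_path) && !file.exists(data_path))
    stop_ts("data_path '%s' does not exist", data_path)
  if (is.null(codebook) && is.null(codebook_path))
    stop_ts("either 'codebook' or 'codebook_path' is required")
  if (!is.null(codebook_path) && !file.exists(codebook_path))
    stop_ts("codebook_path '%s' does not exist", codebook_path)
  structure(list(table = table, codebook = codebook, data_path = data_path,
                 codebook_path = codebook_path, out_dir = out_dir,
                 exclusion_patterns = exclusion_patterns, outcome = outcome,
                 test_fraction = test_fraction, k = as.integer(k),
                 stratify = isTRUE(stratify), penalty_grid = penalty_grid,
                 nn = nn, engine = engine, seed = seed,
                 timestamp_dir = isTRUE(timestamp_dir)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Scalar options of [run_config()] can be given in a YAML file; nested
#' `nn:` and `engine:` maps become [nn_config()] / [engine_config()] calls.
#'
#' @param path YAML file.
#' @param ... overrides passed on to [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  nn <- if (!is.null(raw$nn)) do.call(nn_config, raw$nn) else nn_config()
  engine <- if (!is.null(raw$engine)) do.call(engine_config, raw$engine)
  raw$nn <- NULL; raw$engine <- NULL
  args <- c(raw, list(nn = nn, engine = engine), list(...))
  do.call(run_config, args)
}

#' Run the full analysis
#'
#' Executes preprocess -> {traditional, lasso->ridge, lasso->neural-network}
#' -> test-split evaluation -> knee selection -> iterative thematic
#' categorization, all on one fixed split. Returns (and optionally writes)
#' the complete results.
#'
#' @param cfg a `run_config`.
#' @return an object of class `full_analysis`: `metrics` (per-model
#'   `metric_set`s), `model_table` (data.frame of AUC/BER per model),
#'   `knee` (round-0 ridge `knee_result`), `report` (the engine
#'   `run_report`), `split`, `prevalence`, `seed`, and `out_dir` (or `NULL`).
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  table <- cfg$table %||% read_survey_csv(cfg$data_path)
  codebook <- cfg$codebook %||% read_codebook_json(cfg$codebook_path)
  engine_cfg <- cfg$engine %||%
    engine_config(seed = child_seed(cfg$seed, 40L),
                  penalty_grid = cfg$penalty_grid)

  table <- screen_variables(table, cfg$exclusion_patterns,
                            outcome = cfg$outcome)
  fm <- one_hot_encode(table, outcome = cfg$outcome)
  split <- make_split(nrow(fm$values), test_fraction = cfg$test_fraction,
                      k = cfg$k, seed = child_seed(cfg$seed, 10L),
                      outcome = fm$outcome, stratify = cfg$stratify)
  fm <- normalize_continuous(fm, split)

  trad <- fit_traditional_logistic(fm, split)
  lasso <- fit_lasso(fm, split, penalty_grid = cfg$penalty_grid)
  nz <- select_nonzero(lasso)
  ridge <- if (length(nz))
    fit_ridge(fm, split, penalty_grid = cfg$penalty_grid, features = nz)
  else fit_intercept_only(fm, split)

  metrics <- list(traditional = evaluate_fit(trad, fm, split),
                  ridge = evaluate_fit(ridge, fm, split))
  fits <- list(traditional = trad, lasso = lasso, ridge = ridge)

  if (!is.null(cfg$nn) && length(nz)) {
    nn_cfg <- cfg$nn
    nn_cfg$seed <- child_seed(cfg$seed, 20L)
    nn <- fit_neural_network(fm, split, cfg = nn_cfg, features = nz)
    metrics$neural_net <- evaluate_fit(nn, fm, split)
    fits$neural_net <- nn
  }

  knee <- if (length(nz)) withCallingHandlers(
    select_above_knee(ridge, smooth_window = engine_cfg$smooth_window),
    warning = function(w) invokeRestart("muffleWarning")) else NULL

  report <- run_iterations(fm, split, codebook, engine_cfg)

  model_table <- do.call(rbind, lapply(names(metrics), function(nm) {
    m <- metrics[[nm]]
    data.frame(model = nm, roc_auc = m$roc_auc, ber = m$ber,
               tpr = m$tpr, tnr = m$tnr, stringsAsFactors = FALSE)
  }))

  res <- structure(list(metrics = metrics, model_table = model_table,
                        fits = fits, knee = knee, report = report,
                        split = split, prevalence = mean(fm$outcome),
                        seed = cfg$seed, out_dir = NULL),
                   class = "full_analysis")
  if (!is.null(cfg$out_dir)) res$out_dir <- write_run_artifacts(res, cfg)
  res
}

#' @export
print.full_analysis <- function(x, ...) {
  cat(sprintf("full_analysis (seed %s, prevalence %.3f)\n",
              format(x$seed), x$prevalence))
  tab <- x$model_table
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-12s AUC %.3f  BER %.3f\n",
                tab$model[i], tab$roc_auc[i], tab$ber[i]))
  if (!is.null(x$knee))
    cat(sprintf("  meaningful features above knee: %d\n",
                length(x$knee$selected)))
  print(x$report)
  invisible(x)
}

# --- serialization -----------------------------------------------------------

metrics_as_list <- function(m) {
  list(roc_auc = m$roc_auc, tpr = m$tpr, tnr = m$tnr, ber = m$ber,
       threshold = m$threshold, n_pos = m$n_pos, n_neg = m$n_neg)
}

iteration_as_list <- function(r) {
  list(round = r$round,
       pool_size = length(r$feature_pool),
       selected = as.list(if (is.null(r$knee)) character() else
         r$knee$selected),
       knee_index = if (is.null(r$knee)) NULL else r$knee$knee_index,
       metrics = if (is.null(r$metrics)) NULL else metrics_as_list(r$metrics),
       qualified_themes = lapply(r$qualified_themes, as.list),
       uncoded = as.list(r$uncoded %||% character()),
       qualification_threshold = r$qualification_threshold,
       new_themes = as.list(r$new_themes),
       removed_theme = r$removed_theme,
       stop_reason = r$stop_reason,
       split_checksum = r$split_checksum)
}

#' Serialize a run report (or full analysis) to a stable JSON list
#'
#' Field order is fixed so that identical runs produce byte-identical JSON.
#' @param x a `run_report` or `full_analysis`.
#' @return a plain list ready for [write_stable_json()].
#' @export
report_as_list <- function(x) {
  if (inherits(x, "full_analysis")) {
    return(list(seed = x$seed, prevalence = x$prevalence,
                models = lapply(x$metrics, metrics_as_list),
                n_meaningful_features = if (is.null(x$knee)) 0L else
                  length(x$knee$selected),
                report = report_as_list(x$report)))
  }
  stopifnot(inherits(x, "run_report"))
  list(stop_reason = x$stop_reason,
       removed_order = as.list(x$removed_order),
       split_checksum = x$split_checksum,
       theme_table = lapply(x$theme_table, as.list),
       iterations = lapply(x$iterations, iteration_as_list))
}

write_run_artifacts <- function(res, cfg) {
  dir_out <- cfg$out_dir
  if (cfg$timestamp_dir)
    dir_out <- file.path(dir_out, format(Sys.time(), "run_%Y%m%d_%H%M%S"))
  dir.create(dir_out, recursive = TRUE, showWarnings = FALSE)

  # resolved config echo (sufficient to re-execute)
  write_stable_json(list(
    seed = cfg$seed, outcome = cfg$outcome,
    exclusion_patterns = as.list(cfg$exclusion_patterns),
    test_fraction = cfg$test_fraction, k = cfg$k, stratify = cfg$stratify,
    penalty_grid = cfg$penalty_grid,
    nn = if (is.null(cfg$nn)) NULL else unclass(cfg$nn),
    engine = if (is.null(cfg$engine)) NULL else {
      e <- unclass(cfg$engine); e$penalty_grid <- NULL; e
    }), file.path(dir_out, "config.json"))

  write_stable_json(report_as_list(res), file.path(dir_out, "report.json"))
  utils::write.csv(res$model_table, file.path(dir_out, "model_metrics.csv"),
                   row.names = FALSE)

  rounds <- Filter(function(r) !is.null(r$metrics), res$report$iterations)
  if (length(rounds)) {
    utils::write.csv(do.call(rbind, lapply(rounds, function(r)
      data.frame(round = r$round, pool_size = length(r$feature_pool),
                 n_selected = length(r$knee$selected),
                 roc_auc = r$metrics$roc_auc, ber = r$metrics$ber,
                 removed_theme = r$removed_theme %||% NA_character_,
                 new_themes = paste(r$new_themes, collapse = ";"),
                 stringsAsFactors = FALSE))),
      file.path(dir_out, "metrics_by_round.csv"), row.names = FALSE)
    cb <- res_codebook(res, cfg)
    per_round <- do.call(rbind, lapply(rounds, function(r) {
      kt <- knee_table(r$knee)
      kt$round <- r$round
      kt$themes <- vapply(kt$feature, function(f)
        paste(codebook_themes_of(cb, f), collapse = ";"), "")
      kt
    }))
    utils::write.csv(per_round, file.path(dir_out, "features_by_round.csv"),
                     row.names = FALSE)
  }
  if (length(res$report$theme_table)) {
    tt <- res$report$theme_table
    utils::write.csv(do.call(rbind, lapply(names(tt), function(t)
      data.frame(theme = t, feature = tt[[t]], stringsAsFactors = FALSE))),
      file.path(dir_out, "theme_table.csv"), row.names = FALSE)
  }
  dir_out
}

res_codebook <- function(res, cfg) {
  cfg$codebook %||% read_codebook_json(cfg$codebook_path)
}

#' Render a completed run directory as human-readable text
#'
#' Per-model metrics table, the stop reason, the per-round AUC/BER path, and
#' the final theme table with themes listed in removal order.
#'
#' @param run_dir directory written by [run_full_analysis()].
#' @return the summary lines, invisibly; they are also printed.
#' @export
render_report <- function(run_dir) {
  report_path <- file.path(run_dir, "report.json")
  metrics_path <- file.path(run_dir, "model_metrics.csv")
  if (!file.exists(report_path) || !file.exists(metrics_path))
    stop_ts("'%s' is not a complete run directory", run_dir)
  rep <- jsonlite::read_json(report_path)
  if (!length(rep$report$iterations %||% rep$iterations))
    stop_ts("run report contains no iterations")
  body <- rep$report %||% rep
  lines <- character()
  push <- function(...) lines <<- c(lines, sprintf(...))

  push("== Model comparison (test split) ==")
  mt <- utils::read.csv(metrics_path, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(mt)))
    push("  %-12s AUC %.3f  BER %.3f", mt$model[i], mt$roc_auc[i], mt$ber[i])

  push("== Iterative categorization: stop reason: %s ==", body$stop_reason)
  for (r in body$iterations) {
    if (is.null(r$metrics)) { push("  round %d: no features selected", r$round); next }
    push("  round %d: AUC %.3f BER %.3f | selected %d | new themes: %s | removed: %s",
         r$round, r$metrics$roc_auc, r$metrics$ber, length(r$selected),
         if (length(r$new_themes)) paste(unlist(r$new_themes), collapse = ",")
         else "-",
         r$removed_theme %||% "-")
  }
  push("== Themes (in removal order, then remaining) ==")
  ordered <- unique(c(unlist(body$removed_order),
                      names(body$theme_table)))
  for (t in ordered) {
    push("  [%s]", t)
    for (f in unlist(body$theme_table[[t]])) push("    %s", f)
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
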