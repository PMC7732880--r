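# Synthetic survey generator: wide categorical tables with planted thematic
# effects, calibrated outcome prevalence, and optional latent-copula masking
# between a dominant and a weaker theme.

#' Generate a survey variable schema and theme codebook
#'
#' Builds a schema of categorical and continuous survey variables. Themed
#' categorical variables are organized into `n_themes` blocks of
#' `vars_per_theme` variables each; additional pure-noise categorical
#' variables and continuous variables are appended. Per-variable category
#' probabilities are drawn from a symmetric Dirichlet (concentration 1).
#' Continuous variables receive a random location and scale so that the
#' normalization stage downstream is genuinely exercised.
#'
#' The returned codebook maps every one-hot feature of a themed variable
#' (named `"variable: level"`) to its theme label. Noise and continuous
#' variables are deliberately left uncoded.
#'
#' @param n_themes number of thematic variable blocks.
#' @param vars_per_theme categorical variables per theme.
#' @param n_noise_vars uncoded pure-noise categorical variables.
#' @param n_continuous continuous variables (uncoded).
#' @param levels_range integer pair: min/max number of category levels,
#'   within `[2, 20]`.
#' @param seed integer seed; identical seeds give identical schemas.
#' @param theme_labels optional character vector of length `n_themes`.
#' @param min_level_prob optional lower bound on themed variables' category
#'   probabilities (rejection-sampled Dirichlet). Planted effect levels are
#'   placed on the first level of themed variables; bounding its prevalence
#'   mimics the common survey categories (education, wealth quintiles) that
#'   carry signal in real data. `NULL` disables the bound.
#' @return a list with elements `schema` (class `survey_schema`) and
#'   `codebook` (class `theme_codebook`).
#' @export
generate_schema <- function(n_themes, vars_per_theme, n_noise_vars,
                            n_continuous, levels_range = c(2L, 4L), seed,
                            theme_labels = NULL, min_level_prob = NULL) {
  stopifnot(is_count(n_themes), is_count(vars_per_theme),
            is_count(n_noise_vars), is_count(n_continuous))
  if (length(levels_range) != 2L || levels_range[1] < 2L ||
      levels_range[2] > 20L || levels_range[1] > levels_range[2])
    stop_ts("levels_range must be an increasing pair within [2, 20]")
  n_cat <- n_themes * vars_per_theme + n_noise_vars
  if (n_cat + n_continuous <= 0L)
    stop_ts("schema must contain at least one variable")
  if (is.null(theme_labels)) {
    theme_labels <- sprintf("theme_%02d", seq_len(n_themes))
  } else if (length(theme_labels) != n_themes || anyDuplicated(theme_labels)) {
    stop_ts("theme_labels must be %d distinct labels", n_themes)
  }

  withr::with_seed(seed, {
    vars <- list()
    add_categorical <- function(name, theme) {
      choices <- seq.int(levels_range[1], levels_range[2])
      k <- if (length(choices) == 1L) choices else sample(choices, 1L)
      probs <- draw_dirichlet(k, min_prob = if (!is.null(theme)) min_level_prob)
      list(name = name, kind = "categorical",
           levels = sprintf("l%d", seq_len(k)), probs = probs, theme = theme)
    }
    for (t in seq_len(n_themes)) {
      for (j in seq_len(vars_per_theme)) {
        nm <- sprintf("%s_var%d", theme_labels[t], j)
        vars[[length(vars) + 1L]] <- add_categorical(nm, theme_labels[t])
      }
    }
    for (i in seq_len(n_noise_vars)) {
      vars[[length(vars) + 1L]] <-
        add_categorical(sprintf("noise%03d", i), NULL)
    }
    for (i in seq_len(n_continuous)) {
      vars[[length(vars) + 1L]] <- list(
        name = sprintf("cont%02d", i), kind = "continuous",
        levels = NULL, probs = NULL, theme = NULL,
        mu = runif(1, -5, 5), sigma = runif(1, 0.5, 3))
    }
    schema <- structure(list(variables = vars), class = "survey_schema")
    list(schema = schema, codebook = codebook_from_schema(schema))
  })
}

# Symmetric Dirichlet(1) draw, optionally rejection-sampled so that no
# category is rarer than min_prob (keeps planted effect levels observable).
draw_dirichlet <- function(k, min_prob = NULL) {
  for (i in seq_len(1000L)) {
    g <- rgamma(k, shape = 1)
    p <- g / sum(g)
    if (is.null(min_prob) || min(p) >= min_prob) return(p)
  }
  stop_ts("could not draw level probabilities with min_prob = %g", min_prob)
}

codebook_from_schema <- function(schema) {
  cb <- list()
  for (v in schema$variables) {
    if (!is.null(v$theme)) {
      for (lv in v$levels) cb[[feature_name(v$name, lv)]] <- v$theme
    }
  }
  structure(cb, class = "theme_codebook")
}

feature_name <- function(variable, level) paste0(variable, ": ", level)

#' @export
print.survey_schema <- function(x, ...) {
  kinds <- vapply(x$variables, `[[`, "", "kind")
  cat(sprintf("survey_schema: %d variables (%d categorical, %d continuous)\n",
              length(x$variables), sum(kinds == "categorical"),
              sum(kinds == "continuous")))
  invisible(x)
}

schema_variable_names <- function(schema)
  vapply(schema$variables, `[[`, "", "name")

#' Construct a planted ground truth
#'
#' Describes the data-generating logistic model: per-feature log-odds
#' effects (names follow the `"variable: level"` one-hot convention, or a
#' bare variable name for continuous variables), the theme responsible for
#' each nonzero effect, and the target outcome prevalence to which the
#' intercept is calibrated at generation time.
#'
#' @param effects named numeric vector of log-odds effects.
#' @param theme_of_effect named character vector mapping each nonzero-effect
#'   feature to a theme label; may be `NULL` when no effect is themed.
#' @param target_prevalence outcome prevalence in (0, 1).
#' @return an object of class `planted_truth`.
#' @export
planted_truth <- function(effects, theme_of_effect = NULL,
                          target_prevalence = 0.41) {
  stopifnot(is.numeric(effects))
  if (length(effects) && is.null(names(effects)))
    stop_ts("effects must be named by feature")
  if (!is_prob(target_prevalence))
    stop_ts("target_prevalence must lie strictly inside (0, 1)")
  nonzero <- names(effects)[effects != 0]
  theme_of_effect <- theme_of_effect[names(theme_of_effect) %in% nonzero]
  structure(list(intercept = NA_real_, effects = effects,
                 theme_of_effect = theme_of_effect,
                 target_prevalence = target_prevalence),
            class = "planted_truth")
}

#' Tabulate the planted nonzero effects
#'
#' One row per nonzero planted effect, with its theme (empty string when the
#' effect is unthemed). Used as the oracle table in recovery tests.
#'
#' @param truth a `planted_truth` object.
#' @return a data.frame with columns `feature`, `effect`, `theme`.
#' @export
planted_truth_report <- function(truth) {
  stopifnot(inherits(truth, "planted_truth"))
  nz <- truth$effects[truth$effects != 0]
  th <- truth$theme_of_effect
  data.frame(
    feature = names(nz) %||% character(),
    effect = unname(nz),
    theme = vapply(names(nz) %||% character(),
                   function(f) th[[f]] %||% "", ""),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Generate a synthetic survey table
#'
#' Draws respondents from the schema's marginal distributions and a binary
#' outcome from a logistic model with the planted effects. The intercept is
#' calibrated by bisection against the Monte-Carlo prevalence on the
#' generated covariates, so the empirical outcome prevalence matches
#' `truth$target_prevalence`. An optional masking spec links the latent
#' Gaussians behind two themes' categorical variables through a shared
#' factor (a one-factor Gaussian copula with pairwise correlation `rho`),
#' producing the phenomenon where a weaker theme's association is hidden
#' behind a dominant correlated theme.
#'
#' @param schema a `survey_schema`.
#' @param truth a `planted_truth`; effect names must resolve to schema
#'   features.
#' @param n number of respondents (>= 1).
#' @param masking `NULL`, or `list(dominant = <theme>, weak = <theme>,
#'   rho = <0..1>)`.
#' @param seed integer seed; identical inputs give identical tables.
#' @param calib_tol prevalence calibration tolerance (bisection stops when
#'   the Monte-Carlo prevalence is within this of the target).
#' @param calib_max_steps bisection step cap.
#' @return a `data.frame` with one column per schema variable plus the
#'   binary outcome column `child_marriage`. The calibrated intercept is
#'   attached as attribute `"intercept"`.
#' @export
generate_survey <- function(schema, truth, n, masking = NULL, seed,
                            calib_tol = 0.005, calib_max_steps = 50L) {
  stopifnot(inherits(schema, "survey_schema"), inherits(truth, "planted_truth"))
  if (!is_count(n, min = 1L)) stop_ts("n must be a positive count")
  valid <- schema_feature_universe(schema)
  bad <- setdiff(names(truth$effects), valid)
  if (length(bad))
    stop_ts("effect name(s) not resolvable in schema: %s",
            paste(bad, collapse = ", "))
  if (!is.null(masking)) {
    stopifnot(is.list(masking), !is.null(masking$dominant),
              !is.null(masking$weak))
    masking$rho <- masking$rho %||% 0.4
    stopifnot(masking$rho >= 0, masking$rho < 1)
  }

  withr::with_seed(seed, {
    masked_themes <- if (is.null(masking)) character() else
      c(masking$dominant, masking$weak)
    factor_z <- if (length(masked_themes)) rnorm(n) else NULL

    cols <- list()
    eta <- numeric(n)
    for (v in schema$variables) {
      if (v$kind == "categorical") {
        if (!is.null(v$theme) && v$theme %in% masked_themes) {
          z <- sqrt(masking$rho) * factor_z + sqrt(1 - masking$rho) * rnorm(n)
          u <- stats::pnorm(z)
        } else {
          u <- runif(n)
        }
        lev_idx <- findInterval(u, cumsum(v$probs), left.open = TRUE) + 1L
        lev_idx[lev_idx > length(v$levels)] <- length(v$levels)
        x <- v$levels[lev_idx]
        for (lv in v$levels) {
          b <- truth$effects[feature_name(v$name, lv)]
          if (!is.na(b) && b != 0) eta <- eta + b * (x == lv)
        }
        cols[[v$name]] <- x
      } else {
        raw <- rnorm(n)
        b <- truth$effects[v$name]
        if (!is.na(b) && b != 0) eta <- eta + b * raw  # effect on z-scale
        cols[[v$name]] <- v$mu + v$sigma * raw
      }
    }

    intercept <- calibrate_intercept(eta, truth$target_prevalence,
                                     tol = calib_tol,
                                     max_steps = calib_max_steps)
    y <- rbinom(n, 1L, plogis(intercept + eta))
    tab <- as.data.frame(cols, stringsAsFactors = FALSE,
                         check.names = FALSE)
    tab$child_marriage <- y
    attr(tab, "intercept") <- intercept
    tab
  })
}

schema_feature_universe <- function(schema) {
  out <- character()
  for (v in schema$variables) {
    out <- c(out, if (v$kind == "categorical")
      feature_name(v$name, v$levels) else v$name)
  }
  out
}

# Bisection on the intercept against the Monte-Carlo prevalence evaluated on
# the realized linear predictor; no closed form exists under mixed designs.
calibrate_intercept <- function(eta, target, tol = 0.005, max_steps = 50L) {
  lo <- -30; hi <- 30
  for (step in seq_len(max_steps)) {
    mid <- (lo + hi) / 2
    p <- mean(plogis(mid + eta))
    if (abs(p - target) <= tol) return(mid)
    if (p > target) hi <- mid else lo <- mid
  }
  stop_ts("intercept calibration did not reach tolerance %g in %d steps",
          tol, max_steps)
}

#' Write a survey table to CSV
#' @param table survey data.frame (outcome column included).
#' @param path output file path.
#' @export
write_survey_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a survey table from CSV
#' @param path CSV path with a header row.
#' @return data.frame with character categorical columns.
#' @export
read_survey_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read a theme codebook as JSON
#'
#' The JSON layout is `{"feature": ["theme", ...], ...}`; a feature may be
#' coded to several themes.
#' @param codebook named list mapping feature names to theme label vectors.
#' @param path file path.
#' @export
write_codebook_json <- function(codebook, path) {
  write_stable_json(lapply(codebook, function(x) as.list(as.character(x))),
                    path)
}

#' @rdname write_codebook_json
#' @export
read_codebook_json <- function(path) {
  raw <- jsonlite::read_json(path)
  structure(lapply(raw, function(x) unlist(x, use.names = FALSE)),
            class = "theme_codebook")
}

#' Write a theme codebook as long-format CSV (feature,theme)
#' @rdname write_codebook_json
#' @export
write_codebook_csv <- function(codebook, path) {
  rows <- do.call(rbind, lapply(names(codebook), function(f) {
    data.frame(feature = f, theme = as.character(codebook[[f]]),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write a planted truth object as JSON
#' @param truth a `planted_truth`.
#' @param path file path.
#' @export
write_truth_json <- function(truth, path) {
  write_stable_json(list(
    intercept = truth$intercept,
    effects = as.list(truth$effects),
    theme_of_effect = as.list(truth$theme_of_effect),
    target_prevalence = truth$target_prevalence), path)
}
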