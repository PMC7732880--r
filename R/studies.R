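# Canonical simulation presets. These fix the study conditions used by the
# package's own validation: a masked-theme design for the iterative
# procedure, a support-recovery design for the lasso->ridge stage, and a
# wide collinear design for the model-ordering comparison. Tests and the
# reproduction script both build their data through these presets.

#' Masked-theme simulation bundle
#'
#' Two themed blocks of categorical variables: a dominant theme whose
#' features carry strong positive effects, and a weak theme whose features
#' carry only a small direct effect but are correlated with the dominant
#' theme's variables through a one-factor Gaussian copula. Conditional on
#' the dominant features, the weak theme's features contribute almost
#' nothing, so their round-1 ridge coefficients sit in the noise band below
#' the knee; once the dominant theme's features are removed they inherit its
#' signal through the correlation and surface as a new theme - the masking
#' phenomenon the iterative procedure is designed to reveal.
#'
#' Defaults: 4 variables of 3 levels per theme; graded effects on each
#' variable's first level (+1.2/+1.5/+1.8/+2.1 across the dominant theme's
#' variables, +0.10/+0.13/+0.17/+0.20 across the weak theme's, mirroring the
#' gradual decay of real coefficient tables); copula correlation 0.4;
#' 25 noise categorical variables; 3 continuous variables; outcome
#' prevalence 0.41; n = 4000.
#'
#' @param seed integer seed.
#' @param n respondents.
#' @param beta_dominant,beta_weak planted log-odds effects, one per themed
#'   variable (recycled if shorter).
#' @param rho copula correlation between the two themes' latent variables.
#' @return list with `table`, `codebook`, `truth`, `schema`, and the theme
#'   labels `dominant`, `weak`.
#' @export
sim_masked_themes <- function(seed, n = 4000,
                              beta_dominant = c(1.2, 1.5, 1.8, 2.1),
                              beta_weak = c(0.10, 0.13, 0.17, 0.20),
                              rho = 0.4) {
  labels <- c("dominant_theme", "masked_theme")
  sc <- generate_schema(n_themes = 2L, vars_per_theme = 4L,
                        n_noise_vars = 25L, n_continuous = 3L,
                        levels_range = c(3L, 3L),
                        seed = child_seed(seed, 1L),
                        theme_labels = labels, min_level_prob = 0.15)
  effects <- numeric()
  counts <- c(0L, 0L)
  for (v in sc$schema$variables) {
    if (!is.null(v$theme)) {
      ti <- match(v$theme, labels)
      counts[ti] <- counts[ti] + 1L
      bvec <- if (ti == 1L) beta_dominant else beta_weak
      b <- bvec[((counts[ti] - 1L) %% length(bvec)) + 1L]
      effects[feature_name(v$name, v$levels[1])] <- b
    }
  }
  theme_of <- vapply(names(effects), function(f) sc$codebook[[f]][1], "")
  truth <- planted_truth(effects, theme_of, target_prevalence = 0.41)
  tab <- generate_survey(sc$schema, truth, n = n,
                         masking = list(dominant = labels[1],
                                        weak = labels[2], rho = rho),
                         seed = child_seed(seed, 2L))
  list(table = tab, codebook = sc$codebook, truth = truth,
       schema = sc$schema, dominant = labels[1], weak = labels[2])
}

#' Support-recovery simulation bundle
#'
#' 250 binary categorical variables (500 one-hot features), 20 of which are
#' informative: a positive effect drawn uniformly from
#' `[beta_range[1], beta_range[2]]` is planted on the first level of each
#' informative variable. Informative levels are kept at prevalence >= 0.15
#' so the planted signal is observable at realistic sample sizes, mirroring
#' the common survey categories that carry signal in real data.
#'
#' @param seed integer seed.
#' @param n respondents (default 5000).
#' @param n_informative informative variables (default 20).
#' @param n_vars total binary variables (default 250, i.e. 500 features).
#' @param beta_range positive effect-magnitude range.
#' @return list with `table`, `codebook`, `truth`, `schema`, and
#'   `planted_features` (the informative one-hot feature names).
#' @export
sim_support_recovery <- function(seed, n = 5000, n_informative = 20L,
                                 n_vars = 250L, beta_range = c(0.75, 1.5)) {
  stopifnot(n_informative <= n_vars)
  sc <- generate_schema(n_themes = 1L, vars_per_theme = n_informative,
                        n_noise_vars = n_vars - n_informative,
                        n_continuous = 0L, levels_range = c(2L, 2L),
                        seed = child_seed(seed, 1L),
                        theme_labels = "informative", min_level_prob = 0.15)
  themed <- Filter(function(v) !is.null(v$theme), sc$schema$variables)
  planted <- vapply(themed, function(v) feature_name(v$name, v$levels[1]), "")
  effects <- withr::with_seed(child_seed(seed, 3L), {
    stats::setNames(runif(length(planted), beta_range[1], beta_range[2]),
                    planted)
  })
  theme_of <- stats::setNames(rep("informative", length(planted)), planted)
  truth <- planted_truth(effects, theme_of, target_prevalence = 0.41)
  tab <- generate_survey(sc$schema, truth, n = n, masking = NULL,
                         seed = child_seed(seed, 2L))
  list(table = tab, codebook = sc$codebook, truth = truth,
       schema = sc$schema, planted_features = planted)
}

#' Wide collinear simulation bundle (p comparable to n)
#'
#' 100 categorical variables of 3 levels (300 one-hot features) plus 20
#' continuous variables, against a default n of 350 (280 training rows), so
#' the unregularized logistic fit is rank-deficient and overfits while the
#' regularized pipeline does not. Ten variables form one informative theme
#' with effects +1.2 and are made collinear through a copula (rho = 0.5).
#'
#' @param seed integer seed.
#' @param n respondents (default 350).
#' @return list with `table`, `codebook`, `truth`, `schema`.
#' @export
sim_wide_collinear <- function(seed, n = 350) {
  sc <- generate_schema(n_themes = 1L, vars_per_theme = 10L,
                        n_noise_vars = 90L, n_continuous = 20L,
                        levels_range = c(3L, 3L),
                        seed = child_seed(seed, 1L),
                        theme_labels = "signal", min_level_prob = 0.15)
  effects <- numeric()
  for (v in sc$schema$variables) {
    if (!is.null(v$theme)) effects[feature_name(v$name, v$levels[1])] <- 1.2
  }
  theme_of <- stats::setNames(rep("signal", length(effects)), names(effects))
  truth <- planted_truth(effects, theme_of, target_prevalence = 0.41)
  # reuse the masking machinery to induce collinearity within the block:
  # dominant and weak set to the same theme links all its variables.
  tab <- generate_survey(sc$schema, truth, n = n,
                         masking = list(dominant = "signal", weak = "signal",
                                        rho = 0.5),
                         seed = child_seed(seed, 2L))
  list(table = tab, codebook = sc$codebook, truth = truth, schema = sc$schema)
}
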