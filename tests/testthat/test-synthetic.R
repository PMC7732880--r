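test_that("generate_schema builds the requested variables and codebook", {
  sc <- generate_schema(2, 3, 10, 2, levels_range = c(2, 4), seed = 7)
  expect_length(sc$schema$variables, 18)
  kinds <- vapply(sc$schema$variables, `[[`, "", "kind")
  expect_equal(sum(kinds == "continuous"), 2)
  themes <- unique(unlist(sc$codebook))
  expect_length(themes, 2)
  # codebook covers exactly the themed features, in one-hot naming
  themed_vars <- Filter(function(v) !is.null(v$theme), sc$schema$variables)
  expected <- unlist(lapply(themed_vars, function(v)
    paste0(v$name, ": ", v$levels)))
  expect_setequal(names(sc$codebook), expected)
  # categorical levels within range, probabilities sum to 1
  for (v in sc$schema$variables) {
    if (v$kind == "categorical") {
      expect_gte(length(v$levels), 2)
      expect_lte(length(v$levels), 4)
      expect_equal(sum(v$probs), 1, tolerance = 1e-12)
    }
  }
})

test_that("generate_schema rejects degenerate inputs and repeats under seed", {
  expect_error(generate_schema(0, 0, 0, 0, seed = 1), "at least one variable")
  expect_error(generate_schema(1, 1, 0, 0, levels_range = c(1, 4), seed = 1))
  a <- generate_schema(2, 2, 5, 1, seed = 42)
  b <- generate_schema(2, 2, 5, 1, seed = 42)
  expect_identical(a, b)
})

test_that("planted_truth_report tabulates exactly the nonzero effects", {
  tr <- planted_truth(c(a = 1, b = 0, c = -0.5, d = 2, e = 0.3, f = 0),
                      theme_of_effect = c(a = "t1", c = "t1", d = "t2",
                                          e = "t2"))
  rep <- planted_truth_report(tr)
  expect_equal(nrow(rep), 4)
  expect_setequal(rep$feature, c("a", "c", "d", "e"))
  expect_false(any(rep$theme == ""))
  empty <- planted_truth(stats::setNames(numeric(), character()))
  expect_equal(nrow(planted_truth_report(empty)), 0)
  expect_error(planted_truth(c(a = 1), target_prevalence = 1.2), "prevalence")
})

test_that("outcome prevalence is calibrated to the target", {
  sc <- generate_schema(1, 3, 5, 1, seed = 3, min_level_prob = 0.15)
  themed <- Filter(function(v) !is.null(v$theme), sc$schema$variables)
  eff <- stats::setNames(rep(1, 3), vapply(themed, function(v)
    paste0(v$name, ": ", v$levels[1]), ""))
  tr <- planted_truth(eff, target_prevalence = 0.41)
  tab <- generate_survey(sc$schema, tr, n = 20000, seed = 5)
  # binomial sampling error on n = 20000 is ~0.0035; 0.02 is > 5 sigma plus
  # the 0.005 calibration tolerance
  expect_lt(abs(mean(tab$child_marriage) - 0.41), 0.02)
})

test_that("null effects keep prevalence and give identical tables per seed", {
  sc <- generate_schema(1, 2, 4, 1, seed = 9)
  tr <- planted_truth(stats::setNames(numeric(), character()),
                      target_prevalence = 0.41)
  a <- generate_survey(sc$schema, tr, n = 3000, seed = 21)
  b <- generate_survey(sc$schema, tr, n = 3000, seed = 21)
  expect_identical(a, b)
  expect_lt(abs(mean(a$child_marriage) - 0.41), 0.03)
})

test_that("unresolvable effect names are rejected", {
  sc <- generate_schema(1, 2, 2, 0, seed = 4)
  tr <- planted_truth(c("ghost: l1" = 1))
  expect_error(generate_survey(sc$schema, tr, n = 10, seed = 1),
               "not resolvable")
})

test_that("masking induces correlation between the two themes' variables", {
  b <- sim_masked_themes(seed = 12, n = 3000)
  dom_vars <- grep("^dominant", names(b$table), value = TRUE)
  wk_vars <- grep("^masked", names(b$table), value = TRUE)
  # indicator correlation between effect levels of the two themes
  d1 <- as.integer(b$table[[dom_vars[1]]] == "l1")
  w1 <- as.integer(b$table[[wk_vars[1]]] == "l1")
  expect_gt(cor(d1, w1), 0.1)
  # noise variables stay uncorrelated with the factor
  nz <- as.integer(b$table$noise001 == levels(factor(b$table$noise001))[1])
  expect_lt(abs(cor(d1, nz)), 0.06)
})

test_that("survey and codebook round-trip through CSV/JSON", {
  b <- sim_masked_themes(seed = 2, n = 50)
  csv <- tempfile(fileext = ".csv")
  write_survey_csv(b$table, csv)
  back <- read_survey_csv(csv)
  expect_equal(back$child_marriage, b$table$child_marriage)
  expect_equal(back$dominant_theme_var1, b$table$dominant_theme_var1)
  js <- tempfile(fileext = ".json")
  write_codebook_json(b$codebook, js)
  cb <- read_codebook_json(js)
  expect_identical(lapply(cb, unname),
                   lapply(unclass(b$codebook), function(x) unname(as.character(x))))
})
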