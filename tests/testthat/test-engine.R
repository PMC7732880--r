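make_knee <- function(coefs) {
  fit <- stub_linear_fit(coefs)
  suppressWarnings(select_above_knee(fit))
}

fake_knee <- function(selected, curve = NULL) {
  # knee_result with a prescribed selection (for qualification units)
  structure(list(sorted_features = names(curve) %||% selected,
                 curve = unname(curve) %||% rev(seq_along(selected)),
                 knee_index = length(selected) + 1L, selected = selected,
                 flat = FALSE, curvature = NULL,
                 smoothing_meta = list()), class = "knee_result")
}

test_that("theme qualification applies ceil(fraction x selected) with a
           group-size floor", {
  cb <- structure(as.list(stats::setNames(rep("A", 50), paste0("f", 1:50))),
                  class = "theme_codebook")
  cb[["g1"]] <- "B"; cb[["g2"]] <- "B"; cb[["g3"]] <- "C"

  # 40 selected: threshold ceil(0.05 * 40) = 2; B with 2 members qualifies
  sel40 <- c(paste0("f", 1:38), "g1", "g2")
  q <- qualify_themes(fake_knee(sel40), cb)
  expect_equal(q$threshold, 2L)
  expect_true("B" %in% names(q$themes))
  expect_length(q$themes$B, 2)

  # 36 selected: threshold ceil(1.8) = 2; C with 1 member fails
  sel36 <- c(paste0("f", 1:35), "g3")
  q36 <- qualify_themes(fake_knee(sel36), cb)
  expect_equal(q36$threshold, 2L)
  expect_false("C" %in% names(q36$themes))
  expect_true("A" %in% names(q36$themes))

  # the floor binds at small selection sizes: one member never qualifies
  q5 <- qualify_themes(fake_knee(c(paste0("f", 1:4), "g1")), cb)
  expect_equal(q5$threshold, 2L)
  expect_false("B" %in% names(q5$themes))
  # min_size = 1 recovers the pure fraction rule
  q5b <- qualify_themes(fake_knee(c(paste0("f", 1:4), "g1")), cb,
                        min_size = 1)
  expect_true("B" %in% names(q5b$themes))
  expect_error(qualify_themes(fake_knee(character()), cb), "empty")
})

test_that("multi-theme features count towards every theme; uncoded collect
           separately", {
  cb <- structure(list(f1 = c("A", "B"), f2 = "A", f3 = "B"),
                  class = "theme_codebook")
  q <- qualify_themes(fake_knee(c("f1", "f2", "f3", "zz")), cb)
  expect_setequal(q$themes$A, c("f1", "f2"))
  expect_setequal(q$themes$B, c("f1", "f3"))
  expect_identical(q$uncoded, "zz")
})

test_that("dominant theme follows the largest coefficient with stated
           tie-breaks", {
  curve <- c(f1 = 0.9, f2 = 0.5, f3 = 0.45, f4 = 0.4)
  kn <- fake_knee(names(curve), curve)
  # A holds the top-ranked feature
  expect_equal(dominant_theme(kn, list(A = c("f1", "f4"), B = c("f2", "f3"))),
               "A")
  # top feature coded to both: tie broken by summed member coefficient
  expect_equal(dominant_theme(kn, list(A = c("f1", "f2"),
                                       B = c("f1", "f3"))), "A")
  # full tie: lexicographic
  expect_equal(dominant_theme(kn, list(B = "f1", A = "f1")), "A")
  expect_equal(dominant_theme(kn, list(Z = c("f2", "f3"))), "Z")
  expect_error(dominant_theme(kn, list()), "no qualified themes")
})

test_that("dropping a theme respects multi-theme retention to the end", {
  cb <- structure(list("p1" = "A", "p2" = c("A", "B"), "p3" = "B",
                       "p4" = "C"), class = "theme_codebook")
  pool <- c("p1", "p2", "p3", "p4", "noise")
  after_a <- drop_theme_features(pool, "A", cb)
  expect_setequal(after_a, c("p2", "p3", "p4", "noise"))  # p2 kept: B alive
  after_b <- drop_theme_features(after_a, "B", cb, removed_so_far = "A")
  expect_setequal(after_b, c("p4", "noise"))  # p2 now drops with B
  expect_error(drop_theme_features(after_b, "A", cb,
                                   removed_so_far = c("A", "B")), "already")
})

test_that("stopping rules fire in the documented order", {
  cfg <- engine_config(seed = 1)
  rec <- function(sel, new) list(knee = list(selected = sel),
                                 new_themes = new)
  m <- function(auc) structure(list(roc_auc = auc), class = "metric_set")

  # (c) AUC floor
  chk <- stopping_check(list(rec(c("a", "b"), "T")), m(0.74), cfg)
  expect_true(chk$stop); expect_equal(chk$reason, "auc_below_floor")
  expect_false(stopping_check(list(rec(c("a"), "T")), m(0.75), cfg)$stop)

  # (b) no new features relative to prior rounds
  hist <- list(rec(c("a", "b"), "T"), rec(c("b", "a"), character()))
  chk <- stopping_check(hist, m(0.9), cfg)
  expect_true(chk$stop); expect_equal(chk$reason, "no_new_features")

  # (a) patience: three rounds without a new theme
  hist3 <- list(rec("a", "T"), rec("b", character()),
                rec("c", character()), rec("d", character()))
  chk <- stopping_check(hist3, m(0.9), cfg)
  expect_true(chk$stop); expect_equal(chk$reason, "no_new_themes")

  # AUC floor outranks the others on simultaneous firing
  chk <- stopping_check(hist3[c(1, 2, 3, 3)], m(0.5), cfg)
  expect_equal(chk$reason, "auc_below_floor")
})

test_that("the engine runs the masked-theme study end to end", {
  b <- sim_masked_themes(seed = 11)
  fm <- one_hot_encode(b$table)
  split <- make_split(nrow(fm$values), seed = 1011, outcome = fm$outcome)
  fm <- normalize_continuous(fm, split)
  rep <- run_iterations(fm, split, b$codebook, engine_config(seed = 2011))

  expect_s3_class(rep, "run_report")
  expect_true(rep$stop_reason != "max_rounds")
  # split fixity: every round carries the same test-set checksum
  checks <- vapply(rep$iterations, function(r) r$split_checksum, "")
  expect_length(unique(checks), 1)
  expect_equal(checks[1], rep$split_checksum)
  # monotone pool across removal rounds
  sizes <- vapply(rep$iterations, function(r) length(r$feature_pool), 0L)
  removed <- vapply(rep$iterations, function(r) !is.na(r$removed_theme), TRUE)
  if (length(sizes) > 1)
    expect_true(all(diff(sizes) <= 0))
  # every removed theme appears exactly once
  expect_false(any(duplicated(rep$removed_order)))
  # theme table unions qualified members across rounds
  for (t in names(rep$theme_table)) {
    members <- unlist(lapply(rep$iterations, function(r)
      r$qualified_themes[[t]]))
    expect_setequal(rep$theme_table[[t]], unique(members))
  }
})

test_that("null data stops in round one; empty codebooks stop without themes", {
  sc <- generate_schema(0, 0, 12, 2, seed = 31)
  tr <- planted_truth(stats::setNames(numeric(), character()),
                      target_prevalence = 0.41)
  tab <- generate_survey(sc$schema, tr, n = 2500, seed = 32)
  fm <- one_hot_encode(tab)
  split <- make_split(2500, seed = 33, outcome = fm$outcome)
  fm <- normalize_continuous(fm, split)
  rep <- run_iterations(fm, split, sc$codebook, engine_config(seed = 34))
  expect_equal(length(rep$iterations), 1)
  expect_true(rep$stop_reason %in%
                c("auc_below_floor", "no_features_selected",
                  "no_qualified_themes"))
  # with signal but an empty codebook everything is uncoded -> no themes
  b <- sim_masked_themes(seed = 35, n = 2000)
  fm2 <- one_hot_encode(b$table)
  sp2 <- make_split(2000, seed = 36, outcome = fm2$outcome)
  fm2 <- normalize_continuous(fm2, sp2)
  empty_cb <- structure(list(), class = "theme_codebook")
  rep2 <- run_iterations(fm2, sp2, empty_cb, engine_config(seed = 37))
  expect_equal(rep2$stop_reason, "no_qualified_themes")
  expect_gt(length(rep2$iterations[[1]]$uncoded), 0)
  expect_length(rep2$iterations[[1]]$qualified_themes, 0)
})
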