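test_that("screen_variables removes matching columns and guards the outcome", {
  tab <- data.frame(case_id = 1:4, v1 = 1:4, v2 = letters[1:4],
                    village_id = 4:1, child_marriage = c(0, 1, 0, 1))
  out <- screen_variables(tab, c("*_id"))
  expect_setequal(names(out), c("v1", "v2", "child_marriage"))
  expect_setequal(attr(out, "removed"), c("case_id", "village_id"))
  expect_identical(names(screen_variables(tab, character())), names(tab))
  expect_error(screen_variables(tab, "child_marriage"), "outcome")
  expect_error(screen_variables(tab[, 1:3], "*_id"), "not present")
})

test_that("one-hot encoding keeps every level and names features", {
  tab <- data.frame(v = c("A", "B", "C", "A"),
                    child_marriage = c(0, 1, 0, 1),
                    stringsAsFactors = FALSE)
  fm <- one_hot_encode(tab)
  expect_setequal(fm$feature_names, c("v: A", "v: B", "v: C"))
  expect_equal(unname(rowSums(fm$values)), rep(1, 4))
  # binary variable keeps both levels (no reference dropped)
  tab2 <- data.frame(b = c("x", "y", "x"), child_marriage = c(0, 1, 1))
  expect_equal(ncol(one_hot_encode(tab2)$values), 2)
})

test_that("feature count is the sum of observed levels plus continuous", {
  withr::with_seed(5, {
    tab <- as.data.frame(lapply(1:10, function(i)
      sample(paste0("l", 1:4), 200, replace = TRUE)))
    names(tab) <- paste0("c", 1:10)
    for (i in 1:5) tab[[paste0("z", i)]] <- rnorm(200)
    tab$child_marriage <- rbinom(200, 1, 0.4)
  })
  fm <- one_hot_encode(tab)
  expect_equal(ncol(fm$values), 10 * 4 + 5)
})

test_that("missing values become an explicit level; constants are flagged", {
  tab <- data.frame(v = c("A", NA, "B", NA), child_marriage = c(0, 1, 0, 1),
                    stringsAsFactors = FALSE)
  fm <- one_hot_encode(tab)
  expect_true("v: missing" %in% fm$feature_names)
  expect_equal(sum(fm$values[, "v: missing"]), 2)
  tab2 <- data.frame(v = rep("A", 4), child_marriage = c(0, 1, 0, 1))
  expect_warning(fm2 <- one_hot_encode(tab2), "single observed level")
  expect_true(all(fm2$feature_info$constant[fm2$feature_info$variable == "v"]))
})

test_that("one-hot decoding recovers the original column exactly", {
  tab <- toy_table(100, seed = 3)
  fm <- one_hot_encode(tab)
  expect_identical(decode_one_hot(fm, "x2"), tab$x2)
  expect_error(decode_one_hot(fm, "z"), "not an encoded categorical")
})

test_that("make_split partitions rows with balanced, stratified folds", {
  y <- rep(c(0, 1), c(60, 40))
  sp <- make_split(100, test_fraction = 0.2, k = 5, seed = 11, outcome = y)
  expect_length(sp$test_idx, 20)
  expect_length(sp$train_idx, 80)
  expect_setequal(c(sp$test_idx, sp$train_idx), 1:100)
  expect_true(all(table(sp$foldid) == 16))
  # stratification: test prevalence matches the population
  expect_equal(mean(y[sp$test_idx]), 0.4, tolerance = 1e-12)
  # folds contain both classes
  for (f in 1:5)
    expect_gt(length(unique(y[sp$train_idx[sp$foldid == f]])), 1)
})

test_that("make_split is reproducible and validates inputs", {
  a <- make_split(50, seed = 3, outcome = rep(0:1, 25))
  b <- make_split(50, seed = 3, outcome = rep(0:1, 25))
  expect_identical(a, b)
  expect_error(make_split(10, k = 20, seed = 1), "exceeds")
  expect_error(make_split(100, test_fraction = 1.2, k = 5, seed = 1))
})

test_that("normalization uses training statistics with population SD", {
  tab <- data.frame(z = c(1, 2, 3, 10, 20),
                    child_marriage = c(0, 1, 0, 1, 0))
  fm <- one_hot_encode(tab)
  split <- structure(list(n = 5, test_fraction = 0.4, k = 2, seed = 1,
                          stratified = FALSE, test_idx = c(4L, 5L),
                          train_idx = 1:3, foldid = c(1L, 2L, 1L)),
                     class = "split_plan")
  nf <- normalize_continuous(fm, split)
  expect_equal(nf$values[1:3, "z"], c(-1.2247449, 0, 1.2247449),
               tolerance = 1e-6)
  # test rows use the SAME transform (no leakage): mean/sd from train only
  expect_equal(unname(nf$values[4, "z"]), (10 - 2) / sqrt(2 / 3),
               tolerance = 1e-6)
  # train stats exactly 0/1, test stats differ
  expect_equal(mean(nf$values[1:3, "z"]), 0, tolerance = 1e-12)
  expect_gt(abs(mean(nf$values[4:5, "z"])), 1)
})

test_that("already-standardized columns are preserved; constants rejected", {
  withr::with_seed(8, z <- as.vector(scale(rnorm(40))) * sqrt(40 / 39))
  tab <- data.frame(z = z, child_marriage = rep(0:1, 20))
  fm <- one_hot_encode(tab)
  split <- make_split(40, seed = 1, outcome = fm$outcome)
  nf <- normalize_continuous(fm, split)
  expect_equal(cor(nf$values[, "z"], z), 1, tolerance = 1e-12)
  tab$z <- 1
  fmc <- one_hot_encode(tab)
  expect_error(normalize_continuous(fmc, split), "constant")
})
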