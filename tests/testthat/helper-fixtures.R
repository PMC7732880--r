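# Shared fixtures and independent oracles. Oracles deliberately use the
# crudest possible formulation (pair enumeration, explicit confusion counts,
# brute-force argmax) so they stay independent of the implementation path
# they check.

# tiny survey table with a known signal on one binary variable
toy_table <- function(n = 400, seed = 1, beta = 1.5) {
  withr::with_seed(seed, {
    x1 <- sample(c("yes", "no"), n, replace = TRUE)
    x2 <- sample(c("a", "b", "c"), n, replace = TRUE)
    z <- rnorm(n, mean = 3, sd = 2)
    eta <- -0.5 + beta * (x1 == "yes")
    data.frame(x1 = x1, x2 = x2, z = z,
               child_marriage = rbinom(n, 1, plogis(eta)),
               stringsAsFactors = FALSE)
  })
}

toy_fm <- function(n = 400, seed = 1, beta = 1.5, k = 4L, split_seed = 2) {
  tab <- toy_table(n, seed, beta)
  fm <- one_hot_encode(tab)
  split <- make_split(n, k = k, seed = split_seed, outcome = fm$outcome)
  list(fm = normalize_continuous(fm, split), split = split)
}

# fit_result stub around a fixed coefficient vector (for knee/engine units)
stub_linear_fit <- function(coefficients, model_kind = "ridge",
                            intercept = 0) {
  structure(list(model_kind = model_kind, penalty = 1, intercept = intercept,
                 coefficients = coefficients,
                 features = names(coefficients),
                 predict = function(m) {
                   as.vector(stats::plogis(
                     intercept + m[, names(coefficients), drop = FALSE] %*%
                       coefficients))
                 },
                 training_meta = list()),
            class = "fit_result")
}

# --- metric oracles ----------------------------------------------------------

auc_pair_oracle <- function(probs, labels) {
  pos <- probs[labels == 1]; neg <- probs[labels == 0]
  wins <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  sum(wins) / (length(pos) * length(neg))
}

confusion_oracle <- function(probs, labels, threshold = 0.5) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(probs)) {
    pred <- probs[i] >= threshold
    if (pred && labels[i] == 1) tp <- tp + 1L
    if (pred && labels[i] == 0) fp <- fp + 1L
    if (!pred && labels[i] == 0) tn <- tn + 1L
    if (!pred && labels[i] == 1) fn <- fn + 1L
  }
  c(tpr = tp / (tp + fn), tnr = tn / (tn + fp),
    ber = 1 - 0.5 * (tp / (tp + fn) + tn / (tn + fp)))
}

# --- knee oracles ------------------------------------------------------------

# independent curvature: same definition, written from scratch
curvature_oracle <- function(curve, index) {
  m <- length(curve)
  lo <- min(curve); hi <- max(curve)
  y <- if (hi > lo) (curve - lo) / (hi - lo) else rep(0, m)
  x <- seq(0, 1, length.out = m)
  h <- x[2] - x[1]
  d1 <- (y[index + 1] - y[index - 1]) / (2 * h)
  d2 <- (y[index + 1] - 2 * y[index] + y[index - 1]) / (h * h)
  abs(d2) / (1 + d1 * d1)^(3 / 2)
}

moving_average_oracle <- function(y, window) {
  if (window <= 1) return(y)
  half <- (window - 1) %/% 2
  out <- numeric(length(y))
  for (i in seq_along(y)) {
    k <- min(half, i - 1, length(y) - i)
    out[i] <- mean(y[(i - k):(i + k)])
  }
  out
}

knee_brute_oracle <- function(curve, window = 3L) {
  s <- moving_average_oracle(curve, window)
  best <- NA_integer_; best_k <- -Inf
  for (i in 2:(length(s) - 1)) {
    k <- curvature_oracle(s, i)
    if (k > best_k + 1e-15) { best_k <- k; best <- i }
  }
  if (best_k < 1e-10) NA_integer_ else best
}

# L-shaped curve with the bend planted at index b: steep linear descent,
# then a near-flat slow decay
corner_curve <- function(seed) {
  withr::with_seed(seed, {
    m <- sample(30:80, 1)
    b <- sample(round(0.2 * m):round(0.6 * m), 1)
    shoulder <- runif(1, 0.05, 0.25)
    s2 <- runif(1, 0.0005, 0.002)
    list(curve = c(seq(1, shoulder, length.out = b),
                   shoulder - s2 * seq_len(m - b)),
         b = b)
  })
}

random_sorted_curve <- function(seed, m = NULL) {
  withr::with_seed(seed, {
    if (is.null(m)) m <- sample(10:60, 1)
    sort(rnorm(m, sd = runif(1, 0.1, 2)), decreasing = TRUE)
  })
}
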