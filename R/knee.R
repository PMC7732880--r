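# Knee-point selection: "meaningful features" are those above the point of
# maximum curvature of the sorted coefficient curve. Both axes are min-max
# rescaled to [0, 1] before curvature is taken (curvature is not scale
# invariant otherwise), and the curve is smoothed with a centered moving
# average before differencing, because finite-difference curvature on raw
# coefficient steps is noise-dominated.

#' Sorted coefficient curve of a linear fit
#'
#' Raw signed coefficients in descending order; ties broken by feature name
#' for determinism. Set `absolute = TRUE` to sort `|coefficient|` instead
#' (useful when meaningful effects carry both signs).
#'
#' @param fit a linear `fit_result` (traditional, lasso or ridge).
#' @param absolute sort absolute values instead of signed values.
#' @return list with `features` (names) and `curve` (values), both in
#'   descending order.
#' @export
sort_coefficient_curve <- function(fit, absolute = FALSE) {
  stopifnot(inherits(fit, "fit_result"))
  if (is.null(fit$coefficients))
    stop_ts("'%s' fits carry no coefficient curve", fit$model_kind)
  beta <- fit$coefficients
  beta <- ifelse(is.na(beta), 0, beta)
  if (!length(beta)) stop_ts("fit has no coefficients")
  vals <- if (absolute) abs(beta) else beta
  o <- order_desc_by_value_then_name(unname(vals), names(beta))
  list(features = names(beta)[o], curve = unname(vals[o]))
}

# Centered moving average with the window truncated symmetrically at the
# ends (window 1 = smoothing off).
smooth_curve <- function(y, window = 5L) {
  if (window <= 1L) return(y)
  h <- (window - 1L) %/% 2L
  m <- length(y)
  vapply(seq_len(m), function(i) {
    k <- min(h, i - 1L, m - i)
    mean(y[(i - k):(i + k)])
  }, 0)
}

rescale01 <- function(y) {
  r <- range(y)
  if (r[2] == r[1]) return(rep(0, length(y)))
  (y - r[1]) / (r[2] - r[1])
}

#' Discrete curvature of a sorted curve at an interior index
#'
#' Central finite differences of the closed-form curvature
#' `|y''| / (1 + y'^2)^(3/2)`, evaluated on the curve after min-max
#' rescaling of both the index axis and the value axis to `[0, 1]`.
#'
#' @param curve numeric vector (the sorted coefficient values).
#' @param index interior position, `2 <= index <= length(curve) - 1`.
#' @return curvature value `kappa >= 0`.
#' @export
discrete_curvature <- function(curve, index) {
  m <- length(curve)
  if (m < 3L) stop_ts("curve must have at least 3 points")
  if (index < 2L || index > m - 1L)
    stop_ts("index %d is not interior to the curve", index)
  y <- rescale01(curve)
  h <- 1 / (m - 1)
  yp <- (y[index + 1] - y[index - 1]) / (2 * h)
  ypp <- (y[index + 1] - 2 * y[index] + y[index - 1]) / h^2
  abs(ypp) / (1 + yp^2)^1.5
}

#' Find the knee (maximum-curvature point) of a sorted curve
#'
#' Smooths the curve, evaluates the discrete curvature at every interior
#' index, and returns the argmax; ties go to the smallest index (the
#' earliest levelling-off point). A curve with no curvature anywhere (a
#' straight or constant line) has no knee and is signalled with `flat =
#' TRUE`.
#'
#' @param curve numeric vector, length >= 4.
#' @param smooth_window centered moving-average window (default 3; 1 = off).
#' @return list with `knee_index` (position of the knee point, `NA` when
#'   flat), `flat` flag, and the per-index `curvature` vector (NA at the
#'   endpoints).
#' @export
find_knee <- function(curve, smooth_window = 3L) {
  m <- length(curve)
  if (m < 4L) stop_ts("curve must have at least 4 points, got %d", m)
  s <- smooth_curve(curve, smooth_window)
  kappa <- rep(NA_real_, m)
  for (i in 2:(m - 1)) kappa[i] <- discrete_curvature(s, i)
  interior <- kappa[2:(m - 1)]
  if (max(interior) < 1e-10) {
    return(list(knee_index = NA_integer_, flat = TRUE, curvature = kappa))
  }
  knee <- which.max(interior) + 1L  # which.max takes the earliest maximum
  list(knee_index = knee, flat = FALSE, curvature = kappa)
}

#' Select the meaningful features above the knee
#'
#' Composes [sort_coefficient_curve()], [find_knee()] and the prefix rule:
#' the selected features are exactly those strictly before the knee point in
#' the descending coefficient order. When the curve is flat (no knee) all
#' features are selected and a warning is issued.
#'
#' @param fit a linear `fit_result`.
#' @param smooth_window smoothing window passed to [find_knee()].
#' @param absolute sort by absolute coefficient value.
#' @return an object of class `knee_result`: `sorted_features`, `curve`,
#'   `knee_index`, `selected`, `flat`, `curvature`, `smoothing_meta`.
#' @export
select_above_knee <- function(fit, smooth_window = 3L, absolute = FALSE) {
  sc <- sort_coefficient_curve(fit, absolute = absolute)
  if (length(sc$curve) < 4L) {
    warning("coefficient curve too short for knee detection; selecting all",
            call. = FALSE)
    kn <- list(knee_index = NA_integer_, flat = TRUE,
               curvature = rep(NA_real_, length(sc$curve)))
  } else {
    kn <- find_knee(sc$curve, smooth_window = smooth_window)
  }
  selected <- if (kn$flat) {
    warning("flat coefficient curve: no knee, selecting all features",
            call. = FALSE)
    sc$features
  } else {
    sc$features[seq_len(kn$knee_index - 1L)]
  }
  structure(list(sorted_features = sc$features, curve = sc$curve,
                 knee_index = kn$knee_index, selected = selected,
                 flat = kn$flat, curvature = kn$curvature,
                 smoothing_meta = list(smooth_window = smooth_window,
                                       absolute = absolute)),
            class = "knee_result")
}

#' @export
print.knee_result <- function(x, ...) {
  cat(sprintf("knee_result: %d features, knee at %s, %d selected%s\n",
              length(x$sorted_features),
              if (x$flat) "none (flat)" else x$knee_index,
              length(x$selected), if (x$flat) " (all)" else ""))
  invisible(x)
}

#' Export a knee result as a rank table
#' @param knee a `knee_result`.
#' @return data.frame of (rank, feature, coefficient, curvature, selected).
#' @export
knee_table <- function(knee) {
  data.frame(rank = seq_along(knee$sorted_features),
             feature = knee$sorted_features,
             coefficient = knee$curve,
             curvature = knee$curvature,
             selected = seq_along(knee$sorted_features) %in%
               seq_len(length(knee$selected)),
             stringsAsFactors = FALSE)
}
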