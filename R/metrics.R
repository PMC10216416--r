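# Discrimination and calibration metrics.

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a positive outranks a negative, ties counted 1/2.
#'
#' @param labels binary 0/1 vector, both classes present.
#' @param probs predicted probabilities (any monotone score works).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(labels, probs) {
  y <- as.integer(labels)
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  assert_that(n_pos > 0 && n_neg > 0, "AUC undefined: both classes must be present")
  r <- rank(probs, ties.method = "average")
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Brier score (mean squared error of probabilities)
#'
#' @inheritParams auc
#' @return mean of `(y - p)^2`.
#' @export
brier <- function(labels, probs) {
  assert_that(all(probs >= 0 & probs <= 1), "probabilities must lie in [0, 1]")
  mean((as.numeric(labels) - probs)^2)
}

#' Scaled Brier score (percent error reduction over a naive model)
#'
#' `100 * (1 - BS / BS_ref)`, where `BS_ref` is the Brier score of the naive
#' model that always predicts the training-sample outcome frequency. Under
#' cross-validation each prediction carries the prevalence of its own training
#' fold, so `reference` may be a per-row vector.
#'
#' @inheritParams auc
#' @param reference naive prediction(s): scalar prevalence or per-row vector.
#' @return scaled Brier score in percent (<= 100).
#' @export
scaled_brier <- function(labels, probs, reference) {
  y <- as.numeric(labels)
  bs_ref <- mean((y - rep(as.numeric(reference), length.out = length(y)))^2)
  assert_that(is.finite(bs_ref) && bs_ref > 0,
              "degenerate naive reference (BS_ref must be > 0)")
  100 * (1 - brier(labels, probs) / bs_ref)
}

#' Operating point maximising the Youden index
#'
#' Exhaustive scan over the midpoints of sorted unique probabilities
#' (classify positive when `p >= cutoff`). Ties are broken toward the smallest
#' cutoff, which favours sensitivity.
#'
#' @inheritParams auc
#' @return list with `cutoff`, `sensitivity`, `specificity`, `youden`.
#' @export
youden_cutoff <- function(labels, probs) {
  y <- as.integer(labels)
  assert_that(any(y == 1) && any(y == 0), "both classes must be present")
  u <- sort(unique(probs))
  # midpoints between consecutive values, plus the all-positive and
  # all-negative operating points (so the maximum is never below 0)
  cand <- if (length(u) > 1) {
    c(u[1], (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  } else u
  best <- list(youden = -Inf)
  for (ct in cand) {
    pred <- probs >= ct
    sens <- mean(pred[y == 1]); spec <- mean(!pred[y == 0])
    j <- sens + spec - 1
    if (j > best$youden + 1e-12) {
      best <- list(cutoff = ct, sensitivity = sens, specificity = spec, youden = j)
    }
  }
  best
}

#' Lowess-smoothed calibration curve
#'
#' Locally weighted regression of observed outcomes on predicted
#' probabilities, evaluated on a regular grid and clipped to `[0, 1]`.
#' Proximity to the diagonal indicates good calibration.
#'
#' @inheritParams auc
#' @param smoothing_fraction lowess span (default 0.6).
#' @param grid_size number of evaluation points (default 50).
#' @return data.frame with `predicted` and `observed` columns (a single row
#'   for constant predictions).
#' @export
lowess_calibration <- function(labels, probs, smoothing_fraction = 0.6,
                               grid_size = 50) {
  assert_that(length(labels) >= 20, "need at least 20 observations")
  y <- as.numeric(labels)
  if (length(unique(probs)) == 1) {
    return(data.frame(predicted = probs[1], observed = mean(y)))
  }
  # no robustness iterations: they would treat the minority outcomes of a
  # 0/1 response as outliers and flatten the curve
  lo <- stats::lowess(probs, y, f = smoothing_fraction, iter = 0)
  grid <- seq(min(probs), max(probs), length.out = grid_size)
  obs <- stats::approx(lo$x, lo$y, xout = grid, rule = 2, ties = mean)$y
  data.frame(predicted = grid, observed = pmin(pmax(obs, 0), 1))
}

# metric on a prediction vector or (nodes x repeats) matrix; matrices are
# scored per repeat and averaged, keeping each pooled vector a proper
# one-prediction-per-node set.
metric_value <- function(labels, probs, metric, reference = NULL) {
  f <- switch(metric,
    auc = function(p, r) auc(labels, p),
    brier = function(p, r) brier(labels, p),
    sbs = function(p, r) scaled_brier(labels, p, r))
  if (is.matrix(probs)) {
    vals <- vapply(seq_len(ncol(probs)), function(j) {
      f(probs[, j], if (is.matrix(reference)) reference[, j] else reference)
    }, 0)
    mean(vals)
  } else {
    f(probs, reference)
  }
}

#' Paired bootstrap z-test for a metric difference
#'
#' Draws node rows with replacement (the same rows for both prediction sets),
#' recomputes the metric difference on every draw, and tests
#' `z = mean(diff) / sd(diff)` against a two-sided normal reference.
#'
#' @inheritParams auc
#' @param probs_a,probs_b prediction vectors (or nodes-by-repeats matrices)
#'   for the two models on the same rows.
#' @param metric `"auc"` or `"brier"`.
#' @param B bootstrap draws (>= 500).
#' @param seed integer seed.
#' @return list with `difference` (a - b on the full data), `z`, `p`, `B`; a
#'   logical `degenerate` flag marks the zero-variance corner case.
#' @export
paired_bootstrap_z_test <- function(labels, probs_a, probs_b,
                                    metric = c("brier", "auc"), B = 1000,
                                    seed = 1L) {
  metric <- match.arg(metric)
  assert_that(B >= 500, "B must be >= 500")
  a <- if (is.matrix(probs_a)) probs_a else matrix(probs_a)
  b <- if (is.matrix(probs_b)) probs_b else matrix(probs_b)
  n <- length(labels)
  assert_that(nrow(a) == n && nrow(b) == n, "prediction sets must cover the same rows")
  y <- as.integer(labels)
  diffs <- with_seed(seed, {
    vapply(seq_len(B), function(i) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (metric == "brier" || (any(y[idx] == 1) && any(y[idx] == 0))) break
      }
      metric_value(y[idx], a[idx, , drop = FALSE], metric) -
        metric_value(y[idx], b[idx, , drop = FALSE], metric)
    }, 0)
  })
  s <- stats::sd(diffs); m <- mean(diffs)
  degenerate <- FALSE
  if (s == 0) {
    if (m == 0) { z <- 0; p <- 1 } else {
      z <- sign(m) * Inf; p <- .Machine$double.xmin; degenerate <- TRUE
    }
  } else {
    z <- m / s
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(difference = metric_value(y, a, metric) - metric_value(y, b, metric),
       z = z, p = p, B = B, degenerate = degenerate)
}
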