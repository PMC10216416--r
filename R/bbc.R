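# Bootstrap bias correction (BBC) of pooled out-of-fold predictions.
#
# Selecting the best of many hyperparameter configurations on the same pooled
# predictions that are then reported is optimistically biased. The correction
# repeats the selection inside a bootstrap: on each draw of node rows (with
# replacement) the winning configuration is picked on the in-bag rows and
# evaluated on the out-of-bag rows; the corrected estimate is the mean of the
# out-of-bag values and the percentile interval of the draws is the CI.

#' Bootstrap-bias-corrected selection and estimation
#'
#' @param pm a `prediction_matrix` from [cross_validate()], or a plain
#'   nodes-by-configs matrix of pooled predictions (then `labels` must be
#'   given).
#' @param labels binary labels (taken from `pm` when omitted).
#' @param naive_ref naive per-row reference predictions for the scaled Brier
#'   score (taken from `pm` when omitted).
#' @param selection_metric metric the winner is picked on: `"brier"`
#'   (minimised; the primary metric) or `"auc"` (maximised).
#' @param B bootstrap draws (>= 100).
#' @param seed integer seed.
#' @param conf_level CI level (default 0.95).
#' @return list with `estimates` (corrected AUC, Brier, SBS, sensitivity,
#'   specificity, cutoff), `ci` (percentile intervals), `selection_freq`
#'   per configuration, and the per-draw values.
#' @export
bbc_select <- function(pm, labels = NULL, naive_ref = NULL,
                       selection_metric = c("brier", "auc"), B = 1000,
                       seed = 1L, conf_level = 0.95) {
  selection_metric <- match.arg(selection_metric)
  assert_that(B >= 100, "B must be >= 100")
  if (inherits(pm, "prediction_matrix")) {
    preds <- pm$preds
    labels <- labels %||% pm$labels
    naive_ref <- naive_ref %||% pm$naive
  } else {
    preds <- if (length(dim(pm)) == 3) pm else array(pm, c(dim(pm), 1))
  }
  y <- as.integer(labels)
  n <- length(y)
  n_cfg <- dim(preds)[2]
  n_rep <- dim(preds)[3]
  if (is.null(naive_ref)) naive_ref <- matrix(mean(y), n, n_rep)
  if (!is.matrix(naive_ref)) naive_ref <- matrix(naive_ref, n, n_rep)

  # per-node squared errors averaged over repeats: Brier of a row subset for
  # every config is then a single colMeans
  sqerr <- matrix(0, n, n_cfg)
  for (r in seq_len(n_rep)) sqerr <- sqerr + (preds[, , r] - y)^2
  sqerr <- sqerr / n_rep

  draw_names <- c("auc", "brier", "sbs", "sensitivity", "specificity", "cutoff")
  draws <- matrix(NA_real_, B, length(draw_names),
                  dimnames = list(NULL, draw_names))
  sel <- integer(B)
  with_seed(derive_seed(seed, "bbc"), {
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        oob <- which(tabulate(idx, n) == 0L)
        if (length(oob) > 0 && any(y[oob] == 1) && any(y[oob] == 0) &&
            any(y[idx] == 1) && any(y[idx] == 0)) break
      }
      best <- if (selection_metric == "brier") {
        which.min(colMeans(sqerr[idx, , drop = FALSE]))
      } else {
        which.max(vapply(seq_len(n_cfg), function(ci) {
          metric_value(y[idx], preds[idx, ci, , drop = TRUE], "auc")
        }, 0))
      }
      sel[b] <- best
      po <- matrix(preds[oob, best, , drop = FALSE], length(oob), n_rep)
      yo <- y[oob]
      ops <- vapply(seq_len(n_rep), function(r) {
        op <- youden_cutoff(yo, po[, r])
        c(op$sensitivity, op$specificity, op$cutoff)
      }, numeric(3))
      draws[b, ] <- c(metric_value(yo, po, "auc"),
                      metric_value(yo, po, "brier"),
                      metric_value(yo, po, "sbs",
                                   naive_ref[oob, , drop = FALSE]),
                      rowMeans(ops))
    }
  })
  alpha <- (1 - conf_level) / 2
  list(estimates = colMeans(draws),
       ci = apply(draws, 2, stats::quantile, probs = c(alpha, 1 - alpha)),
       selection_freq = tabulate(sel, n_cfg) / B,
       draws = draws,
       selection_metric = selection_metric, B = B)
}
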