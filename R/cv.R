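# Patient-level repeated cross-validation. Splits are applied on the patient
# level: all of a patient's nodes are in the training set or none are.

#' Build a patient-level fold plan
#'
#' Per repeat, a random equal-as-possible partition of patients into folds.
#' When a patient-level stratum (e.g. "carries at least one positive node")
#' is supplied, patients are dealt round-robin within strata, which spreads
#' positive patients across folds and makes single-class training folds rare.
#'
#' @param patient_ids unique patient identifiers.
#' @param folds folds per repeat (default 20).
#' @param repeats number of repeats (default 10).
#' @param seed integer seed.
#' @param strata optional vector (same length) used to stratify the partition.
#' @return a `fold_plan`: `assignment` is a `length(patient_ids) x repeats`
#'   matrix of fold indices.
#' @export
make_patient_folds <- function(patient_ids, folds = 20, repeats = 10, seed = 1L,
                               strata = NULL) {
  patient_ids <- as.character(patient_ids)
  assert_that(!anyDuplicated(patient_ids), "patient_ids must be unique")
  n <- length(patient_ids)
  assert_that(folds >= 2 && folds <= n,
              sprintf("folds (%d) must be between 2 and the patient count (%d)", folds, n))
  if (is.null(strata)) strata <- rep(1L, n)
  assignment <- vapply(seq_len(repeats), function(r) {
    assign_one_repeat(n, folds, strata, derive_seed(seed, "repeat", r))
  }, integer(n))
  structure(list(patient_ids = patient_ids, folds = as.integer(folds),
                 repeats = as.integer(repeats), assignment = assignment,
                 seed = as.integer(seed), strata = strata),
            class = "fold_plan")
}

assign_one_repeat <- function(n, folds, strata, seed) {
  with_seed(seed, {
    ord <- unlist(lapply(split(seq_len(n), strata), sample), use.names = FALSE)
    fold_of <- integer(n)
    fold_of[ord] <- rep(sample(folds), length.out = n)
    fold_of
  })
}

#' Cross-validate every hyperparameter configuration
#'
#' For each (repeat, fold, configuration): standardisation, PCA and the model
#' are fitted on the training patients only and applied to the held-out
#' patients. Predictions are pooled per repeat into one full-cohort
#' out-of-fold vector per configuration. Every prediction carries the
#' prevalence of its own training fold as the naive reference for the scaled
#' Brier score. A repeat whose partition would give some fold a single-class
#' training set is redrawn (with a warning).
#'
#' @param feature_table data.frame with `node_id`, `patient_id`, `label` and
#'   numeric feature columns.
#' @param configs list of configurations from [sample_hyperparameters()].
#' @param plan a [make_patient_folds()] plan covering the table's patients.
#' @param seed integer seed for the per-fold model fits.
#' @param variance_threshold PCA retained-variance fraction.
#' @return a `prediction_matrix`: `preds` is `nodes x configs x repeats`,
#'   `naive` is `nodes x repeats`, plus labels and ids.
#' @export
cross_validate <- function(feature_table, configs, plan, seed = 1L,
                           variance_threshold = 0.95) {
  stopifnot(inherits(plan, "fold_plan"))
  ids <- feature_table$node_id
  pid <- as.character(feature_table$patient_id)
  y <- as.integer(feature_table$label)
  assert_that(all(pid %in% plan$patient_ids), "plan does not cover all patients")
  feat_cols <- setdiff(names(feature_table), c("node_id", "patient_id", "label"))
  X <- as.matrix(feature_table[feat_cols])
  storage.mode(X) <- "double"
  n <- nrow(X)
  n_cfg <- length(configs)
  preds <- array(NA_real_, c(n, n_cfg, plan$repeats),
                 dimnames = list(NULL, vapply(configs, `[[`, "", "id"), NULL))
  naive <- matrix(NA_real_, n, plan$repeats)
  pid_index <- match(pid, plan$patient_ids)

  for (r in seq_len(plan$repeats)) {
    fold_of_patient <- plan$assignment[, r]
    attempt <- 0L
    repeat {
      node_fold <- fold_of_patient[pid_index]
      ok <- all(vapply(seq_len(plan$folds), function(f) {
        tr <- y[node_fold != f]
        length(unique(tr)) == 2
      }, TRUE))
      if (ok) break
      attempt <- attempt + 1L
      assert_that(attempt <= 50, "could not draw a fold plan with two-class training sets")
      warning(sprintf("repeat %d: redrawing folds (single-class training set)", r))
      fold_of_patient <- assign_one_repeat(length(plan$patient_ids), plan$folds,
                                           plan$strata,
                                           derive_seed(plan$seed, "redraw", r, attempt))
    }
    for (f in seq_len(plan$folds)) {
      test <- which(node_fold == f)
      if (length(test) == 0) next
      train <- which(node_fold != f)
      naive[test, r] <- mean(y[train])
      # cache the train-only transforms per (depth block, pca flag)
      cache <- new.env(parent = emptyenv())
      for (ci in seq_len(n_cfg)) {
        hp <- configs[[ci]]
        cols <- select_model_columns(feat_cols, hp)
        key <- paste(isTRUE(hp$use_pca), paste(range(match(cols, feat_cols)), collapse = ":"),
                     length(cols))
        tr_obj <- cache[[key]] %||% {
          Xtr <- X[train, cols, drop = FALSE]
          std <- fit_standardizer(Xtr)
          Ztr <- apply_standardizer(std, Xtr)
          pca <- if (isTRUE(hp$use_pca)) fit_pca(Ztr, variance_threshold) else NULL
          if (!is.null(pca)) Ztr <- predict(pca, Ztr)
          Zte <- apply_standardizer(std, X[test, cols, drop = FALSE])
          if (!is.null(pca)) Zte <- predict(pca, Zte)
          cache[[key]] <- list(Ztr = Ztr, Zte = Zte)
          cache[[key]]
        }
        core <- fit_core_model(tr_obj$Ztr, y[train], hp,
                               derive_seed(seed, "fit", r, f, ci))
        preds[test, ci, r] <- predict_core_model(core, tr_obj$Zte)
      }
    }
  }
  structure(list(preds = preds, naive = naive, labels = y, node_id = ids,
                 patient_id = pid, config_ids = dimnames(preds)[[2]],
                 configs = configs),
            class = "prediction_matrix")
}

#' @export
print.prediction_matrix <- function(x, ...) {
  d <- dim(x$preds)
  cat(sprintf("<prediction_matrix> %d nodes x %d configs x %d repeats\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Pooled (repeat-averaged) metric for each configuration
#'
#' @param pm a [cross_validate()] result.
#' @param metric `"auc"`, `"brier"` or `"sbs"`.
#' @return named numeric vector, one value per configuration.
#' @export
pooled_config_metrics <- function(pm, metric = "brier") {
  vapply(seq_along(pm$config_ids), function(ci) {
    metric_value(pm$labels, pm$preds[, ci, , drop = TRUE], metric, pm$naive)
  }, 0) |> stats::setNames(pm$config_ids)
}
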