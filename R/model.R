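# Feature-set assembly and classifier fitting under a strict
# fit-on-training-rows-only contract: standardisation statistics, PCA loadings
# and model coefficients are all estimated on training rows and merely applied
# to unseen rows.

#' Assemble one of the three compared feature sets
#'
#' `handcrafted` = first-order + shape + co-occurrence; `deep` = pooled CNN
#' features (all stages; the `depth_k` hyperparameter selects one stage at fit
#' time); `hybrid` = first-order + shape + deep, deliberately excluding the
#' higher-order hand-crafted block.
#'
#' @param handcrafted_table,deep_table data.frames with `node_id`,
#'   `patient_id`, `label` and feature columns, aligned on `node_id`.
#' @param kind `"handcrafted"`, `"deep"` or `"hybrid"`.
#' @return data.frame with id columns, `label`, and the selected features;
#'   the kind is recorded in attribute `feature_set`.
#' @export
assemble_feature_set <- function(handcrafted_table, deep_table,
                                 kind = c("handcrafted", "deep", "hybrid")) {
  kind <- match.arg(kind)
  id_cols <- c("node_id", "patient_id", "label")
  assert_that(all(id_cols %in% names(handcrafted_table)) &&
                all(id_cols %in% names(deep_table)),
              "tables need node_id, patient_id, label columns")
  if (!identical(handcrafted_table$node_id, deep_table$node_id)) {
    stop("alignment error: node_id columns of the two tables differ", call. = FALSE)
  }
  feats <- switch(kind,
    handcrafted = feature_subset(handcrafted_table, c("firstorder", "shape", "glcm")),
    deep = feature_subset(deep_table, "deep"),
    hybrid = cbind(feature_subset(handcrafted_table, c("firstorder", "shape")),
                   feature_subset(deep_table, "deep")))
  out <- cbind(handcrafted_table[id_cols], feats)
  attr(out, "feature_set") <- kind
  out
}

fit_standardizer <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

apply_standardizer <- function(std, X) {
  sweep(sweep(X, 2, std$center), 2, std$scale, `/`)
}

#' Fit a PCA transform on training rows
#'
#' Expects standardised input. Keeps the smallest number of leading
#' components whose cumulative explained variance reaches
#' `variance_threshold`.
#'
#' @param train_features standardised numeric matrix (>= 2 rows).
#' @param variance_threshold fraction of variance to retain (default 0.95).
#' @return a `pca_transform` with `rotation` (columns = retained components)
#'   and `L`.
#' @export
fit_pca <- function(train_features, variance_threshold = 0.95) {
  X <- as.matrix(train_features)
  assert_that(nrow(X) >= 2, "need at least 2 rows")
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  assert_that(sum(ev) > 0, "degenerate input: all variances are zero")
  cum <- cumsum(ev) / sum(ev)
  L <- which(cum >= variance_threshold - 1e-12)[1]
  structure(list(rotation = pc$rotation[, seq_len(L), drop = FALSE], L = L,
                 explained = cum[L], variance_threshold = variance_threshold),
            class = "pca_transform")
}

#' @export
predict.pca_transform <- function(object, newdata, ...) {
  as.matrix(newdata) %*% object$rotation
}

#' Default random-search space
#'
#' Elastic net: penalty strength log-uniform on `[1e-3, 1e2]`, L1 share
#' uniform on `[0, 1]`. Random forest: tree count uniform on `[100, 1000]`,
#' minimum leaf size in `{1, 2, 5, 10}`, maximum depth in
#' `{unlimited, 3, 5, 10}`, features-per-split fraction in
#' `{sqrt, 1/3, 2/3}`. Shared: CNN depth `k` in `1..4`, PCA on/off.
#'
#' @param model `"elastic_logit"` or `"random_forest"`.
#' @return list describing the per-field distributions.
#' @export
default_hp_space <- function(model = c("elastic_logit", "random_forest")) {
  model <- match.arg(model)
  shared <- list(depth_k = 1:4, use_pca = c(TRUE, FALSE))
  if (model == "elastic_logit") {
    c(list(log10_penalty = c(-3, 2), mixing = c(0, 1)), shared)
  } else {
    c(list(trees = c(100L, 1000L), min_leaf = c(1L, 2L, 5L, 10L),
           max_depth = c(0L, 3L, 5L, 10L), mtry_frac = c(NA, 1 / 3, 2 / 3)),
      shared)
  }
}

#' Sample hyperparameter configurations
#'
#' Independent draws from the declared per-field distributions, reproducible
#' from `seed`.
#'
#' @param model `"elastic_logit"` or `"random_forest"`.
#' @param n_configs number of configurations (>= 1).
#' @param seed integer seed.
#' @param space a space as returned by [default_hp_space()].
#' @return list of hyperparameter configurations.
#' @export
sample_hyperparameters <- function(model = c("elastic_logit", "random_forest"),
                                   n_configs, seed,
                                   space = default_hp_space(model)) {
  model <- match.arg(model)
  assert_that(n_configs >= 1, "n_configs must be >= 1")
  assert_that(length(space) > 0, "empty hyperparameter space")
  with_seed(seed, lapply(seq_len(n_configs), function(i) {
    hp <- list(model = model, id = sprintf("%s_%03d", model, i),
               depth_k = sample(space$depth_k, 1),
               use_pca = sample(space$use_pca, 1))
    if (model == "elastic_logit") {
      hp$penalty <- 10^stats::runif(1, space$log10_penalty[1], space$log10_penalty[2])
      hp$mixing <- stats::runif(1, space$mixing[1], space$mixing[2])
    } else {
      hp$trees <- sample(space$trees[1]:space$trees[2], 1)
      hp$min_leaf <- sample(space$min_leaf, 1)
      hp$max_depth <- sample(space$max_depth, 1)
      hp$mtry_frac <- sample(space$mtry_frac, 1)
    }
    hp
  }))
}

# columns the model actually uses: all non-deep features, plus the deep block
# of the configured depth
select_model_columns <- function(feature_names, hp) {
  deep <- startsWith(feature_names, "deep.")
  if (!any(deep)) return(feature_names)
  keep_deep <- startsWith(feature_names, sprintf("deep.s%d.", hp$depth_k))
  out <- feature_names[!deep | keep_deep]
  assert_that(length(out) > 0, "no features left after depth selection")
  out
}

fit_core_model <- function(Z, y, hp, seed) {
  if (hp$model == "elastic_logit") {
    if (ncol(Z) < 2) Z <- cbind(Z, `.pad` = 0)
    fit <- glmnet::glmnet(Z, factor(y, levels = c(0, 1)), family = "binomial",
                          alpha = hp$mixing, standardize = FALSE,
                          thresh = 1e-6, maxit = 1e4)
    list(kind = "elastic_logit", fit = fit, s = hp$penalty)
  } else {
    mtry <- if (is.na(hp$mtry_frac)) max(1L, floor(sqrt(ncol(Z)))) else
      max(1L, floor(hp$mtry_frac * ncol(Z)))
    fit <- ranger::ranger(x = Z, y = factor(y, levels = c(0, 1)),
                          probability = TRUE, num.trees = hp$trees,
                          min.node.size = hp$min_leaf, max.depth = hp$max_depth,
                          mtry = mtry, seed = seed, num.threads = 1L,
                          verbose = FALSE)
    list(kind = "random_forest", fit = fit)
  }
}

predict_core_model <- function(core, Z) {
  p <- if (core$kind == "elastic_logit") {
    if (ncol(Z) < 2) Z <- cbind(Z, `.pad` = 0)
    as.numeric(stats::predict(core$fit, newx = Z, s = core$s, type = "response"))
  } else {
    stats::predict(core$fit, data = Z, num.threads = 1L)$predictions[, "1"]
  }
  pmin(pmax(as.numeric(p), 0), 1)
}

#' Fit a classifier under the train-only contract
#'
#' Standardises on training rows, optionally applies PCA (95% variance rule)
#' to the standardised block, selects the deep block matching `depth_k`, and
#' fits the configured model. No class weighting is applied. Deterministic
#' given `(data, hp, seed)`.
#'
#' @param X_train numeric matrix or data.frame of features (named columns).
#' @param y_train binary labels (0/1), both classes present.
#' @param hp one configuration from [sample_hyperparameters()].
#' @param seed integer seed (used by the random forest).
#' @param variance_threshold PCA retained-variance fraction.
#' @return a `fitted_model`; use [predict_probability()] on new rows.
#' @export
fit_model <- function(X_train, y_train, hp, seed = 1L, variance_threshold = 0.95) {
  X <- as.matrix(X_train)
  y <- as.integer(y_train)
  assert_that(length(unique(y)) == 2, "degenerate labels: training set has a single class")
  cols <- select_model_columns(colnames(X), hp)
  X <- X[, cols, drop = FALSE]
  std <- fit_standardizer(X)
  Z <- apply_standardizer(std, X)
  pca <- if (isTRUE(hp$use_pca)) fit_pca(Z, variance_threshold) else NULL
  if (!is.null(pca)) Z <- predict(pca, Z)
  core <- fit_core_model(Z, y, hp, seed)
  structure(list(columns = cols, std = std, pca = pca, core = core, hp = hp),
            class = "fitted_model")
}

#' Predicted probability of PET positivity
#'
#' @param model a [fit_model()] result.
#' @param X new rows (same feature naming as training).
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict_probability <- function(model, X) {
  stopifnot(inherits(model, "fitted_model"))
  X <- as.matrix(X)[, model$columns, drop = FALSE]
  Z <- apply_standardizer(model$std, X)
  if (!is.null(model$pca)) Z <- predict(model$pca, Z)
  predict_core_model(model$core, Z)
}
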