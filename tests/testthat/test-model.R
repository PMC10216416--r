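toy_tables <- function(n = 10) {
  meta <- data.frame(node_id = sprintf("N%02d", 1:n),
                     patient_id = sprintf("P%02d", 1:n),
                     label = rep_len(0:1, n))
  hc <- cbind(meta, data.frame(firstorder.mean = rnorm(n), shape.volume = rnorm(n),
                               glcm.contrast = rnorm(n)))
  dp <- cbind(meta, data.frame(deep.s1.c1 = rnorm(n), deep.s1.c2 = rnorm(n),
                               deep.s2.c1 = rnorm(n)))
  list(hc = hc, dp = dp)
}

test_that("feature sets follow the published composition rules", {
  set.seed(1)
  tb <- toy_tables()
  hybrid <- assemble_feature_set(tb$hc, tb$dp, "hybrid")
  expect_false(any(startsWith(names(hybrid), "glcm.")))
  expect_true(all(c("firstorder.mean", "shape.volume", "deep.s1.c1") %in% names(hybrid)))
  expect_equal(ncol(hybrid) - 3, 2 + 3)  # firstorder + shape + deep

  hc_only <- assemble_feature_set(tb$hc, tb$dp, "handcrafted")
  expect_false(any(startsWith(names(hc_only), "deep.")))
  deep_only <- assemble_feature_set(tb$hc, tb$dp, "deep")
  expect_true(all(startsWith(setdiff(names(deep_only),
                                     c("node_id", "patient_id", "label")), "deep.")))

  tb$dp$node_id[2] <- "XX"
  expect_error(assemble_feature_set(tb$hc, tb$dp, "hybrid"), "alignment")
})

test_that("PCA keeps the smallest component count reaching the variance rule", {
  set.seed(2)
  # exactly rank-2 data
  n <- 200
  basis <- matrix(rnorm(2 * 6), 2, 6)
  X <- scale(matrix(rnorm(n * 2), n) %*% basis)
  expect_equal(fit_pca(X, 0.95)$L, 2)

  # independent equal-variance dimensions: every component carries ~10%
  X10 <- scale(matrix(rnorm(20000 * 10), ncol = 10))
  expect_equal(fit_pca(X10, 0.95)$L, 10)

  Xfr <- scale(matrix(rnorm(50 * 7), ncol = 7))
  expect_equal(fit_pca(Xfr, 1.0)$L, 7)

  expect_error(fit_pca(matrix(0, 10, 3)), "degenerate")
  # transform uses train statistics only
  p <- fit_pca(X, 0.95)
  expect_equal(dim(predict(p, X[1:5, ])), c(5L, 2L))
})

test_that("elastic net behaves at the penalty extremes", {
  set.seed(3)
  n <- 40
  X <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- rbinom(n, 1, 0.3)
  hp_inf <- list(model = "elastic_logit", id = "x", depth_k = 1, use_pca = FALSE,
                 penalty = 1e6, mixing = 0.5)
  m <- fit_model(X, y, hp_inf, seed = 1)
  expect_equal(unique(round(predict_probability(m, X), 6)),
               round(mean(y), 6))

  # linearly separable 6-point set, weak penalty -> perfect training AUC
  Xs <- cbind(x1 = c(-3, -2, -1, 1, 2, 3), x2 = c(0, 0, 0, 0, 0, 0))
  ys <- c(0, 0, 0, 1, 1, 1)
  hp_w <- list(model = "elastic_logit", id = "w", depth_k = 1, use_pca = FALSE,
               penalty = 1e-4, mixing = 0.5)
  mw <- fit_model(Xs, ys, hp_w, seed = 1)
  expect_equal(auc(ys, predict_probability(mw, Xs)), 1.0)

  expect_error(fit_model(X, rep(1, n), hp_w), "degenerate labels")
})

test_that("stronger L1 share never increases total coefficient mass", {
  set.seed(4)
  n <- 80
  X <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("f", 1:6)))
  y <- rbinom(n, 1, plogis(X[, 1] - X[, 2]))
  skip_if(length(unique(y)) < 2)
  mass <- vapply(c(0.1, 0.5, 0.9), function(alpha) {
    fit <- glmnet::glmnet(scale(X), factor(y), family = "binomial",
                          alpha = alpha, standardize = FALSE)
    sum(abs(as.numeric(coef(fit, s = 0.1))[-1]))
  }, 0)
  expect_true(all(diff(mass) <= 1e-8))
})

test_that("random forests are seeded-deterministic and depth-selectable", {
  set.seed(5)
  n <- 60
  X <- cbind(deep.s1.c1 = rnorm(n), deep.s2.c1 = rnorm(n), deep.s2.c2 = rnorm(n),
             firstorder.mean = rnorm(n))
  y <- rbinom(n, 1, plogis(X[, 4]))
  skip_if(length(unique(y)) < 2)
  hp <- list(model = "random_forest", id = "r", depth_k = 2, use_pca = FALSE,
             trees = 100, min_leaf = 2, max_depth = 0, mtry_frac = NA)
  m1 <- fit_model(X, y, hp, seed = 7)
  m2 <- fit_model(X, y, hp, seed = 7)
  expect_identical(predict_probability(m1, X), predict_probability(m2, X))
  # depth_k = 2 drops the stage-1 block but keeps non-deep features
  expect_setequal(m1$columns, c("deep.s2.c1", "deep.s2.c2", "firstorder.mean"))
})

test_that("hyperparameter sampling is reproducible and in bounds", {
  cfgs <- sample_hyperparameters("elastic_logit", 50, seed = 9)
  expect_length(cfgs, 50)
  expect_identical(sample_hyperparameters("elastic_logit", 50, seed = 9), cfgs)
  pen <- vapply(cfgs, `[[`, 0, "penalty")
  mix <- vapply(cfgs, `[[`, 0, "mixing")
  expect_true(all(pen >= 1e-3 & pen <= 1e2))
  expect_true(all(mix >= 0 & mix <= 1))
  expect_true(all(vapply(cfgs, `[[`, 0, "depth_k") %in% 1:4))

  rf <- sample_hyperparameters("random_forest", 30, seed = 10)
  expect_true(all(vapply(rf, `[[`, 0L, "trees") >= 100))
  expect_true(all(vapply(rf, `[[`, 0L, "trees") <= 1000))
  expect_true(all(vapply(rf, `[[`, 0L, "min_leaf") %in% c(1L, 2L, 5L, 10L)))
  expect_equal(anyDuplicated(vapply(rf, `[[`, "", "id")), 0)
})
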