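test_that("AUC equals brute-force pair counting", {
  expect_equal(auc(c(1, 0), c(0.9, 0.1)), 1.0)
  expect_equal(auc(c(1, 0, 1, 0), rep(0.4, 4)), 0.5)
  expect_equal(auc(c(1, 0, 0), c(0.4, 0.8, 0.1)), 0.5)
  expect_error(auc(c(1, 1), c(0.2, 0.3)), "both classes")

  set.seed(1)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    y <- rbinom(n, 1, runif(1, 0.15, 0.85))
    if (length(unique(y)) < 2) next
    p <- round(runif(n), sample(1:3, 1))  # induce ties
    expect_equal(auc(y, p), brute_force_auc(y, p), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(2)
  y <- rbinom(300, 1, 0.3); p <- runif(300)
  expect_equal(auc(y, p),
               as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("Brier and scaled Brier match hand computation", {
  expect_equal(brier(c(1, 0), c(1, 0)), 0)
  expect_equal(brier(c(1, 0), c(0.8, 0.3)), 0.065)  # (0.04 + 0.09) / 2
  # constant prediction at prevalence: BS = pi (1 - pi)
  y <- c(rep(1, 3), rep(0, 7))
  expect_equal(brier(y, rep(0.3, 10)), 0.3 * 0.7)
  expect_error(brier(c(1, 0), c(1.2, 0)), "\\[0, 1\\]")

  expect_equal(scaled_brier(y, rep(0.3, 10), 0.3), 0)
  expect_equal(scaled_brier(y, y, 0.3), 100)
  # BS = 0.08 against BS_ref = 0.16 -> 50%
  y2 <- c(1, 0); p2 <- c(1 - sqrt(0.08), sqrt(0.08))
  expect_equal(scaled_brier(y2, p2, c(1 - sqrt(0.16), sqrt(0.16))), 50)
  expect_error(scaled_brier(c(1, 1), c(1, 1), c(1, 1)), "degenerate")
})

test_that("the Youden cutoff matches an exhaustive threshold scan", {
  sep <- youden_cutoff(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$specificity, 1)

  mixed <- youden_cutoff(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))
  expect_equal(mixed$youden, 0.5)
  expect_equal(mixed$cutoff, 0.4)  # tie broken toward sensitivity

  flat <- youden_cutoff(c(1, 0), c(0.5, 0.5))
  expect_equal(flat$youden, 0)

  set.seed(3)
  for (i in 1:10) {
    y <- rbinom(50, 1, 0.4); p <- round(runif(50), 2)
    if (length(unique(y)) < 2) next
    got <- youden_cutoff(y, p)
    best <- max(vapply(sort(unique(c(p - 1e-9, p + 1e-9))), function(ct) {
      mean(p[y == 1] >= ct) + mean(p[y == 0] < ct) - 1
    }, 0))
    expect_equal(got$youden, best, tolerance = 1e-9)
  }
})

test_that("lowess calibration tracks the diagonal for calibrated predictions", {
  set.seed(4)
  p <- runif(5000)
  y <- rbinom(5000, 1, p)
  curve <- lowess_calibration(y, p)
  expect_lt(max(abs(curve$observed - curve$predicted)), 0.05)
  expect_true(all(curve$observed >= 0 & curve$observed <= 1))

  const <- lowess_calibration(y, rep(0.31, 5000))
  expect_equal(nrow(const), 1)
  expect_equal(const$predicted, 0.31)
  expect_equal(const$observed, mean(y))

  ord <- sample(5000)
  expect_equal(lowess_calibration(y[ord], p[ord]), curve)

  expect_error(lowess_calibration(y[1:10], p[1:10]), "at least 20")
})

test_that("paired bootstrap z-test separates identical, null and oracle pairs", {
  set.seed(5)
  y <- rbinom(200, 1, 0.3)
  p <- runif(200)
  same <- paired_bootstrap_z_test(y, p, p, "brier", B = 500, seed = 1)
  expect_equal(same$difference, 0)
  expect_equal(same$p, 1)

  oracle <- as.numeric(y)
  rand <- runif(200)
  win <- paired_bootstrap_z_test(y, oracle, rand, "brier", B = 500, seed = 2)
  expect_lt(win$p, 0.001)
  expect_lt(win$difference, 0)  # lower Brier is better
  win_auc <- paired_bootstrap_z_test(y, 0.5 + 0.49 * (2 * y - 1), rand, "auc",
                                     B = 500, seed = 3)
  expect_lt(win_auc$p, 0.001)
  expect_gt(win_auc$difference, 0)
})
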