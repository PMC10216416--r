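# Shared fixtures, all built in code. Expensive simulations are computed once
# per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, fn) {
  if (!exists(name, envir = .fixture_cache)) assign(name, fn(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# wrap a bare intensity array (everything in-mask) as a node VOI
array_voi <- function(values, spacing = c(1, 1, 1), mask = NULL) {
  a <- if (is.array(values)) values else array(values, c(length(values), 1, 1))
  if (is.null(mask)) mask <- array(1L, dim(a))
  node_voi(image_volume(a, spacing), mask)
}

# discretised ball of radius r_mm on an isotropic grid
digital_ball <- function(r_mm, spacing = 1, margin = 2) {
  n <- as.integer(2 * ceiling((r_mm + margin) / spacing) + 1)
  ctr <- (n + 1) / 2
  x <- (seq_len(n) - ctr) * spacing
  q <- outer(outer(x^2, x^2, "+"), x^2, "+")
  array(as.integer(q <= r_mm^2), c(n, n, n))
}

# brute-force AUC: count concordant positive-negative pairs, ties = 1/2
brute_force_auc <- function(labels, probs) {
  pos <- probs[labels == 1]
  neg <- probs[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# small feature table with patient structure and label-independent noise
# features; optionally with an informative column
null_feature_table <- function(n_patients = 12, nodes_per_patient = 6,
                               n_features = 8, prevalence = 0.25, seed = 1) {
  withr::with_seed(seed, {
    n <- n_patients * nodes_per_patient
    tbl <- data.frame(
      node_id = sprintf("N%04d", seq_len(n)),
      patient_id = rep(sprintf("P%03d", seq_len(n_patients)),
                       each = nodes_per_patient),
      label = stats::rbinom(n, 1, prevalence))
    # guarantee both classes
    if (sum(tbl$label) < 2) tbl$label[1:2] <- 1L
    if (sum(tbl$label == 0) < 2) tbl$label[1:2] <- 0L
    feats <- matrix(stats::rnorm(n * n_features), n,
                    dimnames = list(NULL, sprintf("firstorder.f%02d", seq_len(n_features))))
    cbind(tbl, as.data.frame(feats))
  })
}

# the standard-signal synthetic experiment used by the headline checks;
# desk-scale sizes (60 patients, 5-fold x 2 repeats, 8 configurations,
# 64 x 64 slices) documented in the methods vignette
standard_experiment <- function() {
  cached_fixture("standard_experiment", function() {
    cfg <- experiment_config(cohort_config(n_patients = 60, seed = 11),
                             n_configs = 8, folds = 5, repeats = 2,
                             bbc_B = 500, xy_size = c(64, 64), seed = 11)
    run_experiment(cfg)
  })
}

# null-signal cohort features (handcrafted block only; tiny backbone)
null_cohort_features <- function() {
  cached_fixture("null_cohort_features", function() {
    cc <- cohort_config(n_patients = 30, nodes_per_patient_mean = 20,
                        nodes_per_patient_sd = 8, size_effect = 0,
                        attenuation_effect = 0, texture_effect = 0, seed = 21)
    ch <- generate_cohort(cc)
    bb <- build_backbone(backbone_config(c(4, 4, 4), seed = 22))
    tb <- extract_feature_tables(ch, bb, xy_size = c(16, 16))
    assemble_feature_set(tb$handcrafted, tb$deep, "handcrafted")
  })
}
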