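# Signal-channel properties of the synthetic cohort.

test_that("the texture channel is first-order invisible on the native grid", {
  # rank-Gaussianised texture: identical in-mask marginals for both classes,
  # so with size/attenuation effects off, first-order features computed on
  # the native grid carry no label information
  cc <- cohort_config(n_patients = 20, nodes_per_patient_mean = 10,
                      nodes_per_patient_sd = 3, size_effect = 0,
                      attenuation_effect = 0, texture_effect = 2,
                      base_hu_sd = 0, noise_sd = 0, seed = 51)
  ch <- generate_cohort(cc)
  rows <- list(); labs <- integer()
  for (pc in ch) for (nd in pc$nodes) {
    voi <- extract_voi(nd$image, nd$mask)
    rows[[length(rows) + 1L]] <- compute_first_order(voi)
    labs <- c(labs, nd$label)
  }
  X <- do.call(rbind, rows)
  skip_if(sum(labs) < 10 || sum(labs == 0) < 10)
  # per-feature discrimination stays at chance level
  aucs <- apply(X[, apply(X, 2, stats::sd) > 0], 2, function(f) auc(labs, f))
  expect_lt(max(abs(aucs - 0.5)), 0.12)
})

test_that("increasing the size effect monotonically helps a shape-only model", {
  aucs <- vapply(c(0, 1, 2.5), function(se) {
    cc <- cohort_config(n_patients = 20, nodes_per_patient_mean = 10,
                        nodes_per_patient_sd = 3, size_effect = se,
                        attenuation_effect = 0, texture_effect = 0,
                        texture_amp = 0, noise_sd = 5, seed = 31)
    ch <- generate_cohort(cc)
    rows <- list(); meta <- list()
    for (pc in ch) for (nd in pc$nodes) {
      msk <- resample_isotropic(image_volume(array(as.numeric(nd$mask),
                                                   dim(nd$mask)),
                                             nd$image$spacing), 1, is_mask = TRUE)
      rows[[length(rows) + 1L]] <- compute_shape(msk$voxels, c(1, 1, 1))
      meta[[length(meta) + 1L]] <- data.frame(node_id = nd$node_id,
                                              patient_id = pc$patient_id,
                                              label = nd$label)
    }
    ft <- cbind(do.call(rbind, meta), as.data.frame(do.call(rbind, rows)))
    pos <- tapply(ft$label, ft$patient_id, max)
    plan <- make_patient_folds(names(pos), folds = 4, repeats = 2, seed = 32,
                               strata = as.integer(pos))
    hp <- list(model = "elastic_logit", id = "c1", depth_k = 1, use_pca = FALSE,
               penalty = 0.01, mixing = 0.5)
    pm <- cross_validate(ft, list(hp), plan, seed = 33)
    pooled_config_metrics(pm, "auc")
  }, 0)
  expect_true(all(diff(aucs) > 0))
  expect_gt(aucs[3], 0.85)
})

test_that("deep features alone detect the texture-arrangement channel", {
  cc <- cohort_config(n_patients = 30, nodes_per_patient_mean = 12,
                      nodes_per_patient_sd = 4, size_effect = 0,
                      attenuation_effect = 0, texture_effect = 2, seed = 41)
  ch <- generate_cohort(cc)
  bb <- build_backbone(backbone_config(seed = 42))
  tb <- extract_feature_tables(ch, bb, xy_size = c(64, 64))
  dt <- assemble_feature_set(tb$handcrafted, tb$deep, "deep")
  pats <- unique(dt$patient_id)
  tr_pats <- withr::with_seed(1, sample(pats, length(pats) / 2))
  tr <- dt$patient_id %in% tr_pats
  hp <- list(model = "random_forest", id = "c", depth_k = 1, use_pca = FALSE,
             trees = 400, min_leaf = 5, max_depth = 0, mtry_frac = NA)
  m <- fit_model(dt[tr, -(1:3)], dt$label[tr], hp, seed = 2)
  a <- auc(dt$label[!tr], predict_probability(m, dt[!tr, -(1:3)]))
  expect_gt(a, 0.55)
})
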