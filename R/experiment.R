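# End-to-end experiment: cohort -> features -> CV grid -> corrected report.

#' Extract hand-crafted and deep feature tables for a cohort
#'
#' Per node: the volume and mask are resampled to isotropic 1 mm voxels
#' (trilinear for the image, nearest-neighbour for the mask; no intensity
#' scaling). Hand-crafted features are computed strictly over in-mask voxels
#' of the cropped VOI. For the deep path the VOI is masked with the intensity
#' window minimum, standardised to a fixed slice stack and forwarded through
#' the frozen backbone, pooling features at every stage.
#'
#' @param cohort output of [generate_cohort()] or [read_cohort()].
#' @param backbone a [build_backbone()] result.
#' @param target_spacing_mm isotropic resampling target (default 1 mm).
#' @param disc a [discretization_config()].
#' @param z_slices,xy_size,window arguments of [standardize_stack()].
#' @return list with `handcrafted` and `deep` data.frames (aligned rows).
#' @export
extract_feature_tables <- function(cohort, backbone, target_spacing_mm = 1,
                                   disc = discretization_config(),
                                   z_slices = 10, xy_size = c(224, 224),
                                   window = c(-160, 240)) {
  hc_rows <- list(); dp_rows <- list(); meta <- list()
  for (pc in cohort) {
    for (nd in pc$nodes) {
      img <- resample_isotropic(nd$image, target_spacing_mm, is_mask = FALSE)
      msk <- resample_isotropic(image_volume(array(as.numeric(nd$mask),
                                                   dim(nd$mask)),
                                             nd$image$spacing),
                                target_spacing_mm, is_mask = TRUE)
      voi <- extract_voi(img, msk$voxels, fill_value = NULL,
                         patient_id = pc$patient_id, label = nd$label,
                         node_id = nd$node_id)
      hc_rows[[length(hc_rows) + 1L]] <- assemble_handcrafted(voi, disc)
      voi_cnn <- extract_voi(img, msk$voxels, fill_value = window[1])
      stack <- standardize_stack(voi_cnn, z_slices = z_slices,
                                 xy_size = xy_size, window = window)
      dp_rows[[length(dp_rows) + 1L]] <- forward_features_all(backbone, stack)
      meta[[length(meta) + 1L]] <- data.frame(node_id = nd$node_id,
                                              patient_id = pc$patient_id,
                                              label = as.integer(nd$label),
                                              stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, meta)
  list(handcrafted = cbind(meta, as.data.frame(do.call(rbind, hc_rows))),
       deep = cbind(meta, as.data.frame(do.call(rbind, dp_rows))))
}

#' Experiment configuration
#'
#' Bundles every stage's settings. The defaults mirror the full evaluation
#' design (10 x 20 patient-level CV, Brier-selected BBC with B = 1000);
#' desk-scale runs shrink `repeats`/`folds`/`n_configs`/`xy_size`.
#'
#' @param cohort a [cohort_config()] or a manifest CSV path.
#' @param models model families to fit.
#' @param feature_sets feature sets to compare.
#' @param n_configs random-search budget per model family.
#' @param folds,repeats patient-level CV plan.
#' @param bbc_B bootstrap draws for the bias correction.
#' @param selection_metric `"brier"` (primary) or `"auc"`.
#' @param stage_channels backbone stage widths.
#' @param z_slices,xy_size,window deep-path standardisation settings.
#' @param bin_width texture discretisation (HU).
#' @param seed global seed; every stage derives its own stream from it.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(cohort,
                              models = c("elastic_logit", "random_forest"),
                              feature_sets = c("handcrafted", "deep", "hybrid"),
                              n_configs = 50, folds = 20, repeats = 10,
                              bbc_B = 1000, selection_metric = "brier",
                              stage_channels = c(32, 64, 128, 256),
                              z_slices = 10, xy_size = c(224, 224),
                              window = c(-160, 240), bin_width = 25,
                              seed = 1L) {
  structure(list(cohort = cohort, models = models, feature_sets = feature_sets,
                 n_configs = n_configs, folds = folds, repeats = repeats,
                 bbc_B = bbc_B, selection_metric = selection_metric,
                 stage_channels = stage_channels, z_slices = z_slices,
                 xy_size = xy_size, window = window, bin_width = bin_width,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run the full comparison experiment
#'
#' Generates (or reads) the cohort, extracts all feature sets, runs the
#' model-by-feature-set grid under patient-level repeated CV, applies the
#' bootstrap bias correction, tests pairwise AUC and Brier differences
#' between feature sets, and assembles the comparative report. Fully
#' reproducible from `(config, config$seed)`.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional directory for CSV/JSON outputs.
#' @return an `experiment_report`: `table` (one row per feature set x model),
#'   `pairwise` tests, `calibration` curves, prediction matrices and BBC
#'   results.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  seed <- config$seed
  cohort <- if (inherits(config$cohort, "cohort_config")) {
    generate_cohort(config$cohort)
  } else {
    read_cohort(config$cohort)
  }
  backbone <- build_backbone(backbone_config(
    stage_channels = config$stage_channels, seed = derive_seed(seed, "backbone")))
  tables <- extract_feature_tables(cohort, backbone,
                                   disc = discretization_config(config$bin_width),
                                   z_slices = config$z_slices,
                                   xy_size = config$xy_size,
                                   window = config$window)
  labels_tbl <- tables$handcrafted[c("node_id", "patient_id", "label")]
  patient_has_pos <- tapply(labels_tbl$label, labels_tbl$patient_id, max)
  patient_ids <- names(patient_has_pos)
  plan <- make_patient_folds(patient_ids, folds = config$folds,
                             repeats = config$repeats,
                             seed = derive_seed(seed, "folds"),
                             strata = as.integer(patient_has_pos))
  sets <- lapply(stats::setNames(config$feature_sets, config$feature_sets),
                 function(fs) assemble_feature_set(tables$handcrafted,
                                                   tables$deep, fs))
  rows <- list(); pairwise <- list(); calib <- list()
  pms <- list(); bbcs <- list()
  for (model in config$models) {
    configs <- sample_hyperparameters(model, config$n_configs,
                                      derive_seed(seed, "hp", model))
    for (fs in config$feature_sets) {
      key <- paste(model, fs, sep = ".")
      pm <- cross_validate(sets[[fs]], configs, plan,
                           seed = derive_seed(seed, "cv", model, fs))
      bbc <- bbc_select(pm, selection_metric = config$selection_metric,
                        B = config$bbc_B, seed = derive_seed(seed, "bbc", model, fs))
      pms[[key]] <- pm; bbcs[[key]] <- bbc
      est <- bbc$estimates; ci <- bbc$ci
      rows[[key]] <- data.frame(
        model = model, feature_set = fs,
        auc = est["auc"], auc_lo = ci[1, "auc"], auc_hi = ci[2, "auc"],
        brier = est["brier"], brier_lo = ci[1, "brier"], brier_hi = ci[2, "brier"],
        sbs = est["sbs"], sbs_lo = ci[1, "sbs"], sbs_hi = ci[2, "sbs"],
        sensitivity = est["sensitivity"], specificity = est["specificity"],
        cutoff = est["cutoff"], row.names = NULL)
      best <- which.min(pooled_config_metrics(pm, config$selection_metric))
      calib[[key]] <- lowess_calibration(pm$labels,
                                         rowMeans(pm$preds[, best, , drop = FALSE]))
    }
    # pairwise feature-set tests on each arm's selected-config pooled predictions
    fsets <- config$feature_sets
    if (length(fsets) > 1) {
      combos <- utils::combn(fsets, 2, simplify = FALSE)
      for (cmb in combos) {
        pa <- best_config_predictions(pms[[paste(model, cmb[1], sep = ".")]],
                                      config$selection_metric)
        pb <- best_config_predictions(pms[[paste(model, cmb[2], sep = ".")]],
                                      config$selection_metric)
        for (met in c("auc", "brier")) {
          tst <- paired_bootstrap_z_test(labels_tbl$label, pa, pb, metric = met,
                                         B = max(500, config$bbc_B),
                                         seed = derive_seed(seed, "ztest", model,
                                                            cmb[1], cmb[2], met))
          pairwise[[length(pairwise) + 1L]] <- data.frame(
            model = model, a = cmb[1], b = cmb[2], metric = met,
            difference = tst$difference, z = tst$z, p = tst$p)
        }
      }
    }
  }
  report <- structure(list(table = do.call(rbind, rows),
                           pairwise = do.call(rbind, pairwise),
                           calibration = calib,
                           prediction_matrices = pms, bbc = bbcs,
                           config = config),
                      class = "experiment_report")
  if (!is.null(out_dir)) write_report(report, out_dir, cohort, backbone)
  report
}

#' Pooled predictions of the plainly selected configuration
#'
#' Returns the nodes-by-repeats pooled out-of-fold predictions of the
#' configuration that wins the (uncorrected) pooled selection metric — the
#' per-arm prediction set the pairwise feature-set tests compare.
#'
#' @param pm a [cross_validate()] result.
#' @param selection_metric `"brier"` (minimised) or `"auc"` (maximised).
#' @return numeric matrix, nodes x repeats.
#' @export
best_config_predictions <- function(pm, selection_metric = "brier") {
  vals <- pooled_config_metrics(pm, selection_metric)
  best <- if (selection_metric == "auc") which.max(vals) else which.min(vals)
  matrix(pm$preds[, best, , drop = FALSE], dim(pm$preds)[1], dim(pm$preds)[3])
}

write_report <- function(report, out_dir, cohort, backbone) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$table, file.path(out_dir, "report.csv"), row.names = FALSE)
  utils::write.csv(report$pairwise, file.path(out_dir, "pairwise_tests.csv"),
                   row.names = FALSE)
  for (key in names(report$calibration)) {
    utils::write.csv(report$calibration[[key]],
                     file.path(out_dir, sprintf("calibration_%s.csv", key)),
                     row.names = FALSE)
  }
  jsonlite::write_json(list(table = report$table, pairwise = report$pairwise),
                       file.path(out_dir, "report.json"), digits = NA,
                       dataframe = "rows")
  # feature-map illustration for one positive and one negative node
  maps <- tryCatch(example_feature_maps(cohort, backbone), error = function(e) NULL)
  if (!is.null(maps)) {
    for (nm in names(maps)) {
      write_nifti_volume(maps[[nm]], file.path(out_dir, sprintf("map_%s.nii.gz", nm)))
    }
  }
  invisible(out_dir)
}

#' Voxel-based and deep feature maps for one node of each class
#'
#' Picks the first positive and first negative node of the cohort and returns
#' a hand-crafted voxel map (local mean and local contrast) plus one stage-3
#' deep activation map for each, for side-by-side visual comparison.
#'
#' @param cohort a generated or read cohort.
#' @param backbone a [build_backbone()] result.
#' @return named list of [image_volume()] objects.
#' @export
example_feature_maps <- function(cohort, backbone) {
  nodes <- do.call(c, lapply(cohort, `[[`, "nodes"))
  lab <- vapply(nodes, function(nd) as.integer(nd$label), 0L)
  picks <- c(positive = which(lab == 1)[1], negative = which(lab == 0)[1])
  assert_that(!anyNA(picks), "need at least one node of each class")
  out <- list()
  for (cls in names(picks)) {
    nd <- nodes[[picks[[cls]]]]
    img <- resample_isotropic(nd$image, 1)
    msk <- resample_isotropic(image_volume(array(as.numeric(nd$mask), dim(nd$mask)),
                                           nd$image$spacing), 1, is_mask = TRUE)
    voi <- extract_voi(img, msk$voxels)
    out[[paste0(cls, "_mean")]] <- compute_voxel_map(voi, "firstorder.mean", 2)
    out[[paste0(cls, "_contrast")]] <- compute_voxel_map(voi, "glcm.contrast", 2)
    voi_cnn <- extract_voi(img, msk$voxels, fill_value = -160)
    stack <- standardize_stack(voi_cnn, xy_size = c(64, 64))
    dm <- deep_feature_maps(backbone, stack, layer_index = 3)[[1]]
    out[[paste0(cls, "_deep_s3c1")]] <- image_volume(array(dm, c(dim(dm), 1)),
                                                     c(1, 1, 1))
  }
  out
}
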