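#!/usr/bin/env Rscript
# Stage 2: read the cohort back through the real-data path (manifest +
# NIfTI), resample to isotropic 1 mm voxels, and extract both feature
# families per node:
#   * hand-crafted IBSI-style first-order, 3D shape and GLCM features over
#     the in-mask voxels (no intensity rescaling)
#   * deep features: windowed, z-scored 10-slice stacks forwarded through a
#     frozen seeded-random 4-stage 2D conv backbone, average-pooled at every
#     stage (the model layer later picks the stage via its depth hyperparameter)

library(nodalrad)

manifest <- "results/cohort/manifest.csv"
seed <- 11L

cohort <- read_cohort(manifest)
backbone <- build_backbone(backbone_config(seed = derive_seed(seed, "backbone")))
tables <- extract_feature_tables(cohort, backbone, xy_size = c(64, 64))

write.csv(tables$handcrafted, "results/features_handcrafted.csv", row.names = FALSE)
write.csv(tables$deep, "results/features_deep.csv", row.names = FALSE)

cat(sprintf("hand-crafted: %d nodes x %d features\n",
            nrow(tables$handcrafted), ncol(tables$handcrafted) - 3))
cat(sprintf("deep: %d nodes x %d features\n",
            nrow(tables$deep), ncol(tables$deep) - 3))
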