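#!/usr/bin/env Rscript
# Stage 4: interpretability output — voxel-based hand-crafted feature maps
# (local mean, local GLCM contrast) and un-pooled stage-3 deep activation
# maps for one PET-positive and one PET-negative example node, plus lowess
# calibration curves for the selected configurations.

library(nodalrad)

cohort <- read_cohort("results/cohort/manifest.csv")
backbone <- build_backbone(backbone_config(seed = derive_seed(11L, "backbone")))

maps <- example_feature_maps(cohort, backbone)
dir.create("results/maps", showWarnings = FALSE)
for (nm in names(maps)) {
  path <- file.path("results/maps", paste0(nm, ".nii.gz"))
  write_nifti_volume(maps[[nm]], path)
  cat("wrote", path, "\n")
}
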