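#' Write a cohort to NIfTI volumes plus a CSV manifest
#'
#' One `.nii.gz` image and one `.nii.gz` mask per node, and a manifest CSV with
#' columns `node_id`, `patient_id`, `label`, `image_path`, `mask_path` (paths
#' relative to the manifest's directory). The layout round-trips losslessly
#' through [read_cohort()].
#'
#' @param cohort output of [generate_cohort()].
#' @param out_dir writable directory (created if missing).
#' @return path to the manifest CSV.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  assert_that(dir.exists(out_dir), sprintf("cannot create directory '%s'", out_dir))
  rows <- list()
  for (pc in cohort) {
    for (nd in pc$nodes) {
      img_rel <- file.path(pc$patient_id, paste0(nd$node_id, "_image.nii.gz"))
      msk_rel <- file.path(pc$patient_id, paste0(nd$node_id, "_mask.nii.gz"))
      dir.create(file.path(out_dir, pc$patient_id), showWarnings = FALSE)
      write_nifti_volume(nd$image, file.path(out_dir, img_rel))
      write_nifti_volume(image_volume(array(as.numeric(nd$mask), dim(nd$mask)),
                                      nd$image$spacing),
                         file.path(out_dir, msk_rel))
      rows[[length(rows) + 1L]] <- data.frame(
        node_id = nd$node_id, patient_id = pc$patient_id,
        label = as.integer(nd$label), image_path = img_rel, mask_path = msk_rel,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  path
}

#' Write an image volume to NIfTI
#'
#' Voxel data are stored as float64 (lossless); spacing goes through the
#' NIfTI-1 header's float32 `pixdim`.
#'
#' @param volume an [image_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_nifti_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  image_volume(array(as.numeric(img), dim(img)), RNifti::pixdim(img)[1:3])
}

#' Validate a cohort manifest
#'
#' Checks that the manifest has the required columns, that every referenced
#' file exists, that labels are binary, that each mask is non-empty and shares
#' grid and spacing with its image. Violations are reported with the row
#' number and node id. Returns a lazily loading handle.
#'
#' @param path manifest CSV path.
#' @return a `cohort_manifest` handle with the manifest table and a
#'   `load_node(i)` closure.
#' @export
validate_manifest <- function(path) {
  assert_that(file.exists(path), sprintf("manifest '%s' does not exist", path))
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("node_id", "patient_id", "label", "image_path", "mask_path")
  missing_cols <- setdiff(required, names(man))
  assert_that(length(missing_cols) == 0,
              paste("manifest missing columns:", paste(missing_cols, collapse = ", ")))
  base <- dirname(path)
  if (!all(man$label %in% c(0L, 1L))) {
    bad <- which(!(man$label %in% c(0L, 1L)))[1]
    stop(sprintf("row %d (node %s): label '%s' is not in {0,1}",
                 bad, man$node_id[bad], man$label[bad]), call. = FALSE)
  }
  for (i in seq_len(nrow(man))) {
    for (col in c("image_path", "mask_path")) {
      f <- file.path(base, man[[col]][i])
      if (!file.exists(f)) {
        stop(sprintf("row %d (node %s): missing file '%s'", i, man$node_id[i], f),
             call. = FALSE)
      }
    }
    msk <- read_nifti_volume(file.path(base, man$mask_path[i]))
    img <- read_nifti_volume(file.path(base, man$image_path[i]))
    if (!identical(dim(img$voxels), dim(msk$voxels)) ||
        max(abs(img$spacing - msk$spacing)) > 1e-5) {
      stop(sprintf("row %d (node %s): image and mask grids disagree", i, man$node_id[i]),
           call. = FALSE)
    }
    if (sum(msk$voxels != 0) == 0) {
      stop(sprintf("row %d (node %s): empty mask", i, man$node_id[i]), call. = FALSE)
    }
  }
  load_node <- function(i) {
    img <- read_nifti_volume(file.path(base, man$image_path[i]))
    msk <- read_nifti_volume(file.path(base, man$mask_path[i]))
    list(image = img, mask = array(as.integer(msk$voxels != 0), dim(msk$voxels)),
         label = as.integer(man$label[i]), node_id = man$node_id[i],
         patient_id = man$patient_id[i])
  }
  structure(list(manifest = man, dir = base, load_node = load_node),
            class = "cohort_manifest")
}

#' Read a cohort back from a manifest
#'
#' @param manifest_path manifest CSV written by [write_cohort()].
#' @return the same structure [generate_cohort()] returns.
#' @export
read_cohort <- function(manifest_path) {
  handle <- validate_manifest(manifest_path)
  man <- handle$manifest
  lapply(unique(man$patient_id), function(pid) {
    idx <- which(man$patient_id == pid)
    list(patient_id = pid, nodes = lapply(idx, handle$load_node))
  })
}
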