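#' Voxel-based feature map
#'
#' Recomputes a first-order or co-occurrence feature in the cubic
#' neighbourhood of every in-mask voxel (the neighbourhood is intersected with
#' the mask), yielding a map of the feature's spatial distribution for
#' visual interpretation. Out-of-mask voxels carry `NA` as the sentinel.
#'
#' @param voi a [node_voi()].
#' @param feature_name one of the names returned by [compute_first_order()] or
#'   [compute_glcm()] (e.g. `"firstorder.mean"`, `"glcm.contrast"`).
#' @param kernel_radius neighbourhood half-width in voxels (box of side
#'   `2 * kernel_radius + 1`).
#' @param disc a [discretization_config()].
#' @return an [image_volume()] of feature values (`NA` outside the mask).
#' @export
compute_voxel_map <- function(voi, feature_name, kernel_radius = 1,
                              disc = discretization_config()) {
  stopifnot(inherits(voi, "node_voi"))
  fo_names <- names(first_order_from_values(c(0, 1), disc$bin_width))
  glcm_names <- c("glcm.joint_energy", "glcm.joint_entropy", "glcm.contrast",
                  "glcm.idm", "glcm.correlation")
  if (!(feature_name %in% c(fo_names, glcm_names))) {
    stop(sprintf("unknown feature name '%s'", feature_name), call. = FALSE)
  }
  is_glcm <- feature_name %in% glcm_names
  d <- dim(voi$mask)
  out <- array(NA_real_, d)
  idx <- which(voi$mask == 1L, arr.ind = TRUE)
  r <- as.integer(kernel_radius)
  for (row in seq_len(nrow(idx))) {
    lo <- pmax(idx[row, ] - r, 1L)
    hi <- pmin(idx[row, ] + r, d)
    sub_img <- voi$image$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    sub_msk <- voi$mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    dims <- hi - lo + 1L
    if (is_glcm) {
      sub_voi <- node_voi(image_volume(array(sub_img, dims), voi$image$spacing),
                          array(sub_msk, dims))
      val <- tryCatch(compute_glcm(sub_voi, disc)[[feature_name]],
                      error = function(e) NA_real_)
    } else {
      vals <- sub_img[sub_msk == 1L]
      val <- first_order_from_values(vals, disc$bin_width)[[feature_name]]
    }
    out[idx[row, 1], idx[row, 2], idx[row, 3]] <- val
  }
  image_volume(out, voi$image$spacing, voi$image$origin)
}

#' Full hand-crafted feature vector for one node
#'
#' Concatenates the first-order, shape and co-occurrence blocks in a stable
#' order. The `firstorder` + `shape` subset (without `glcm.*`) is the
#' hand-crafted half of the hybrid feature set.
#'
#' @param voi a [node_voi()].
#' @param disc a [discretization_config()].
#' @return named numeric vector.
#' @export
assemble_handcrafted <- function(voi, disc = discretization_config()) {
  c(compute_first_order(voi, disc),
    compute_shape(voi$mask, voi$image$spacing),
    compute_glcm(voi, disc))
}

#' Select feature blocks by name prefix
#'
#' @param x named numeric vector or data.frame of features.
#' @param blocks character vector of prefixes, e.g. `c("firstorder", "shape")`.
#' @return the subset with matching `prefix.` names (columns for data.frames).
#' @export
feature_subset <- function(x, blocks) {
  nm <- if (is.data.frame(x)) names(x) else names(x)
  keep <- Reduce(`|`, lapply(blocks, function(b) startsWith(nm, paste0(b, "."))))
  if (is.data.frame(x)) x[, keep, drop = FALSE] else x[keep]
}
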