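#' Image volume container
#'
#' A minimal 3D scalar grid with physical spacing, the unit of exchange between
#' the cohort generator, the preprocessing steps and the feature extractors.
#' Intensities are in Hounsfield units (HU); spacing and origin are in mm.
#'
#' @param voxels 3D numeric array.
#' @param spacing numeric length-3, voxel spacing in mm (all > 0).
#' @param origin numeric length-3, physical position of voxel (1,1,1) in mm.
#' @return an `image_volume` object.
#' @export
image_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3)
  spacing <- as.numeric(spacing)
  assert_that(length(spacing) == 3 && all(spacing > 0),
              "spacing must be three positive numbers (mm)")
  # NA is tolerated as the out-of-mask sentinel in feature maps
  assert_that(!any(is.nan(voxels) | is.infinite(voxels)),
              "voxel intensities must be finite or NA")
  structure(list(voxels = voxels, spacing = spacing, origin = as.numeric(origin)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.1f, %.1f] HU\n",
              min(x$voxels, na.rm = TRUE), max(x$voxels, na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$voxels)

#' Node volume of interest
#'
#' A node's image cropped to the tight bounding box of its segmentation, with
#' the binary mask on the same grid, plus bookkeeping (patient id, label).
#'
#' @param image `image_volume` restricted to the bounding box.
#' @param mask binary (0/1) array of the same shape.
#' @param patient_id,label,node_id optional metadata carried through the pipeline.
#' @return a `node_voi` object.
#' @export
node_voi <- function(image, mask, patient_id = NA_character_,
                     label = NA_integer_, node_id = NA_character_) {
  stopifnot(inherits(image, "image_volume"))
  mask <- array(as.integer(mask != 0), dim = dim(mask))
  assert_that(identical(dim(image$voxels), dim(mask)),
              "image and mask must share a grid")
  assert_that(sum(mask) > 0, "empty segmentation mask")
  structure(list(image = image, mask = mask, patient_id = patient_id,
                 label = label, node_id = node_id),
            class = "node_voi")
}

#' @export
print.node_voi <- function(x, ...) {
  d <- dim(x$image$voxels)
  cat(sprintf("<node_voi> %s (patient %s, label %s): %d x %d x %d grid, %d in-mask voxels\n",
              x$node_id, x$patient_id, x$label, d[1], d[2], d[3], sum(x$mask)))
  invisible(x)
}

# in-mask intensity vector
voi_values <- function(voi) voi$image$voxels[voi$mask == 1L]
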