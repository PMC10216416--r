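# Preprocessing: isotropic resampling, VOI extraction, and standardisation of
# each node into a fixed-shape slice stack for the deep feature extractor.
#
# Conventions (stated once, tested): voxel indices are 0-based in the
# coordinate mapping below; bounding boxes are inclusive index ranges;
# physical spacing is in mm. Resampling maps output voxel centres through the
# shared physical extent: src = (j + 0.5) * ratio - 0.5, so a no-op resample
# is the exact identity.

resample_axis <- function(a, dim_index, n_new, ratio, linear = TRUE) {
  d <- dim(a)
  n <- d[dim_index]
  if (n_new == n && abs(ratio - 1) < 1e-12) return(a)
  src <- (seq_len(n_new) - 0.5) * ratio - 0.5  # 0-based source coordinates
  src <- pmin(pmax(src, 0), n - 1)
  perm <- c(dim_index, setdiff(1:3, dim_index))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- matrix(ap, nrow = n)
  if (linear) {
    i0 <- pmin(floor(src), n - 1)
    w <- src - i0
    i1 <- pmin(i0 + 1, n - 1)
    out <- m[i0 + 1, , drop = FALSE] * (1 - w) + m[i1 + 1, , drop = FALSE] * w
  } else {
    out <- m[round(src) + 1, , drop = FALSE]
  }
  out <- array(out, dim = c(n_new, dp[-1]))
  aperm(out, order(perm))
}

#' Resample a volume to isotropic spacing
#'
#' Grid size per axis is `round(size * spacing / target)`; interpolation is
#' trilinear (separable) for images and nearest-neighbour for masks. No
#' intensity rescaling is applied.
#'
#' @param volume an [image_volume()].
#' @param target_spacing_mm scalar target spacing (default 1 mm).
#' @param is_mask if `TRUE`, use nearest-neighbour interpolation.
#' @return resampled [image_volume()].
#' @export
resample_isotropic <- function(volume, target_spacing_mm = 1, is_mask = FALSE) {
  stopifnot(inherits(volume, "image_volume"))
  assert_that(is.numeric(target_spacing_mm) && target_spacing_mm > 0,
              "target spacing must be positive")
  d <- dim(volume$voxels)
  n_new <- pmax(1L, as.integer(round(d * volume$spacing / target_spacing_mm)))
  a <- volume$voxels
  for (ax in 1:3) {
    a <- resample_axis(a, ax, n_new[ax], target_spacing_mm / volume$spacing[ax],
                       linear = !is_mask)
  }
  if (is_mask) a <- array(as.integer(a != 0), dim = dim(a))
  image_volume(a, rep(target_spacing_mm, 3), volume$origin)
}

#' Extract a node's volume of interest
#'
#' Crops image and mask to the tight axis-aligned bounding box of the mask;
#' optionally replaces out-of-mask voxels by `fill_value`. Hand-crafted
#' features are computed strictly over in-mask voxels, so they need no fill;
#' the deep path fills with its intensity-window minimum.
#'
#' @param volume an [image_volume()].
#' @param mask binary array on the same grid.
#' @param fill_value HU value for out-of-mask voxels, or `NULL` to leave them.
#' @param patient_id,label,node_id metadata to carry.
#' @return a [node_voi()].
#' @export
extract_voi <- function(volume, mask, fill_value = NULL,
                        patient_id = NA_character_, label = NA_integer_,
                        node_id = NA_character_) {
  stopifnot(inherits(volume, "image_volume"))
  assert_that(identical(dim(volume$voxels), dim(mask)), "mask and volume grids differ")
  idx <- which(mask != 0, arr.ind = TRUE)
  assert_that(nrow(idx) > 0, "empty segmentation mask")
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  img <- volume$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  msk <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  msk <- array(as.integer(msk != 0), dim = dim(msk))
  if (!is.null(fill_value)) img[msk == 0L] <- fill_value
  node_voi(image_volume(array(img, dim(msk)), volume$spacing,
                        volume$origin + (lo - 1) * volume$spacing),
           msk, patient_id = patient_id, label = label, node_id = node_id)
}

#' Standardise a VOI into a fixed-shape slice stack
#'
#' Resamples the z-axis to `z_slices` (default 10, the median node z-extent at
#' 1 mm spacing in the emulated population), resizes every slice to `xy_size`,
#' clips intensities to `window` and maps them affinely to `[0, 1]`. This is
#' the input format of the deep feature extractor.
#'
#' @param voi a [node_voi()] (out-of-mask voxels should already be filled).
#' @param z_slices target slice count.
#' @param xy_size target in-plane size (pixels), length 2.
#' @param window HU clipping window `(low, high)`, mapped to `(0, 1)`.
#' @return a `slice_stack`: array `xy_size[1] x xy_size[2] x z_slices` with the
#'   window recorded as an attribute.
#' @export
standardize_stack <- function(voi, z_slices = 10, xy_size = c(224, 224),
                              window = c(-160, 240)) {
  stopifnot(inherits(voi, "node_voi"))
  a <- voi$image$voxels
  d <- dim(a)
  assert_that(all(d >= 1) && z_slices >= 1 && all(xy_size >= 1),
              "degenerate VOI or target shape")
  assert_that(window[2] > window[1], "intensity window must be increasing")
  a <- resample_axis(a, 3, as.integer(z_slices), d[3] / z_slices)
  a <- resample_axis(a, 1, as.integer(xy_size[1]), d[1] / xy_size[1])
  a <- resample_axis(a, 2, as.integer(xy_size[2]), d[2] / xy_size[2])
  a <- (pmin(pmax(a, window[1]), window[2]) - window[1]) / (window[2] - window[1])
  structure(a, class = "slice_stack", window = window)
}
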