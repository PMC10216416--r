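# Grey-level co-occurrence texture features over the in-mask voxels of a VOI.

#' The 13 unique 3D direction offsets
#'
#' One representative per opposite-direction pair of the 26-neighbourhood.
#' @return integer matrix 13 x 3.
#' @export
glcm_offsets <- function() {
  m <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
             c(1, 1, 0), c(1, -1, 0),
             c(1, 0, 1), c(1, 0, -1),
             c(0, 1, 1), c(0, 1, -1),
             c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  storage.mode(m) <- "integer"
  m
}

# Accumulate symmetric co-occurrence counts of the discretised VOI for one
# offset; both voxels of a pair must be in-mask.
glcm_counts_offset <- function(lev, mask, off, n_levels) {
  d <- dim(lev)
  r <- lapply(1:3, function(ax) {
    lo <- max(1L, 1L - off[ax]); hi <- min(d[ax], d[ax] - off[ax])
    if (lo > hi) return(NULL)
    lo:hi
  })
  if (any(vapply(r, is.null, TRUE))) return(numeric(n_levels^2))
  a_lev <- lev[r[[1]], r[[2]], r[[3]], drop = FALSE]
  a_msk <- mask[r[[1]], r[[2]], r[[3]], drop = FALSE]
  b_lev <- lev[r[[1]] + off[1], r[[2]] + off[2], r[[3]] + off[3], drop = FALSE]
  b_msk <- mask[r[[1]] + off[1], r[[2]] + off[2], r[[3]] + off[3], drop = FALSE]
  keep <- a_msk == 1L & b_msk == 1L
  if (!any(keep)) return(numeric(n_levels^2))
  ai <- a_lev[keep]; bi <- b_lev[keep]
  # symmetric: count each ordered pair in both directions
  tabulate(ai + (bi - 1L) * n_levels, nbins = n_levels^2) +
    tabulate(bi + (ai - 1L) * n_levels, nbins = n_levels^2)
}

#' Grey-level co-occurrence matrix features
#'
#' Builds a single symmetric GLCM accumulated over the given direction offsets
#' at the given voxel distance, restricted to voxel pairs that are both
#' in-mask, normalised to sum 1; then returns joint energy, joint entropy,
#' contrast, inverse difference moment and correlation. Correlation is defined
#' as 1 when the discretised VOI is constant.
#'
#' @param voi a [node_voi()].
#' @param disc a [discretization_config()].
#' @param distance offset length in voxels (default 1).
#' @param offsets integer matrix of direction offsets (default the 13 unique
#'   3D directions); exposed so single directions can be checked by hand.
#' @return named numeric vector, names prefixed `glcm.`.
#' @export
compute_glcm <- function(voi, disc = discretization_config(), distance = 1,
                         offsets = glcm_offsets()) {
  stopifnot(inherits(voi, "node_voi"))
  x <- voi_values(voi)
  assert_that(length(x) >= 2, "need at least two in-mask voxels")
  lev_in <- discretize_hu(x, disc$bin_width)
  n_levels <- max(lev_in)
  lev <- array(0L, dim(voi$mask))
  lev[voi$mask == 1L] <- lev_in
  counts <- numeric(n_levels^2)
  for (k in seq_len(nrow(offsets))) {
    counts <- counts + glcm_counts_offset(lev, voi$mask,
                                          as.integer(offsets[k, ]) * as.integer(distance),
                                          n_levels)
  }
  assert_that(sum(counts) > 0, "no valid in-mask voxel pairs at this offset/distance")
  p <- matrix(counts / sum(counts), n_levels, n_levels)
  i <- row(p); j <- col(p)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  sd_i <- sqrt(sum((i - mu_i)^2 * p)); sd_j <- sqrt(sum((j - mu_j)^2 * p))
  nz <- p > 0
  correlation <- if (sd_i > 0 && sd_j > 0) {
    sum((i - mu_i) * (j - mu_j) * p) / (sd_i * sd_j)
  } else 1
  c(glcm.joint_energy = sum(p^2),
    glcm.joint_entropy = -sum(p[nz] * log2(p[nz])),
    glcm.contrast = sum((i - j)^2 * p),
    glcm.idm = sum(p / (1 + (i - j)^2)),
    glcm.correlation = correlation)
}
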