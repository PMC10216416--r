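#' Discretisation settings for texture features
#'
#' Intensities are binned with a fixed bin width anchored at the in-mask
#' minimum: `level = floor((x - min) / bin_width) + 1`. Applies to the
#' co-occurrence features and to the first-order entropy; all other
#' first-order statistics use raw HU.
#'
#' @param bin_width bin width in HU (> 0), default 25.
#' @return a `discretization_config` list.
#' @export
discretization_config <- function(bin_width = 25) {
  assert_that(is.numeric(bin_width) && bin_width > 0, "bin_width must be > 0")
  structure(list(bin_width = bin_width), class = "discretization_config")
}

discretize_hu <- function(x, bin_width) {
  as.integer(floor((x - min(x)) / bin_width)) + 1L
}

# First-order statistics from a bare intensity vector. Variance, skewness and
# kurtosis are the population (biased, n-denominator) estimators; kurtosis is
# the plain standardised fourth moment (3 for a normal). Percentiles use the
# default interpolation of stats::quantile (type 7).
first_order_from_values <- function(x, bin_width) {
  n <- length(x)
  m <- mean(x)
  cx <- x - m
  m2 <- mean(cx^2)
  skew <- if (m2 > 0) mean(cx^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean(cx^4) / m2^2 else 0
  q <- unname(stats::quantile(x, c(0.1, 0.25, 0.75, 0.9)))
  lev <- discretize_hu(x, bin_width)
  p <- tabulate(lev) / n
  p <- p[p > 0]
  c(firstorder.mean = m,
    firstorder.median = stats::median(x),
    firstorder.minimum = min(x),
    firstorder.maximum = max(x),
    firstorder.range = max(x) - min(x),
    firstorder.variance = m2,
    firstorder.skewness = skew,
    firstorder.kurtosis = kurt,
    firstorder.energy = sum(x^2),
    firstorder.rms = sqrt(mean(x^2)),
    firstorder.p10 = q[1],
    firstorder.p90 = q[4],
    firstorder.iqr = q[3] - q[2],
    firstorder.entropy = -sum(p * log2(p)))
}

#' First-order intensity features
#'
#' Computed strictly over in-mask voxels. Entropy uses the fixed-bin-width
#' discretisation from `disc`; everything else uses raw HU.
#'
#' @param voi a [node_voi()].
#' @param disc a [discretization_config()].
#' @return named numeric vector, names prefixed `firstorder.`.
#' @export
compute_first_order <- function(voi, disc = discretization_config()) {
  stopifnot(inherits(voi, "node_voi"), inherits(disc, "discretization_config"))
  x <- voi_values(voi)
  assert_that(length(x) > 0, "empty segmentation mask")
  first_order_from_values(x, disc$bin_width)
}
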