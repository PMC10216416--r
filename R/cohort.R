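#' Configuration for the synthetic CT lymph-node cohort
#'
#' The generator emulates the study population the pipeline is designed for:
#' ~100 patients carrying on average 27 (SD 14) thoracic lymph nodes each, with
#' about 20.3% of nodes PET-positive overall and strong patient-level
#' clustering of positivity. Positive nodes can differ from negative ones in
#' three controllable signal channels: size (mean radius shift in mm), mean
#' attenuation (HU shift) and spatial texture (the arrangement of a coarse
#' texture component: concentric core-rim in positive nodes versus random
#' blobs in negative ones). Setting all three effects to zero yields a null
#' cohort in which the label is independent of the images.
#'
#' @param n_patients number of patients (>= 1).
#' @param nodes_per_patient_mean,nodes_per_patient_sd parameters of the
#'   truncated-at-1 normal from which per-patient node counts are drawn.
#' @param target_prevalence expected overall fraction of PET-positive nodes.
#' @param prevalence_sd standard deviation of the per-patient positivity rate
#'   (a beta distribution with this dispersion drives patient clustering).
#' @param size_effect shift (mm) of the positive-node mean radius.
#' @param attenuation_effect shift (HU) of the positive-node mean intensity.
#' @param texture_effect dimensionless amplitude of the class-specific texture
#'   difference. Both classes mix short-range texture with a coarse component
#'   of variance weight `w = min(0.85, 0.4 * texture_effect)`; the coarse
#'   component is randomly blob-structured in negative nodes and organised as
#'   a concentric core-rim pattern (emulating central necrosis, random
#'   polarity) in positive nodes. Because weights, correlation scales and
#'   in-mask moments are matched, the class signal lives in the spatial
#'   arrangement: first-order statistics are blind to it by construction and
#'   translation-invariant co-occurrence summaries see little of it, while
#'   descriptors with large spatial context (the convolutional features)
#'   retain it. `texture_effect = 0` removes the coarse component from both
#'   classes.
#' @param native_spacing voxel spacing (mm) of the generated volumes.
#' @param noise_sd white-noise SD in HU added inside the node.
#' @param base_radius_mean,base_radius_sd negative-node mean-radius
#'   distribution (mm).
#' @param base_hu_mean,base_hu_sd negative-node mean attenuation distribution.
#' @param texture_amp amplitude (HU) of the unit-variance texture field, equal
#'   for both classes.
#' @param texture_sigma_mm short-range texture correlation length (mm).
#' @param texture_long_sigma_mm correlation length (mm) of the coarse blob
#'   component of negative nodes.
#' @param background_hu fill value outside the node (air, -1000 HU).
#' @param seed integer seed; the cohort is fully reproducible from it.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_patients,
                          nodes_per_patient_mean = 27,
                          nodes_per_patient_sd = 14,
                          target_prevalence = 0.203,
                          prevalence_sd = 0.15,
                          size_effect = 0.8,
                          attenuation_effect = 8,
                          texture_effect = 1,
                          native_spacing = c(0.7, 0.7, 2.0),
                          noise_sd = 10,
                          base_radius_mean = 6,
                          base_radius_sd = 1.2,
                          base_hu_mean = 35,
                          base_hu_sd = 8,
                          texture_amp = 15,
                          texture_sigma_mm = 1.2,
                          texture_long_sigma_mm = 4,
                          background_hu = -1000,
                          seed = 1L) {
  assert_that(is.numeric(n_patients) && n_patients >= 1, "n_patients must be >= 1")
  assert_that(target_prevalence > 0 && target_prevalence < 1,
              "target_prevalence must lie in (0, 1)")
  assert_that(size_effect >= 0 && attenuation_effect >= 0 && texture_effect >= 0,
              "effects must be non-negative")
  assert_that(all(native_spacing > 0), "spacing components must be positive")
  assert_that(nodes_per_patient_mean >= 1 && nodes_per_patient_sd >= 0,
              "invalid node-count distribution")
  cfg <- list(n_patients = as.integer(n_patients),
              nodes_per_patient_mean = nodes_per_patient_mean,
              nodes_per_patient_sd = nodes_per_patient_sd,
              target_prevalence = target_prevalence,
              prevalence_sd = prevalence_sd,
              size_effect = size_effect,
              attenuation_effect = attenuation_effect,
              texture_effect = texture_effect,
              native_spacing = as.numeric(native_spacing),
              noise_sd = noise_sd,
              base_radius_mean = base_radius_mean,
              base_radius_sd = base_radius_sd,
              base_hu_mean = base_hu_mean,
              base_hu_sd = base_hu_sd,
              texture_amp = texture_amp,
              texture_sigma_mm = texture_sigma_mm,
              texture_long_sigma_mm = texture_long_sigma_mm,
              background_hu = background_hu,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

# beta(a, b) with the requested mean and SD; dispersion is clamped to stay in
# the feasible region.
beta_params <- function(mean, sd) {
  v <- min(sd^2, 0.9 * mean * (1 - mean))
  s <- mean * (1 - mean) / v - 1
  s <- max(s, 1e-3)
  c(a = mean * s, b = (1 - mean) * s)
}

#' Render one synthetic lymph node
#'
#' The node is a discretised ellipsoid on an anisotropic grid. In-mask
#' intensities are `base_hu + texture_amp * T + e`, where `T` is a
#' unit-variance textured field and `e` is white noise with SD `noise_sd`.
#' `T` mixes a short-range Gaussian-filtered component (correlation length
#' `texture_sigma_mm`, variance weight `1 - texture_long_weight`) with a
#' coarse component of weight `texture_long_weight` whose spatial arrangement
#' is either random blobs (`"blob"`, correlation length
#' `texture_long_sigma_mm`) or a concentric core-rim profile (`"radial"`,
#' emulating central necrosis, with random polarity). Every component is
#' normalised over the in-mask voxels, so the in-mask mean and variance are
#' independent of the mixture. Outside the mask the volume is filled with a
#' fixed air-like constant.
#'
#' @param radii_mm ellipsoid semi-axes (mm); each must be at least twice the
#'   largest spacing component so the discretised mask is non-degenerate.
#' @param base_hu mean in-mask attenuation (HU).
#' @param texture_amp texture amplitude (HU).
#' @param spacing voxel spacing (mm).
#' @param seed integer seed for the texture and noise fields.
#' @param texture_sigma_mm short-range texture correlation length (mm);
#'   scalar or per-axis length 3.
#' @param texture_long_weight fraction of texture variance in the coarse
#'   component (0 = pure short-range texture).
#' @param texture_long_sigma_mm correlation length (mm) of the blob-structured
#'   coarse component.
#' @param texture_structure spatial arrangement of the coarse component:
#'   `"blob"` or `"radial"`.
#' @param noise_sd white-noise SD (HU).
#' @param background_hu fill value outside the mask.
#' @param margin_mm margin of background around the ellipsoid.
#' @return list with `image` (an [image_volume]) and binary `mask` array.
#' @export
render_node_volume <- function(radii_mm, base_hu, texture_amp, spacing, seed,
                               texture_sigma_mm = 1.2, texture_long_weight = 0,
                               texture_long_sigma_mm = 4,
                               texture_structure = c("blob", "radial"),
                               noise_sd = 0,
                               background_hu = -1000, margin_mm = 3) {
  texture_structure <- match.arg(texture_structure)
  radii_mm <- rep(as.numeric(radii_mm), length.out = 3)
  spacing <- rep(as.numeric(spacing), length.out = 3)
  if (any(radii_mm < 2 * max(spacing))) {
    stop(sprintf("degenerate geometry: radii (%.2f, %.2f, %.2f) mm below 2 x max spacing (%.2f mm)",
                 radii_mm[1], radii_mm[2], radii_mm[3], 2 * max(spacing)), call. = FALSE)
  }
  n <- pmax(3L, as.integer(ceiling(2 * (radii_mm + margin_mm) / spacing)))
  n <- n + 1L - n %% 2L  # odd grid so the ellipsoid centre sits on a voxel
  coords <- lapply(1:3, function(ax) (seq_len(n[ax]) - (n[ax] + 1) / 2) * spacing[ax])
  q <- outer(outer((coords[[1]] / radii_mm[1])^2,
                   (coords[[2]] / radii_mm[2])^2, "+"),
             (coords[[3]] / radii_mm[3])^2, "+")
  mask <- array(as.integer(q <= 1), dim = n)
  vox <- array(background_hu, dim = n)
  inside <- mask == 1L
  vals <- rep(base_hu, sum(inside))
  # components are normalised over the in-mask voxels so the marginal
  # in-mask mean/variance cannot carry class information
  unit_in_mask <- function(f) {
    v <- f[inside]
    s <- stats::sd(v)
    if (is.na(s) || s == 0) return(f * 0)
    (f - mean(v)) / s
  }
  smooth_field <- function(sigma_mm) {
    unit_in_mask(gaussian_smooth_3d(array(stats::rnorm(prod(n)), dim = n),
                                    sigma_mm / spacing))
  }
  with_seed(seed, {
    if (texture_amp != 0) {
      w <- min(max(texture_long_weight, 0), 1)
      field <- sqrt(1 - w) * smooth_field(texture_sigma_mm)
      if (w > 0) {
        coarse <- if (identical(texture_structure, "radial")) {
          # concentric core-rim profile over the ellipsoidal radius, with a
          # random sign (hypo- or hyperdense core)
          unit_in_mask(cos(pi * sqrt(pmin(q, 1)))) * sample(c(-1, 1), 1)
        } else {
          smooth_field(texture_long_sigma_mm)
        }
        field <- field + sqrt(w) * coarse
      }
      # rank-Gaussianise the in-mask field: every node's texture has exactly
      # the same marginal distribution, so first-order statistics are blind
      # to the texture channel by construction and only the spatial
      # arrangement carries class information
      v <- field[inside]
      vals <- vals + texture_amp *
        stats::qnorm((rank(v, ties.method = "first") - 0.5) / length(v))
    }
    if (noise_sd > 0) vals <- vals + stats::rnorm(sum(inside), sd = noise_sd)
  })
  vox[inside] <- vals
  list(image = image_volume(vox, spacing), mask = mask)
}

#' Generate a patient-clustered synthetic cohort
#'
#' Node counts per patient come from a truncated-at-1 normal; per-patient
#' positivity rates from a beta distribution with mean `target_prevalence` and
#' SD `prevalence_sd`; node labels are Bernoulli draws from the patient rate.
#' Positive nodes receive the configured size, attenuation and texture shifts.
#' Fully reproducible from `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return list of patient cases, each `list(patient_id, nodes)` where every
#'   node is `list(image, mask, label, node_id)`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  np <- config$n_patients
  seed <- config$seed
  counts <- with_seed(derive_seed(seed, "counts"), {
    pmax(1L, as.integer(round(stats::rnorm(np, config$nodes_per_patient_mean,
                                           config$nodes_per_patient_sd))))
  })
  bp <- beta_params(config$target_prevalence, config$prevalence_sd)
  rates <- with_seed(derive_seed(seed, "rates"),
                     stats::rbeta(np, bp["a"], bp["b"]))
  min_r <- 2 * max(config$native_spacing) + 0.2
  lapply(seq_len(np), function(i) {
    pid <- sprintf("P%04d", i)
    labels <- with_seed(derive_seed(seed, "labels", i),
                        stats::rbinom(counts[i], 1L, rates[i]))
    nodes <- lapply(seq_len(counts[i]), function(j) {
      lab <- labels[j]
      geo <- with_seed(derive_seed(seed, "geom", i, j), {
        r0 <- stats::rnorm(1, config$base_radius_mean + config$size_effect * lab,
                           config$base_radius_sd)
        radii <- pmax(r0 * exp(stats::rnorm(3, 0, 0.08)), min_r)
        hu <- stats::rnorm(1, config$base_hu_mean + config$attenuation_effect * lab,
                           config$base_hu_sd)
        list(radii = radii, hu = hu)
      })
      rendered <- render_node_volume(
        radii_mm = geo$radii, base_hu = geo$hu,
        texture_amp = config$texture_amp, spacing = config$native_spacing,
        seed = derive_seed(seed, "render", i, j),
        texture_sigma_mm = config$texture_sigma_mm,
        texture_long_weight = min(0.85, 0.4 * config$texture_effect),
        texture_long_sigma_mm = config$texture_long_sigma_mm,
        texture_structure = if (lab == 1) "radial" else "blob",
        noise_sd = config$noise_sd, background_hu = config$background_hu)
      list(image = rendered$image, mask = rendered$mask, label = lab,
           node_id = sprintf("%s_N%03d", pid, j))
    })
    list(patient_id = pid, nodes = nodes)
  })
}

#' Tabulate cohort labels
#'
#' @param cohort output of [generate_cohort()] or [read_cohort()].
#' @return data.frame with `node_id`, `patient_id`, `label`.
#' @export
cohort_labels <- function(cohort) {
  do.call(rbind, lapply(cohort, function(pc) {
    data.frame(node_id = vapply(pc$nodes, `[[`, "", "node_id"),
               patient_id = pc$patient_id,
               label = vapply(pc$nodes, function(nd) as.integer(nd$label), 0L),
               stringsAsFactors = FALSE)
  }))
}
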