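test_that("isotropic resampling follows the size rule and preserves constants", {
  set.seed(1)
  v <- image_volume(array(rnorm(50 * 50 * 20), c(50, 50, 20)), c(0.6, 0.6, 2.0))
  r <- resample_isotropic(v, 1)
  expect_equal(dim(r$voxels), c(30L, 30L, 40L))  # round(size * spacing / t)
  expect_equal(r$spacing, c(1, 1, 1))

  vi <- image_volume(array(rnorm(8 * 7 * 6), c(8, 7, 6)), c(1, 1, 1))
  expect_identical(resample_isotropic(vi, 1)$voxels, vi$voxels)

  vc <- image_volume(array(12.5, c(9, 9, 5)), c(0.5, 0.5, 1.5))
  expect_true(all(abs(resample_isotropic(vc, 1)$voxels - 12.5) < 1e-12))

  # idempotence: resampling an already-isotropic volume again is a no-op
  r2 <- resample_isotropic(r, 1)
  expect_lt(max(abs(r2$voxels - r$voxels)), 1e-6)

  expect_error(resample_isotropic(v, -1), "positive")
})

test_that("masks are resampled nearest-neighbour and stay binary", {
  m <- array(0L, c(10, 10, 4)); m[3:7, 3:7, 2:3] <- 1L
  mv <- image_volume(array(as.numeric(m), dim(m)), c(0.7, 0.7, 2))
  rm_ <- resample_isotropic(mv, 1, is_mask = TRUE)
  expect_true(all(rm_$voxels %in% c(0L, 1L)))
  expect_gt(sum(rm_$voxels), 0)
})

test_that("VOI extraction crops tightly and fills outside the mask", {
  a <- array(seq_len(6 * 6 * 6), c(6, 6, 6))
  v <- image_volume(a, c(1, 1, 1))
  m <- array(0L, c(6, 6, 6)); m[4, 2, 5] <- 1L
  voi <- extract_voi(v, m)
  expect_equal(dim(voi$image$voxels), c(1L, 1L, 1L))
  expect_equal(voi$image$voxels[1, 1, 1], a[4, 2, 5])

  m3 <- array(0L, c(6, 6, 6)); m3[3:6, 2:4, 1:2] <- 1L
  voi3 <- extract_voi(v, m3)
  expect_equal(dim(voi3$image$voxels), c(4L, 3L, 2L))

  # checkerboard mask with explicit fill
  m4 <- array(rep_len(c(0L, 1L), 6 * 6 * 6), c(6, 6, 6))
  voi4 <- extract_voi(v, m4, fill_value = 0)
  expect_true(all(voi4$image$voxels[voi4$mask == 0] == 0))
  expect_true(all(voi4$image$voxels[voi4$mask == 1] != 0))

  expect_error(extract_voi(v, array(0L, c(6, 6, 6))), "empty")
})

test_that("masking before vs after cropping commutes", {
  set.seed(42)
  a <- array(rnorm(10 * 10 * 8), c(10, 10, 8))
  m <- array(0L, c(10, 10, 8)); m[3:8, 2:6, 3:6] <- rbinom(6 * 5 * 4, 1, 0.6)
  m[5, 4, 4] <- 1L
  v <- image_volume(a, c(1, 1, 1))
  # mask first, then crop
  a_masked <- a; a_masked[m == 0] <- -160
  voi_a <- extract_voi(image_volume(a_masked, c(1, 1, 1)), m)
  # crop with fill
  voi_b <- extract_voi(v, m, fill_value = -160)
  expect_identical(voi_a$image$voxels, voi_b$image$voxels)
})

test_that("slice stacks have the configured shape and normalisation", {
  nd <- render_node_volume(c(8, 7, 6), 40, 10, c(1, 1, 1), seed = 3, noise_sd = 5)
  voi <- extract_voi(nd$image, nd$mask, fill_value = -160)
  st <- standardize_stack(voi, z_slices = 10, xy_size = c(32, 32),
                          window = c(-160, 240))
  expect_equal(dim(st), c(32L, 32L, 10L))
  expect_true(all(st >= 0 & st <= 1))

  # constant VOI at the window midpoint maps to 0.5 everywhere
  cv <- array_voi(array(40, c(6, 6, 6)))
  stc <- standardize_stack(cv, 10, c(16, 16), window = c(0, 80))
  expect_true(all(abs(stc - 0.5) < 1e-12))

  # a VOI already at target shape and inside the window is unchanged
  set.seed(8)
  a <- array(runif(16 * 16 * 10, -100, 200), c(16, 16, 10))
  sti <- standardize_stack(array_voi(a), 10, c(16, 16), window = c(-160, 240))
  expect_equal(as.numeric(sti) * 400 - 160, as.numeric(a), tolerance = 1e-9)
})

test_that("standardised stacks ignore where the node sits in the volume", {
  nd <- render_node_volume(c(6, 6, 6), 50, 10, c(1, 1, 1), seed = 12, noise_sd = 0)
  d <- dim(nd$image$voxels)
  big <- array(-1000, d + c(8, 6, 4))
  bigm <- array(0L, dim(big))
  for (off in list(c(0, 0, 0), c(8, 6, 4))) {
    big2 <- big; bigm2 <- bigm
    big2[off[1] + 1:d[1], off[2] + 1:d[2], off[3] + 1:d[3]] <- nd$image$voxels
    bigm2[off[1] + 1:d[1], off[2] + 1:d[2], off[3] + 1:d[3]] <- nd$mask
    voi <- extract_voi(image_volume(big2, c(1, 1, 1)), bigm2, fill_value = -160)
    st <- standardize_stack(voi, 10, c(16, 16))
    if (off[1] == 0) st0 <- st else expect_identical(st, st0)
  }
})
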