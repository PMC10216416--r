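# first-order, shape, and assembly

test_that("first-order statistics match direct formula evaluation", {
  fo <- compute_first_order(array_voi(c(0, 0, 2, 2)))
  expect_equal(fo[["firstorder.mean"]], 1)
  expect_equal(fo[["firstorder.variance"]], 1)  # population estimator
  expect_equal(fo[["firstorder.skewness"]], 0)
  expect_equal(fo[["firstorder.range"]], 2)

  fo2 <- compute_first_order(array_voi(c(1, 2, 3)))
  expect_equal(fo2[["firstorder.energy"]], 14)  # 1 + 4 + 9
  expect_equal(fo2[["firstorder.rms"]], sqrt(14 / 3))
  expect_equal(fo2[["firstorder.median"]], 2)

  const <- compute_first_order(array_voi(rep(40, 100)))
  expect_equal(const[["firstorder.mean"]], 40)
  expect_equal(const[["firstorder.variance"]], 0)
  expect_equal(const[["firstorder.range"]], 0)
  expect_equal(const[["firstorder.entropy"]], 0)

  # entropy of a 50/50 two-bin split is exactly 1 bit
  two <- compute_first_order(array_voi(c(rep(0, 8), rep(100, 8))),
                             discretization_config(25))
  expect_equal(two[["firstorder.entropy"]], 1)
})

test_that("first-order features only see in-mask voxels and ignore order", {
  set.seed(3)
  vals <- rnorm(60, 50, 12)
  a <- array(-1000, c(5, 4, 3)); m <- array(0L, c(5, 4, 3))
  m[seq_len(60) %% 2 == 1] <- 1L
  a[m == 1L] <- vals[seq_len(sum(m))]
  voi <- node_voi(image_volume(a, c(1, 1, 1)), m)
  fo <- compute_first_order(voi)
  expect_equal(fo[["firstorder.mean"]], mean(vals[seq_len(sum(m))]))

  perm <- sample(sum(m))
  a2 <- a; a2[m == 1L] <- vals[seq_len(sum(m))][perm]
  fo2 <- compute_first_order(node_voi(image_volume(a2, c(1, 1, 1)), m))
  expect_equal(fo2, fo, tolerance = 1e-12)
})

test_that("shape features agree with analytic solids", {
  sv <- compute_shape(array(1L, c(1, 1, 1)), c(1, 1, 1))
  expect_equal(sv[["shape.volume"]], 1)

  ball <- digital_ball(10, 1)
  sh <- compute_shape(ball, c(1, 1, 1))
  expect_lt(abs(sh[["shape.volume"]] - 4188.79) / 4188.79, 0.03)
  expect_gt(sh[["shape.sphericity"]], 0.95)
  expect_lt(sh[["shape.sphericity"]], 1.05)
  expect_equal(sh[["shape.elongation"]], 1, tolerance = 0.02)
  expect_equal(sh[["shape.max_diameter_3d"]], 20, tolerance = 0.05 * 20)

  # anisotropic spacing: volume is voxel count times voxel volume
  m <- array(1L, c(4, 5, 2))
  expect_equal(compute_shape(m, c(0.5, 0.5, 2))[["shape.volume"]], 40 * 0.5 * 0.5 * 2)
})

test_that("shape features are invariant to 90-degree rotation about z", {
  set.seed(11)
  m <- digital_ball(6, 1)
  m[2:5, 3:9, 4:7] <- 1L  # break symmetry
  rot <- aperm(m[, rev(seq_len(dim(m)[2])), , drop = FALSE], c(2, 1, 3))
  a <- compute_shape(m, c(1, 1, 1)); b <- compute_shape(rot, c(1, 1, 1))
  for (f in c("shape.volume", "shape.sphericity", "shape.max_diameter_3d")) {
    expect_lt(abs(a[[f]] - b[[f]]) / abs(a[[f]]), 0.01)
  }
})

test_that("assembled vectors concatenate stable blocks and subset cleanly", {
  nd <- render_node_volume(c(7, 6, 6), 45, 12, c(1, 1, 1), seed = 2, noise_sd = 6)
  voi <- extract_voi(nd$image, nd$mask)
  v <- assemble_handcrafted(voi)
  fo <- compute_first_order(voi); sh <- compute_shape(voi$mask, c(1, 1, 1))
  gl <- compute_glcm(voi)
  expect_equal(length(v), length(fo) + length(sh) + length(gl))
  expect_identical(names(v), c(names(fo), names(sh), names(gl)))

  sub <- feature_subset(v, c("firstorder", "shape"))
  expect_false(any(startsWith(names(sub), "glcm.")))
  expect_equal(length(sub), length(fo) + length(sh))

  expect_identical(assemble_handcrafted(voi), v)
})
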