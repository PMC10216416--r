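make_stack <- function(a) structure(a, class = "slice_stack")

test_that("backbones are deterministic and shape-correct", {
  cfg <- backbone_config(c(32, 64, 128), seed = 5)
  b1 <- build_backbone(cfg); b2 <- build_backbone(cfg)
  expect_identical(b1$stages, b2$stages)
  expect_equal(ncol(b1$stages[[2]]$W), 64)

  st <- make_stack(array(runif(16 * 16 * 3), c(16, 16, 3)))
  f2 <- forward_features(b1, st, depth_k = 2)
  expect_length(f2, 64)
  expect_identical(forward_features(b1, st, 2), f2)
  expect_error(forward_features(b1, st, 4), "depth_k")

  # dimensionality depends only on (config, depth), not content
  st2 <- make_stack(array(runif(16 * 16 * 3), c(16, 16, 3)))
  expect_length(forward_features(b1, st2, 2), 64)

  expect_error(backbone_config(c(8, 8)), "3 stages")
})

test_that("external weight files are honoured and validated", {
  cfg0 <- backbone_config(c(4, 8, 4), kernel_size = 3, seed = 1)
  zero <- lapply(seq_len(3), function(s) {
    c_in <- if (s == 1) 1L else c(4L, 8L, 4L)[s - 1]
    list(W = matrix(0, 9 * c_in, c(4L, 8L, 4L)[s]), b = numeric(c(4L, 8L, 4L)[s]))
  })
  wf <- withr::local_tempfile(fileext = ".rds")
  saveRDS(zero, wf)
  bb <- build_backbone(backbone_config(c(4, 8, 4), weight_init = "external-file",
                                       weights_file = wf))
  st <- make_stack(array(runif(12 * 12 * 2), c(12, 12, 2)))
  expect_true(all(forward_features(bb, st, 3) == 0))
  expect_true(all(unlist(deep_feature_maps(bb, st, 3)) == 0))

  zero[[2]]$W <- matrix(0, 3, 3)
  saveRDS(zero, wf)
  expect_error(build_backbone(backbone_config(c(4, 8, 4),
                                              weight_init = "external-file",
                                              weights_file = wf)),
               "malformed weight file")
})

test_that("average pooling matches the hand-computed oracle", {
  # stage 1: 1x1 identity convolution, stride 1 -> pooled feature is the
  # spatial mean per slice, averaged over slices
  ident <- list(list(W = matrix(1, 1, 1), b = 0),
                list(W = matrix(1, 1, 1), b = 0),
                list(W = matrix(1, 1, 1), b = 0))
  wf <- withr::local_tempfile(fileext = ".rds")
  saveRDS(ident, wf)
  bb <- build_backbone(backbone_config(c(1, 1, 1), kernel_size = 1, stride = 1,
                                       weight_init = "external-file",
                                       weights_file = wf, input_norm = "none"))
  a <- array(0, c(2, 2, 2))
  a[, , 1] <- matrix(c(0.1, 0.2, 0.3, 0.4), 2)
  a[, , 2] <- matrix(c(0.5, 0.6, 0.7, 0.8), 2)
  f <- forward_features(bb, make_stack(a), 1)
  expect_equal(unname(f), mean(c(mean(a[, , 1]), mean(a[, , 2]))))

  # un-pooled maps are consistent with pooling for a single-slice stack
  b2 <- build_backbone(backbone_config(c(8, 8, 8), seed = 9))
  s1 <- make_stack(array(runif(16 * 16), c(16, 16, 1)))
  maps <- deep_feature_maps(b2, s1, layer_index = 3, slice_index = 1)
  pooled <- forward_features(b2, s1, 3)
  expect_length(maps, 8)
  expect_equal(vapply(maps, mean, 0), unname(pooled), tolerance = 1e-12)
})

test_that("pooled features are robust to small in-plane translations", {
  bb <- build_backbone(backbone_config(seed = 5))
  nd <- render_node_volume(c(7, 7, 6), 50, 15, c(1, 1, 1), seed = 3, noise_sd = 8)
  voi <- extract_voi(nd$image, nd$mask, fill_value = -160)
  st <- standardize_stack(voi, 10, c(64, 64))
  f0 <- forward_features_all(bb, st)
  sh <- unclass(st) * 0
  sh[3:64, , ] <- unclass(st)[1:62, , ]
  fs <- forward_features_all(bb, make_stack(sh))
  rel <- sqrt(sum((fs - f0)^2)) / sqrt(sum(f0^2))
  expect_lt(rel, 0.10)
})
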