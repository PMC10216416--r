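# Transfer-learning style deep features: pooled activations from the first k
# stages of a small frozen 2D convolutional backbone applied to each node's
# standardised slice stack. Weights are never trained here; they are either
# seeded random (the default, which preserves texture separability) or loaded
# from an external file. Convolutions are evaluated as im2col + matrix
# multiplication so the heavy lifting runs in BLAS.

#' Backbone configuration
#'
#' @param stage_channels filter count per convolutional stage (>= 3 stages).
#' @param kernel_size square kernel side per stage (scalar or per stage).
#' @param stride stride per stage (scalar or per stage).
#' @param input_channels channels expected at the first stage; single-channel
#'   CT slices are replicated to this count.
#' @param weight_init `"seeded-random"` (He-scaled, reproducible from `seed`)
#'   or `"external-file"` (load from `weights_file`, an RDS list of per-stage
#'   `W` arrays `k x k x in x out` and bias vectors `b`).
#' @param weights_file path used when `weight_init = "external-file"`.
#' @param input_norm `"zscore"` (default) standardises each input stack to
#'   zero mean and unit variance before the first convolution, the usual
#'   input normalisation of pretrained classification networks; it makes the
#'   pooled features sensitive to spatial texture rather than to the mean
#'   intensity, so the deep features — like those of a pretrained backbone —
#'   carry no information about absolute attenuation or node size. `"none"`
#'   feeds the windowed `[0, 1]` stack as is.
#' @param seed integer seed for random initialisation.
#' @return a `backbone_config` list.
#' @export
backbone_config <- function(stage_channels = c(32, 64, 128, 256),
                            kernel_size = 3, stride = 2, input_channels = 1,
                            weight_init = c("seeded-random", "external-file"),
                            weights_file = NULL,
                            input_norm = c("zscore", "none"), seed = 0L) {
  weight_init <- match.arg(weight_init)
  input_norm <- match.arg(input_norm)
  assert_that(length(stage_channels) >= 3, "need at least 3 stages")
  assert_that(all(stage_channels > 0), "channel counts must be positive")
  structure(list(stage_channels = as.integer(stage_channels),
                 kernel_size = rep(as.integer(kernel_size),
                                   length.out = length(stage_channels)),
                 stride = rep(as.integer(stride),
                              length.out = length(stage_channels)),
                 input_channels = as.integer(input_channels),
                 weight_init = weight_init, weights_file = weights_file,
                 input_norm = input_norm, seed = as.integer(seed)),
            class = "backbone_config")
}

# weight matrix layout: (k*k*c_in) x c_out, rows ordered (ki, kj, channel)
he_weights <- function(k, c_in, c_out, seed) {
  with_seed(seed, matrix(stats::rnorm(k * k * c_in * c_out, sd = sqrt(2 / (k * k * c_in))),
                         nrow = k * k * c_in, ncol = c_out))
}

load_weight_stages <- function(path, config) {
  w <- tryCatch(readRDS(path), error = function(e) {
    stop(sprintf("malformed weight file '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  n_stages <- length(config$stage_channels)
  assert_that(is.list(w) && length(w) == n_stages,
              sprintf("malformed weight file: expected %d stages", n_stages))
  c_in <- config$input_channels
  lapply(seq_len(n_stages), function(s) {
    k <- config$kernel_size[s]; c_out <- config$stage_channels[s]
    W <- w[[s]]$W; b <- w[[s]]$b %||% numeric(c_out)
    if (is.array(W) && length(dim(W)) == 4) W <- matrix(W, nrow = k * k * c_in)
    assert_that(is.matrix(W) && nrow(W) == k * k * c_in && ncol(W) == c_out,
                sprintf("malformed weight file: stage %d has wrong shape", s))
    assert_that(length(b) == c_out, sprintf("malformed weight file: stage %d bias", s))
    c_in <<- c_out
    list(W = W, b = as.numeric(b), k = k, stride = config$stride[s])
  })
}

#' Build a frozen convolutional backbone
#'
#' @param config a [backbone_config()].
#' @return a `backbone` object (list of frozen stages).
#' @export
build_backbone <- function(config) {
  stopifnot(inherits(config, "backbone_config"))
  stages <- if (config$weight_init == "external-file") {
    assert_that(!is.null(config$weights_file), "weights_file required")
    load_weight_stages(config$weights_file, config)
  } else {
    c_in <- config$input_channels
    lapply(seq_along(config$stage_channels), function(s) {
      k <- config$kernel_size[s]; c_out <- config$stage_channels[s]
      st <- list(W = he_weights(k, c_in, c_out, derive_seed(config$seed, "stage", s)),
                 b = numeric(c_out), k = k, stride = config$stride[s])
      c_in <<- c_out
      st
    })
  }
  structure(list(stages = stages, config = config), class = "backbone")
}

#' @export
print.backbone <- function(x, ...) {
  cat(sprintf("<backbone> %d frozen stages, channels %s (%s init)\n",
              length(x$stages),
              paste(x$config$stage_channels, collapse = "/"),
              x$config$weight_init))
  invisible(x)
}

# im2col: (oh*ow) x (k*k*c) patch matrix, zero padding, column order (ki, kj, c)
im2col <- function(x, k, stride, pad) {
  d <- dim(x)
  hp <- d[1] + 2 * pad; wp <- d[2] + 2 * pad
  xp <- array(0, c(hp, wp, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  oh <- (hp - k) %/% stride + 1L
  ow <- (wp - k) %/% stride + 1L
  out <- matrix(0, oh * ow, k * k * d[3])
  ri <- (seq_len(oh) - 1L) * stride
  rj <- (seq_len(ow) - 1L) * stride
  for (ki in seq_len(k)) {
    for (kj in seq_len(k)) {
      block <- xp[ri + ki, rj + kj, , drop = FALSE]
      cols <- ((ki - 1L) * k + (kj - 1L)) * d[3] + seq_len(d[3])
      out[, cols] <- matrix(block, oh * ow, d[3])
    }
  }
  attr(out, "oshape") <- c(oh, ow)
  out
}

conv_stage <- function(x, stage) {
  pad <- (stage$k - 1L) %/% 2L
  cols <- im2col(x, stage$k, stage$stride, pad)
  z <- cols %*% stage$W
  z <- sweep(z, 2, stage$b, `+`)
  z[z < 0] <- 0  # ReLU
  os <- attr(cols, "oshape")
  array(z, c(os[1], os[2], ncol(stage$W)))
}

forward_slice <- function(backbone, slice, max_depth) {
  x <- array(rep(slice, backbone$config$input_channels),
             c(dim(slice), backbone$config$input_channels))
  acts <- vector("list", max_depth)
  for (s in seq_len(max_depth)) {
    x <- conv_stage(x, backbone$stages[[s]])
    acts[[s]] <- x
  }
  acts
}

normalize_input <- function(backbone, stack) {
  if ((backbone$config$input_norm %||% "none") != "zscore") return(stack)
  s <- stats::sd(stack)
  if (s == 0) return(stack * 0)
  (stack - mean(stack)) / s
}

# pooled activations (spatial mean, then mean over slices) at stages 1..max_depth
forward_pooled <- function(backbone, stack, max_depth) {
  stack <- normalize_input(backbone, stack)
  d <- dim(stack)
  pooled <- NULL
  for (z in seq_len(d[3])) {
    acts <- forward_slice(backbone, stack[, , z], max_depth)
    p <- lapply(acts, function(a) colMeans(matrix(a, ncol = dim(a)[3])))
    pooled <- if (is.null(pooled)) p else Map(`+`, pooled, p)
  }
  lapply(pooled, function(v) v / d[3])
}

#' Pooled deep features at depth k
#'
#' Each slice of the standardised stack is forwarded independently through the
#' first `depth_k` stages; stage-`depth_k` activations are average-pooled over
#' both spatial dimensions and then averaged over slices. The output length
#' equals the filter count of stage `depth_k`.
#'
#' @param backbone a [build_backbone()] result.
#' @param stack a `slice_stack` from [standardize_stack()].
#' @param depth_k final stage index (hyperparameter; default 3).
#' @return named numeric vector `deep.s<k>.c<j>`.
#' @export
forward_features <- function(backbone, stack, depth_k = 3) {
  n_stages <- length(backbone$stages)
  assert_that(depth_k >= 1 && depth_k <= n_stages,
              sprintf("depth_k must be in 1..%d", n_stages))
  v <- forward_pooled(backbone, unclass(stack), depth_k)[[depth_k]]
  names(v) <- sprintf("deep.s%d.c%d", depth_k, seq_along(v))
  v
}

#' Pooled deep features at every depth
#'
#' Single forward pass returning the concatenated pooled features of all
#' stages; the model layer later selects the `deep.s<k>.*` block matching its
#' `depth_k` hyperparameter.
#'
#' @inheritParams forward_features
#' @return named numeric vector covering all stages.
#' @export
forward_features_all <- function(backbone, stack) {
  pooled <- forward_pooled(backbone, unclass(stack), length(backbone$stages))
  unlist(lapply(seq_along(pooled), function(s) {
    v <- pooled[[s]]
    names(v) <- sprintf("deep.s%d.c%d", s, seq_along(v))
    v
  }))
}

#' Un-pooled activation maps of one stage
#'
#' Returns the stage-`layer_index` activation maps of one slice for
#' visualisation; channel order matches the pooled feature order.
#'
#' @inheritParams forward_features
#' @param layer_index stage to visualise (default 3).
#' @param slice_index which slice of the stack (default the middle one).
#' @return list of 2D matrices, one per channel.
#' @export
deep_feature_maps <- function(backbone, stack, layer_index = 3,
                              slice_index = NULL) {
  n_stages <- length(backbone$stages)
  assert_that(layer_index >= 1 && layer_index <= n_stages,
              sprintf("layer_index must be in 1..%d", n_stages))
  a <- normalize_input(backbone, unclass(stack))
  slice_index <- slice_index %||% ceiling(dim(a)[3] / 2)
  act <- forward_slice(backbone, a[, , slice_index], layer_index)[[layer_index]]
  lapply(seq_len(dim(act)[3]), function(ch) act[, , ch])
}
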