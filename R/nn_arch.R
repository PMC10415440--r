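# Water-fat separation network architectures.
#
# Both variants share a 4-stage convolutional encoder (each stage: two
# [conv3x3 -> ReLU -> batch norm] layers, then 2x2 max pooling) and a
# bottleneck conv block at 1/16 resolution. The multi-decoder variant
# ("mdwf") attaches three independent decoders to the bottleneck — a
# 2-channel water/fat magnitude decoder, a 1-channel R2* decoder and a
# 1-channel fieldmap decoder whose first upsampling is followed by a
# self-attention block. The comparator ("unet") uses one decoder with a
# 4-channel head. Decoders upsample by 2x2 transposed convolutions and
# concatenate the equal-shape encoder features (skip connections).

#' Network configuration
#'
#' Defaults reproduce the full-scale architecture: 192x192 inputs, encoder
#' filters 72/144/288/576 and an 1152-channel bottleneck, which sits at
#' 12x12 after the four pooling stages. Reduced configurations (e.g. 64x64
#' with filters 8/16/32/64) are used for desk-scale training.
#'
#' @param input_size Image side in pixels, divisible by 16.
#' @param n_echoes Number of echoes; the input has `2 * n_echoes` channels
#'   (real and imaginary parts per echo).
#' @param encoder_filters Four strictly increasing filter counts.
#' @param bottleneck_filters Bottleneck channels (default twice the last
#'   encoder filter count).
#' @param attention_in_fieldmap_decoder Apply self-attention after the first
#'   upsampling of the fieldmap decoder (mdwf variant only).
#' @param variant `"mdwf"` (multi-decoder) or `"unet"` (single decoder).
#' @return An object of class `network_config`.
#' @export
network_config <- function(input_size = 192L, n_echoes = 3L,
                           encoder_filters = c(72L, 144L, 288L, 576L),
                           bottleneck_filters = 2L * encoder_filters[4],
                           attention_in_fieldmap_decoder = TRUE,
                           variant = c("mdwf", "unet")) {
  variant <- match.arg(variant)
  input_size <- as.integer(input_size)
  if (is.na(input_size) || input_size < 16L || input_size %% 16L != 0L) {
    stop("input_size must be divisible by 16")
  }
  encoder_filters <- as.integer(encoder_filters)
  if (length(encoder_filters) != 4L || any(diff(encoder_filters) <= 0)) {
    stop("encoder_filters must be 4 strictly increasing integers")
  }
  bottleneck_filters <- as.integer(bottleneck_filters)
  if (is.na(bottleneck_filters) || bottleneck_filters < 1L) {
    stop("bottleneck_filters must be a positive integer")
  }
  structure(list(input_size = input_size, n_echoes = as.integer(n_echoes),
                 encoder_filters = encoder_filters,
                 bottleneck_filters = bottleneck_filters,
                 attention_in_fieldmap_decoder =
                   isTRUE(attention_in_fieldmap_decoder),
                 variant = variant),
            class = "network_config")
}

# conv block: two (conv3 -> relu -> bn) layers
conv_block <- function(g, input, filters) {
  x <- nn_conv(g, input, filters, kernel = 3L)
  x <- nn_relu(g, x)
  x <- nn_bn(g, x)
  x <- nn_conv(g, x, filters, kernel = 3L)
  x <- nn_relu(g, x)
  nn_bn(g, x)
}

build_decoder <- function(g, z, skips, filters, out_ch, act_spec,
                          attention = FALSE) {
  cur <- z
  for (i in 4:1) {
    cur <- nn_convT(g, cur, filters[i])
    if (attention && i == 4L) cur <- nn_attention(g, cur)
    cur <- nn_concat(g, cur, skips[[i]])
    cur <- conv_block(g, cur, filters[i])
  }
  head <- nn_conv(g, cur, out_ch, kernel = 1L)
  nn_chanact(g, head, act_spec)
}

#' Build a water-fat separation network
#'
#' Constructs the network graph with seeded He-uniform weight
#' initialization. `build_mdwf_net()` builds the multi-decoder variant;
#' `build_unet()` the single-decoder comparator with a 4-channel output
#' (water, fat, normalized R2*, normalized fieldmap). Output activations:
#' ReLU on the water/fat magnitudes (non-negative), sigmoid on normalized
#' R2* (in `[0, 1]`), linear on the normalized fieldmap (signed).
#'
#' @param config A [network_config].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `wf_net_arch`: the graph, the configuration,
#'   node ids of the bottleneck and the outputs, and the channel layout of
#'   the concatenated 4-channel prediction.
#' @export
build_mdwf_net <- function(config = network_config(), seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  if (config$variant != "mdwf") {
    config$variant <- "mdwf"
  }
  build_wf_net(config, seed)
}

#' @rdname build_mdwf_net
#' @export
build_unet <- function(config = network_config(variant = "unet"), seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  if (config$variant != "unet") {
    config$variant <- "unet"
  }
  build_wf_net(config, seed)
}

build_wf_net <- function(config, seed = 1L) {
  with_seed(seed, {
    g <- nn_graph()
    x <- nn_input(g, 2L * config$n_echoes)
    skips <- vector("list", 4L)
    cur <- x
    for (i in 1:4) {
      skips[[i]] <- conv_block(g, cur, config$encoder_filters[i])
      cur <- nn_pool(g, skips[[i]])
    }
    bottleneck <- conv_block(g, cur, config$bottleneck_filters)
    if (config$variant == "mdwf") {
      out_wf <- build_decoder(g, bottleneck, skips, config$encoder_filters,
                              2L, c("linear", "linear"))
      out_r2s <- build_decoder(g, bottleneck, skips, config$encoder_filters,
                               1L, "sigmoid")
      out_df <- build_decoder(g, bottleneck, skips, config$encoder_filters,
                              1L, "linear",
                              attention = config$attention_in_fieldmap_decoder)
      outputs <- c(waterfat = out_wf, r2star = out_r2s, fieldmap = out_df)
    } else {
      out_all <- build_decoder(g, bottleneck, skips, config$encoder_filters,
                               4L, c("linear", "linear", "sigmoid", "linear"))
      outputs <- c(all = out_all)
    }
    structure(list(graph = g, config = config, bottleneck = bottleneck,
                   outputs = outputs, seed = as.integer(seed)),
              class = "wf_net_arch")
  })
}

#' @export
print.wf_net_arch <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("%s water-fat network: input %dx%dx%d\n",
              toupper(cfg$variant), cfg$input_size, cfg$input_size,
              2L * cfg$n_echoes))
  cat(sprintf("  encoder filters %s, bottleneck %d @ %dx%d, %s parameters\n",
              paste(cfg$encoder_filters, collapse = "/"),
              cfg$bottleneck_filters, cfg$input_size %/% 16L,
              cfg$input_size %/% 16L,
              format(nn_param_count(x$graph), big.mark = ",")))
  invisible(x)
}

# forward a batch through an architecture; xb is (2E) x (H*W*N),
# channels-first. Returns list(pred = 4 x (H*W*N) matrix with rows
# [water, fat, r2s, df], fw = forward record, bottleneck shape/channels)
arch_forward <- function(arch, xb, N, training = TRUE) {
  cfg <- arch$config
  H <- cfg$input_size
  fw <- nn_forward(arch$graph, xb, H, H, N, training = training)
  if (cfg$variant == "mdwf") {
    pred <- rbind(fw$values[[arch$outputs[["waterfat"]]]],
                  fw$values[[arch$outputs[["r2star"]]]],
                  fw$values[[arch$outputs[["fieldmap"]]]])
  } else {
    pred <- fw$values[[arch$outputs[["all"]]]]
  }
  list(pred = pred, fw = fw,
       bottleneck_shape = fw$shapes[[arch$bottleneck]],
       bottleneck_channels = arch$graph$nodes[[arch$bottleneck]]$ch)
}

# backward from a 4-channel prediction gradient (4 x HWN)
arch_backward <- function(arch, fwrec, dpred) {
  if (arch$config$variant == "mdwf") {
    douts <- list()
    douts[[as.character(arch$outputs[["waterfat"]])]] <- dpred[1:2, , drop = FALSE]
    douts[[as.character(arch$outputs[["r2star"]])]] <- dpred[3, , drop = FALSE]
    douts[[as.character(arch$outputs[["fieldmap"]])]] <- dpred[4, , drop = FALSE]
  } else {
    douts <- stats::setNames(list(dpred), as.character(arch$outputs[["all"]]))
  }
  nn_backward(arch$graph, fwrec, douts)
}

#' Run a raw forward pass through a network
#'
#' Low-level inference entry point, mainly useful to inspect the
#' architecture (bottleneck shape, output layout). For map prediction from
#' an echo series use [predict_maps()].
#'
#' @param arch A `wf_net_arch` (or trained `wf_net`).
#' @param x Channels-first input matrix, `2 * n_echoes` rows and
#'   `input_size^2 * n_samples` columns.
#' @param n_samples Number of images in the batch.
#' @param training Use batch statistics (`TRUE`) or running statistics
#'   (`FALSE`) in the batch-normalization layers.
#' @return List with `pred` (a `4 x (H*W*N)` matrix ordered water, fat,
#'   normalized R2*, normalized fieldmap), `bottleneck_shape` and
#'   `bottleneck_channels`.
#' @export
network_forward <- function(arch, x, n_samples = 1L, training = FALSE) {
  if (inherits(arch, "wf_net")) arch <- arch$arch
  stopifnot(inherits(arch, "wf_net_arch"))
  out <- arch_forward(arch, x, as.integer(n_samples), training = training)
  out$fw <- NULL
  out
}

#' Number of trainable parameters of a network
#'
#' @param arch A `wf_net_arch` (or trained `wf_net`).
#' @return Integer count of trainable scalars.
#' @export
n_parameters <- function(arch) {
  if (inherits(arch, "wf_net")) arch <- arch$arch
  stopifnot(inherits(arch, "wf_net_arch"))
  nn_param_count(arch$graph)
}

#' Self-attention block over spatial positions
#'
#' The standard query-key-value spatial attention with 1x1 convolutions and
#' a learnable residual scale: every position attends to every other
#' position through a row-stochastic softmax weight matrix, and the output
#' is `x + gamma * attention(x)`. With `gamma = 0` (its initialization) the
#' block is the identity.
#'
#' @param features Numeric array `(H, W, C)`.
#' @param weights Optional list with `Wq, bq, Wk, bk, Wv, bv` (`C x C/8`
#'   query/key and `C x C` value projections); seeded He-uniform defaults
#'   are drawn when `NULL`.
#' @param gamma Residual scale (scalar).
#' @param seed Seed for the default weights.
#' @param return_weights If `TRUE`, also return the `(H*W) x (H*W)`
#'   attention matrix.
#' @return Array shaped like `features`, or a list with `output` and
#'   `attention` when `return_weights = TRUE`.
#' @export
self_attention_block <- function(features, weights = NULL, gamma = 0,
                                 seed = 1L, return_weights = FALSE) {
  stopifnot(is.array(features), length(dim(features)) == 3L)
  dm <- dim(features)
  C <- dm[3]
  chk <- max(1L, C %/% 8L)
  if (is.null(weights)) {
    weights <- with_seed(seed, list(
      Wq = he_uniform(chk, C, C), bq = numeric(chk),
      Wk = he_uniform(chk, C, C), bk = numeric(chk),
      Wv = he_uniform(C, C, C), bv = numeric(C)))
  }
  X <- t(matrix(features, dm[1] * dm[2], C))    # channels-first
  a <- attn_forward(X, dm[1] * dm[2], 1L, weights$Wq, weights$bq,
                    weights$Wk, weights$bk, weights$Wv, weights$bv,
                    gamma, 1 / sqrt(chk))
  out <- array(t(a$Y), dm)
  if (return_weights) list(output = out, attention = a$B[[1]]) else out
}
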