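# Backbone feature extractors. Contract: a 256 x 256 input yields a
# 16 x 16 x c feature grid (total stride 16), so the grayscale mask, the CAM
# and the feature maps all live on the same lattice.

#' Construct a backbone feature extractor
#'
#' Two backbones satisfy the 16 x 16-grid contract for 256 x 256 patches:
#'
#' * `"small_cnn"`: four conv + ReLU stages (a 5 x 5 stride-4 stem followed
#'   by three 3 x 3 stages at strides 2, 2, 1; channels 8, 16, 32, 64 by
#'   default), c = 64. Trains on a laptop CPU in minutes and is the default
#'   for the synthetic task.
#' * `"resnet18"`: the standard 18-layer residual network (7 x 7 stem,
#'   max-pool, four stages of two basic blocks), c = 512, with the last
#'   stage at stride 1 so that a 256 x 256 input ends at 16 x 16 rather
#'   than 8 x 8. Parameter count is unaffected by the stride change.
#'
#' @param name `"small_cnn"` or `"resnet18"`.
#' @param in_channels input channels (3 for RGB, 1 for the anomaly map; the
#'   1-channel stem is a fresh convolution of matching shape).
#' @param channels for `small_cnn`, the per-stage channel counts (length 4).
#' @return A `backbone`: list with `layers`, `out_channels`, `out_grid`
#'   (relative to 256 input), `name`.
#' @export
backbone <- function(name = c("small_cnn", "resnet18"), in_channels = 3,
                     channels = c(8, 16, 32, 64)) {
  name <- match.arg(name)
  layers <- switch(name,
    small_cnn = {
      stopifnot(length(channels) == 4)
      # stride-4 5x5 stem, then 3x3 stages: 256 -> 64 -> 32 -> 16 -> 16
      strides <- c(4, 2, 2, 1)
      ks <- c(5, 3, 3, 3)
      cin <- in_channels
      out <- list()
      for (i in 1:4) {
        out <- c(out, list(layer_conv(ks[i], cin, channels[i],
                                      stride = strides[i]), layer_relu()))
        cin <- channels[i]
      }
      out
    },
    resnet18 = {
      c(list(layer_conv(7, in_channels, 64, stride = 2, pad = 3, bias = FALSE),
             layer_bn(64), layer_relu(), layer_maxpool(3, 2, 1)),
        list(layer_resblock(64, 64), layer_resblock(64, 64),
             layer_resblock(64, 128, stride = 2), layer_resblock(128, 128),
             layer_resblock(128, 256, stride = 2), layer_resblock(256, 256),
             # final stage kept at stride 1: 16 x 16 grid for 256 x 256 input
             layer_resblock(256, 512, stride = 1), layer_resblock(512, 512)))
    })
  out_channels <- switch(name, small_cnn = channels[4], resnet18 = 512L)
  structure(list(name = name, layers = layers, in_channels = in_channels,
                 out_channels = out_channels, out_grid = c(16L, 16L)),
            class = "backbone")
}

backbone_forward <- function(bb, x, train = FALSE) {
  r <- nn_forward(bb$layers, x, train)
  bb$layers <- r$layers
  list(out = r$out, caches = r$caches, backbone = bb)
}

#' Count trainable parameters of a model configuration
#'
#' Builds the configured model and counts every trainable array element
#' exactly (convolution and linear weights and biases, batch-norm and
#' layer-norm scale/shift; running statistics are not trainable and are not
#' counted).
#'
#' For reference points: a standard ResNet18 backbone with a plain 2-class
#' linear head has 11,177,538 parameters (11.18M); the dual-ResNet18
#' two-branch classifier (1-channel stem on the map branch, LayerNorm + linear
#' fusion head) has 22,350,850 (22.35M).
#'
#' @param config a [pge_config()] (any backbone/branch combination), or a
#'   `backbone` object.
#' @param head for a bare `backbone`, the number of classes of a plain linear
#'   head to include (default `NULL`: backbone only).
#' @return list with `count` (exact integer) and `millions` (2 dp).
#' @export
count_parameters <- function(config, head = NULL) {
  if (inherits(config, "backbone")) {
    n <- nn_count_params(config$layers)
    if (!is.null(head))
      n <- n + nn_count_params(list(layer_linear(config$out_channels, head)))
  } else if (inherits(config, "pge_config")) {
    model <- pge_init(config, seed = 1)
    n <- pge_count_params(model)
  } else stop("expected a pge_config or backbone")
  list(count = as.integer(n), millions = round(n / 1e6, 2))
}
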