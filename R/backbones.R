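# Reference lightweight backbones, encoded layer-for-layer so that trainable
# parameter counts match the standard architectures exactly. Each builder
# returns a bcs_model with $features (ends at the last convolutional feature
# map) and $head (pooling + classifier), so attention blocks and alternative
# heads can be spliced in between.

BACKBONE_NAMES <- c("efficientnet_b0", "mobilenet_v3_large", "mobilenet_v2",
                    "mobilenet_v3_small", "squeezenet_1_1", "shufflenet_v2_x1_0")

make_divisible <- function(v, divisor = 8) {
  nv <- max(divisor, (floor(v + divisor / 2) %/% divisor) * divisor)
  if (nv < 0.9 * v) nv <- nv + divisor
  as.integer(nv)
}

conv_bn <- function(in_ch, out_ch, kernel, stride = 1, act = "relu",
                    depthwise = FALSE) {
  pad <- (kernel - 1L) %/% 2L
  ls <- list(layer_conv2d(in_ch, out_ch, kernel, stride, pad,
                          depthwise = depthwise, bias = FALSE),
             layer_batchnorm2d(out_ch))
  if (!identical(act, "none")) ls <- c(ls, list(layer_act(act)))
  ls
}

new_bcs_model <- function(name, features, head, feature_channels,
                          num_classes, input_size = 224L) {
  structure(list(name = name, features = features, head = head,
                 feature_channels = feature_channels,
                 num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size)),
            class = "bcs_model")
}

linear_head <- function(feature_channels, num_classes, dropout = 0.2,
                        pre = list()) {
  layer_sequential(c(
    list(layer_global_avgpool(), layer_flatten(), layer_dropout(dropout)),
    pre,
    list(layer_linear(feature_channels, num_classes))))
}

# ---- EfficientNet-B0 --------------------------------------------------------

mbconv <- function(in_ch, out_ch, kernel, stride, expand) {
  exp_ch <- in_ch * expand
  ls <- list()
  if (expand != 1) ls <- c(ls, conv_bn(in_ch, exp_ch, 1, act = "silu"))
  ls <- c(ls, conv_bn(exp_ch, exp_ch, kernel, stride, act = "silu", depthwise = TRUE))
  squeeze <- max(1L, in_ch %/% 4L)
  ls <- c(ls, list(layer_se_block(exp_ch, squeeze, act = "silu", gate = "sigmoid")))
  ls <- c(ls, conv_bn(exp_ch, out_ch, 1, act = "none"))
  if (stride == 1 && in_ch == out_ch) list(layer_residual(ls)) else ls
}

build_efficientnet_b0 <- function(num_classes) {
  cfg <- list( # expand, kernel, stride, out_ch, repeats
    c(1, 3, 1, 16, 1), c(6, 3, 2, 24, 2), c(6, 5, 2, 40, 2),
    c(6, 3, 2, 80, 3), c(6, 5, 1, 112, 3), c(6, 5, 2, 192, 4),
    c(6, 3, 1, 320, 1))
  ls <- conv_bn(3, 32, 3, 2, act = "silu")
  in_ch <- 32
  for (st in cfg) {
    for (r in seq_len(st[5])) {
      s <- if (r == 1) st[3] else 1
      ls <- c(ls, mbconv(in_ch, st[4], st[2], s, st[1]))
      in_ch <- st[4]
    }
  }
  ls <- c(ls, conv_bn(320, 1280, 1, act = "silu"))
  new_bcs_model("efficientnet_b0", layer_sequential(ls),
                linear_head(1280, num_classes), 1280, num_classes)
}

# ---- MobileNetV2 ------------------------------------------------------------

inverted_residual <- function(in_ch, out_ch, stride, expand) {
  exp_ch <- in_ch * expand
  ls <- list()
  if (expand != 1) ls <- c(ls, conv_bn(in_ch, exp_ch, 1, act = "relu6"))
  ls <- c(ls, conv_bn(exp_ch, exp_ch, 3, stride, act = "relu6", depthwise = TRUE))
  ls <- c(ls, conv_bn(exp_ch, out_ch, 1, act = "none"))
  if (stride == 1 && in_ch == out_ch) list(layer_residual(ls)) else ls
}

build_mobilenet_v2 <- function(num_classes) {
  cfg <- list( # expand, out_ch, repeats, stride
    c(1, 16, 1, 1), c(6, 24, 2, 2), c(6, 32, 3, 2), c(6, 64, 4, 2),
    c(6, 96, 3, 1), c(6, 160, 3, 2), c(6, 320, 1, 1))
  ls <- conv_bn(3, 32, 3, 2, act = "relu6")
  in_ch <- 32
  for (st in cfg) {
    for (r in seq_len(st[3])) {
      s <- if (r == 1) st[4] else 1
      ls <- c(ls, inverted_residual(in_ch, st[2], s, st[1]))
      in_ch <- st[2]
    }
  }
  ls <- c(ls, conv_bn(320, 1280, 1, act = "relu6"))
  new_bcs_model("mobilenet_v2", layer_sequential(ls),
                linear_head(1280, num_classes), 1280, num_classes)
}

# ---- MobileNetV3 ------------------------------------------------------------

v3_bneck <- function(in_ch, kernel, exp_ch, out_ch, use_se, act, stride) {
  ls <- list()
  if (exp_ch != in_ch) ls <- c(ls, conv_bn(in_ch, exp_ch, 1, act = act))
  ls <- c(ls, conv_bn(exp_ch, exp_ch, kernel, stride, act = act, depthwise = TRUE))
  if (use_se) {
    squeeze <- make_divisible(exp_ch / 4)
    ls <- c(ls, list(layer_se_block(exp_ch, squeeze, act = "relu", gate = "hardsigmoid")))
  }
  ls <- c(ls, conv_bn(exp_ch, out_ch, 1, act = "none"))
  if (stride == 1 && in_ch == out_ch) list(layer_residual(ls)) else ls
}

build_mobilenet_v3 <- function(num_classes, size = c("large", "small")) {
  size <- match.arg(size)
  if (size == "large") {
    cfg <- list( # kernel, exp, out, se, act, stride
      list(3, 16, 16, FALSE, "relu", 1),  list(3, 64, 24, FALSE, "relu", 2),
      list(3, 72, 24, FALSE, "relu", 1),  list(5, 72, 40, TRUE, "relu", 2),
      list(5, 120, 40, TRUE, "relu", 1),  list(5, 120, 40, TRUE, "relu", 1),
      list(3, 240, 80, FALSE, "hardswish", 2), list(3, 200, 80, FALSE, "hardswish", 1),
      list(3, 184, 80, FALSE, "hardswish", 1), list(3, 184, 80, FALSE, "hardswish", 1),
      list(3, 480, 112, TRUE, "hardswish", 1), list(3, 672, 112, TRUE, "hardswish", 1),
      list(5, 672, 160, TRUE, "hardswish", 2), list(5, 960, 160, TRUE, "hardswish", 1),
      list(5, 960, 160, TRUE, "hardswish", 1))
    last_conv <- 960L; hidden <- 1280L
  } else {
    cfg <- list(
      list(3, 16, 16, TRUE, "relu", 2),   list(3, 72, 24, FALSE, "relu", 2),
      list(3, 88, 24, FALSE, "relu", 1),  list(5, 96, 40, TRUE, "hardswish", 2),
      list(5, 240, 40, TRUE, "hardswish", 1), list(5, 240, 40, TRUE, "hardswish", 1),
      list(5, 120, 48, TRUE, "hardswish", 1), list(5, 144, 48, TRUE, "hardswish", 1),
      list(5, 288, 96, TRUE, "hardswish", 2), list(5, 576, 96, TRUE, "hardswish", 1),
      list(5, 576, 96, TRUE, "hardswish", 1))
    last_conv <- 576L; hidden <- 1024L
  }
  ls <- conv_bn(3, 16, 3, 2, act = "hardswish")
  in_ch <- 16
  for (st in cfg) {
    ls <- c(ls, v3_bneck(in_ch, st[[1]], st[[2]], st[[3]], st[[4]], st[[5]], st[[6]]))
    in_ch <- st[[3]]
  }
  ls <- c(ls, conv_bn(in_ch, last_conv, 1, act = "hardswish"))
  head <- layer_sequential(list(
    layer_global_avgpool(), layer_flatten(),
    layer_linear(last_conv, hidden), layer_act("hardswish"), layer_dropout(0.2),
    layer_linear(hidden, num_classes)))
  new_bcs_model(paste0("mobilenet_v3_", size), layer_sequential(ls), head,
                last_conv, num_classes)
}

# ---- SqueezeNet 1.1 ---------------------------------------------------------

fire <- function(in_ch, squeeze, e1, e3) {
  list(
    layer_conv2d(in_ch, squeeze, 1, bias = TRUE), layer_act("relu"),
    layer_concat(list(
      layer_sequential(list(layer_conv2d(squeeze, e1, 1, bias = TRUE),
                            layer_act("relu"))),
      layer_sequential(list(layer_conv2d(squeeze, e3, 3, padding = 1, bias = TRUE),
                            layer_act("relu"))))))
}

build_squeezenet_1_1 <- function(num_classes) {
  ls <- c(
    list(layer_conv2d(3, 64, 3, stride = 2, bias = TRUE), layer_act("relu"),
         layer_maxpool2d(3, 2)),
    fire(64, 16, 64, 64), fire(128, 16, 64, 64),
    list(layer_maxpool2d(3, 2)),
    fire(128, 32, 128, 128), fire(256, 32, 128, 128),
    list(layer_maxpool2d(3, 2)),
    fire(256, 48, 192, 192), fire(384, 48, 192, 192),
    fire(384, 64, 256, 256), fire(512, 64, 256, 256))
  # SqueezeNet classifies with a final 1x1 convolution instead of a linear layer.
  head <- layer_sequential(list(
    layer_dropout(0.5),
    layer_conv2d(512, num_classes, 1, bias = TRUE), layer_act("relu"),
    layer_global_avgpool(), layer_flatten()))
  new_bcs_model("squeezenet_1_1", layer_sequential(ls), head, 512, num_classes)
}

# ---- ShuffleNetV2 x1.0 ------------------------------------------------------

shuffle_stage <- function(in_ch, out_ch, repeats) {
  br <- out_ch %/% 2L
  units <- list(layer_shuffle_stride(
    branch1 = c(conv_bn(in_ch, in_ch, 3, 2, act = "none", depthwise = TRUE),
                conv_bn(in_ch, br, 1, act = "relu")),
    branch2 = c(conv_bn(in_ch, br, 1, act = "relu"),
                conv_bn(br, br, 3, 2, act = "none", depthwise = TRUE),
                conv_bn(br, br, 1, act = "relu"))))
  for (r in seq_len(repeats - 1)) {
    units <- c(units, list(layer_shuffle_basic(
      branch2 = c(conv_bn(br, br, 1, act = "relu"),
                  conv_bn(br, br, 3, 1, act = "none", depthwise = TRUE),
                  conv_bn(br, br, 1, act = "relu")))))
  }
  units
}

build_shufflenet_v2_x1_0 <- function(num_classes) {
  ls <- c(conv_bn(3, 24, 3, 2, act = "relu"),
          list(layer_maxpool2d(3, 2, padding = 1)),
          shuffle_stage(24, 116, 4),
          shuffle_stage(116, 232, 8),
          shuffle_stage(232, 464, 4),
          conv_bn(464, 1024, 1, act = "relu"))
  head <- layer_sequential(list(layer_global_avgpool(), layer_flatten(),
                                layer_linear(1024, num_classes)))
  new_bcs_model("shufflenet_v2_x1_0", layer_sequential(ls), head, 1024, num_classes)
}

# ---- public builder ---------------------------------------------------------

#' Build a reference lightweight backbone with a BCS classification head
#'
#' Constructs one of six standard mobile architectures with only the final
#' classification layer resized to `num_classes` outputs (for SqueezeNet the
#' final 1x1 convolution is resized); every other layer keeps its reference
#' configuration, so trainable-parameter counts match the standard models.
#'
#' @param name one of `"efficientnet_b0"`, `"mobilenet_v3_large"`,
#'   `"mobilenet_v2"`, `"mobilenet_v3_small"`, `"squeezenet_1_1"`,
#'   `"shufflenet_v2_x1_0"`.
#' @param num_classes number of output classes (default 5, the BCS levels).
#' @param seed integer seed for weight initialization.
#' @return a `bcs_model` object.
#' @examples
#' m <- build_backbone("squeezenet_1_1", num_classes = 5)
#' count_parameters(m)
#' @export
build_backbone <- function(name, num_classes = 5L, seed = 42L) {
  if (!name %in% BACKBONE_NAMES)
    stop("unknown backbone: ", name, " (expected one of ",
         paste(BACKBONE_NAMES, collapse = ", "), ")")
  if (num_classes < 2) stop("num_classes must be >= 2")
  set.seed(seed)
  switch(name,
    efficientnet_b0    = build_efficientnet_b0(num_classes),
    mobilenet_v3_large = build_mobilenet_v3(num_classes, "large"),
    mobilenet_v2       = build_mobilenet_v2(num_classes),
    mobilenet_v3_small = build_mobilenet_v3(num_classes, "small"),
    squeezenet_1_1     = build_squeezenet_1_1(num_classes),
    shufflenet_v2_x1_0 = build_shufflenet_v2_x1_0(num_classes))
}
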