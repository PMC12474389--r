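# Composite model assembly: backbone + optional SE / spatial attention on the
# final feature map + linear or convolutional (YOLO-style) classification
# head. The eight ablation presets A1-A8 are named configurations.

#' Build the convolutional (YOLO-style) classification head
#'
#' A light depthwise-separable stack replacing the fully connected
#' classifier: 1x1 pointwise convolution to 512 channels, 3x3 depthwise
#' convolution, 1x1 pointwise expansion to 1280, each followed by batch
#' normalization and SiLU; then global average pooling and a linear layer to
#' the class logits. Softmax is applied at inference only.
#'
#' @param in_channels channels of the incoming feature map.
#' @param num_classes number of classes.
#' @return a sequential head layer.
#' @export
build_yolo_head <- function(in_channels, num_classes) {
  if (in_channels < num_classes)
    stop("in_channels must be at least num_classes")
  layer_sequential(c(
    conv_bn(in_channels, 512, 1, act = "silu"),
    conv_bn(512, 512, 3, act = "silu", depthwise = TRUE),
    conv_bn(512, 1280, 1, act = "silu"),
    list(layer_global_avgpool(), layer_flatten(),
         layer_linear(1280, num_classes))))
}

#' Model configuration
#'
#' Describes one member of the model family: a backbone, attention flags, a
#' head kind and a loss name. The eight ablation presets map onto these
#' fields (see [ablation_config()]).
#'
#' @param backbone backbone id, see [build_backbone()].
#' @param use_se add a squeeze-and-excitation block (reduction 16, with
#'   biases) on the final feature map.
#' @param use_spatial add a 7x7 spatial attention block after the SE block
#'   (when both are present), before global pooling.
#' @param head `"linear"` or `"yolo"`.
#' @param loss `"cross_entropy"` or `"label_smoothing"` (training-time only;
#'   does not change the architecture).
#' @param num_classes class count (default 5).
#' @return a `model_config` object.
#' @export
model_config <- function(backbone = "efficientnet_b0", use_se = FALSE,
                         use_spatial = FALSE, head = c("linear", "yolo"),
                         loss = c("cross_entropy", "label_smoothing"),
                         num_classes = 5L) {
  head <- match.arg(head)
  loss <- match.arg(loss)
  if (!backbone %in% BACKBONE_NAMES) stop("unknown backbone: ", backbone)
  if (num_classes < 2) stop("num_classes must be >= 2")
  structure(list(backbone = backbone, use_se = isTRUE(use_se),
                 use_spatial = isTRUE(use_spatial), head = head, loss = loss,
                 num_classes = as.integer(num_classes)),
            class = "model_config")
}

#' Ablation presets A1-A8
#'
#' A1 is the bare EfficientNet-B0 with linear head and cross entropy; A2 adds
#' SE attention; A3 adds spatial attention; A4 swaps in the label-smoothing
#' loss; A5 swaps in the convolutional head; A6 combines both attentions;
#' A7 is A6 with label smoothing; A8 combines SE, spatial, label smoothing
#' and the convolutional head.
#'
#' @param id `"A1"` ... `"A8"`.
#' @param backbone backbone id (default EfficientNet-B0 as in the ablation).
#' @param num_classes class count.
#' @return a [model_config()] object.
#' @export
ablation_config <- function(id, backbone = "efficientnet_b0", num_classes = 5L) {
  presets <- list(
    A1 = list(se = FALSE, sp = FALSE, head = "linear", loss = "cross_entropy"),
    A2 = list(se = TRUE,  sp = FALSE, head = "linear", loss = "cross_entropy"),
    A3 = list(se = FALSE, sp = TRUE,  head = "linear", loss = "cross_entropy"),
    A4 = list(se = FALSE, sp = FALSE, head = "linear", loss = "label_smoothing"),
    A5 = list(se = FALSE, sp = FALSE, head = "yolo",   loss = "cross_entropy"),
    A6 = list(se = TRUE,  sp = TRUE,  head = "linear", loss = "cross_entropy"),
    A7 = list(se = TRUE,  sp = TRUE,  head = "linear", loss = "label_smoothing"),
    A8 = list(se = TRUE,  sp = TRUE,  head = "yolo",   loss = "label_smoothing"))
  if (!id %in% names(presets)) stop("unknown ablation id: ", id)
  p <- presets[[id]]
  model_config(backbone, use_se = p$se, use_spatial = p$sp, head = p$head,
               loss = p$loss, num_classes = num_classes)
}

#' Assemble a composite model from a configuration
#'
#' Splices the optional attention blocks between the backbone's final feature
#' map and the classification head: backbone features, then SE (reduction 16,
#' with biases), then spatial attention, then the linear or convolutional
#' head.
#'
#' @param config a [model_config()] or an ablation id string.
#' @param seed integer seed for weight initialization.
#' @return a `bcs_model`.
#' @export
build_composite <- function(config, seed = 42L) {
  if (is.character(config)) config <- ablation_config(config)
  stopifnot(inherits(config, "model_config"))
  model <- build_backbone(config$backbone, config$num_classes, seed = seed)
  fc <- model$feature_channels
  extras <- list()
  if (config$use_se) {
    if (fc %% 16 != 0) stop("SE reduction 16 does not divide ", fc, " channels")
    extras <- c(extras, list(layer_se_block(fc, fc %/% 16L,
                                            act = "relu", gate = "sigmoid")))
  }
  if (config$use_spatial) extras <- c(extras, list(layer_spatial_block(7L)))
  if (length(extras))
    model$features <- layer_sequential(c(model$features$layers, extras))
  if (config$head == "yolo")
    model$head <- build_yolo_head(fc, config$num_classes)
  model$name <- paste0(config$backbone,
                       if (config$use_se) "+se" else "",
                       if (config$use_spatial) "+spatial" else "",
                       if (config$head == "yolo") "+yolo_head" else "")
  model$config <- config
  model
}
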