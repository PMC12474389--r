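# Grad-CAM: gradient-weighted class activation maps over a convolutional
# feature map, upsampled to the input and min-max normalized.

#' Grad-CAM heatmap
#'
#' Channel weights are the spatially averaged gradients of the target-class
#' logit with respect to the chosen feature map; the raw map is the ReLU of
#' the weighted channel sum, bilinearly upsampled to the input size and
#' min-max normalized to `[0, 1]` (an identically zero raw map stays all
#' zeros).
#'
#' @param model a `bcs_model` or `bcs_fit`.
#' @param input network input, array `(H, W, 3)` (preprocessed pixels).
#' @param target_class 0-based class whose logit is explained; default the
#'   predicted class.
#' @param layer_id index of the feature-map layer within the model's feature
#'   stack; default the last one (the final convolutional feature map before
#'   pooling).
#' @return a `bcs_heatmap`: `heatmap` (input-sized, in `[0, 1]`), `raw`
#'   (feature-map resolution, pre-normalization), `target_class`,
#'   `channel_weights`.
#' @export
grad_cam <- function(model, input, target_class = NULL, layer_id = NULL) {
  if (inherits(model, "bcs_fit")) model <- model$model
  d <- dim(input)
  if (length(d) != 3) stop("input must be a single (H, W, 3) image")
  x <- array(input, c(d, 1))
  nlay <- length(model$features$layers)
  if (is.null(layer_id)) layer_id <- nlay
  if (!is.numeric(layer_id) || layer_id < 1 || layer_id > nlay)
    stop("unknown layer: ", layer_id, " (model has ", nlay, " feature layers)")

  pre <- layer_sequential(model$features$layers[seq_len(layer_id)])
  post_layers <- if (layer_id < nlay)
    model$features$layers[(layer_id + 1):nlay] else list()
  post <- layer_sequential(c(post_layers, model$head$layers))

  rp <- layer_forward(pre, x)
  fmap <- rp$out                                   # (h, w, C, 1)
  rq <- layer_forward(post, fmap)
  logits <- rq$out
  if (is.null(target_class)) target_class <- which.max(logits[1, ]) - 1L
  if (target_class < 0 || target_class > model$num_classes - 1)
    stop("target_class out of range")
  dlog <- matrix(0, 1, model$num_classes)
  dlog[1, target_class + 1] <- 1
  dfmap <- layer_backward(post, rq$cache, dlog)$dx  # d logit / d feature map

  fd <- dim(fmap)
  w <- colMeans(matrix(dfmap, fd[1] * fd[2], fd[3]))  # spatial mean per channel
  raw <- matrix(matrix(fmap, fd[1] * fd[2], fd[3]) %*% w, fd[1], fd[2])
  raw <- pmax(raw, 0)
  up <- bilinear_resize(raw, d[1], d[2])
  hm <- if (max(up) > 0) (up - min(up)) / (max(up) - min(up)) else up * 0
  structure(list(heatmap = hm, raw = raw, target_class = target_class,
                 channel_weights = w), class = "bcs_heatmap")
}

# Blue -> red diverging colormap on [0, 1].
heat_colormap <- function(v) {
  r <- pmin(pmax(1.5 * v - 0.25, 0), 1)
  g <- pmax(1 - abs(2 * v - 1), 0) * 0.8
  b <- pmin(pmax(1.25 - 1.5 * v, 0), 1)
  list(r = r, g = g, b = b)
}

#' Overlay a heatmap on an image
#'
#' Blends a blue-to-red colormapped heatmap over the image:
#' `alpha = 0` returns the image, `alpha = 1` the pure colormap.
#'
#' @param heatmap a `bcs_heatmap` or an `(H, W)` matrix in `[0, 1]`.
#' @param image RGB array `(H, W, 3)` in `[0, 1]`.
#' @param alpha blend weight of the colormap.
#' @return RGB array `(H, W, 3)`.
#' @export
overlay <- function(heatmap, image, alpha = 0.5) {
  if (inherits(heatmap, "bcs_heatmap")) heatmap <- heatmap$heatmap
  d <- dim(image)
  if (length(d) != 3 || !all(dim(heatmap) == d[1:2]))
    stop("heatmap and image sizes do not match")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  cm <- heat_colormap(heatmap)
  out <- image
  out[, , 1] <- (1 - alpha) * image[, , 1] + alpha * cm$r
  out[, , 2] <- (1 - alpha) * image[, , 2] + alpha * cm$g
  out[, , 3] <- (1 - alpha) * image[, , 3] + alpha * cm$b
  out
}

#' Heatmap mass inside a box
#'
#' Sum of normalized heatmap values inside a 0-based half-open box, used to
#' quantify whether attention concentrates on the tail region.
#'
#' @param heatmap `(H, W)` matrix or `bcs_heatmap`.
#' @param bbox `c(x0, y0, x1, y1)` in heatmap coordinates.
#' @return scalar mass.
#' @export
heatmap_mass <- function(heatmap, bbox) {
  if (inherits(heatmap, "bcs_heatmap")) heatmap <- heatmap$heatmap
  bbox <- as.numeric(bbox)
  sum(crop_tail(heatmap, bbox))
}
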