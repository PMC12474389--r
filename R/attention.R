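# User-facing attention operations on raw feature maps. Feature maps here
# follow the field's C x H x W convention; internally the layer kernel uses
# (H, W, C, N) and these wrappers convert.

chw_to_internal <- function(f) {
  d <- dim(f)
  if (length(d) != 3) stop("feature map must be a 3-d array (C, H, W)")
  x <- aperm(f, c(2, 3, 1))
  dim(x) <- c(d[2], d[3], d[1], 1)
  x
}

internal_to_chw <- function(x) {
  d <- dim(x)
  aperm(array(x, d[1:3]), c(3, 1, 2))
}

#' Squeeze-and-excitation parameters
#'
#' Two projections with biases: `w1` maps the C channel descriptors to `C/r`
#' and `w2` maps back to C. ReLU between, sigmoid gate after.
#'
#' @param channels channel count C of the feature map.
#' @param reduction bottleneck ratio r (must divide C; default 16).
#' @param w1,b1,w2,b2 optional explicit weights (`w1`: `C/r x C`,
#'   `w2`: `C x C/r`); random initialization when omitted.
#' @return an `se_params` object.
#' @export
se_params <- function(channels, reduction = 16L, w1 = NULL, b1 = NULL,
                      w2 = NULL, b2 = NULL) {
  if (channels %% reduction != 0)
    stop("reduction must divide the channel count")
  sq <- channels %/% reduction
  lay <- layer_se_block(channels, sq, act = "relu", gate = "sigmoid")
  if (!is.null(w1)) lay$params$w1 <- array(w1, c(sq, channels))
  if (!is.null(b1)) lay$params$b1 <- b1
  if (!is.null(w2)) lay$params$w2 <- array(w2, c(channels, sq))
  if (!is.null(b2)) lay$params$b2 <- b2
  structure(list(layer = lay, channels = channels, reduction = reduction),
            class = "se_params")
}

#' Apply squeeze-and-excitation channel attention
#'
#' Per-channel global averages are squeezed through the bottleneck; the
#' sigmoid gate in (0,1)^C rescales each channel of the input.
#'
#' @param f feature map, array `(C, H, W)`.
#' @param p an [se_params()] object.
#' @return gated feature map, same shape.
#' @export
se_forward <- function(f, p) {
  stopifnot(inherits(p, "se_params"))
  if (dim(f)[1] != p$channels)
    stop("feature map has ", dim(f)[1], " channels, parameters expect ", p$channels)
  internal_to_chw(layer_forward(p$layer, chw_to_internal(f))$out)
}

#' Spatial attention parameters
#'
#' A single 7x7 convolution (with bias) over the 2-channel concatenation of
#' the channel-wise mean and max maps, followed by a sigmoid.
#'
#' @param kernel spatial kernel size (default 7).
#' @param w,b optional explicit kernel (`kernel x kernel x 2 x 1`) and bias.
#' @return a `spatial_params` object.
#' @export
spatial_params <- function(kernel = 7L, w = NULL, b = NULL) {
  lay <- layer_spatial_block(kernel)
  if (!is.null(w)) lay$params$w <- array(w, c(kernel, kernel, 2, 1))
  if (!is.null(b)) lay$params$b <- b
  structure(list(layer = lay, kernel = kernel), class = "spatial_params")
}

#' Apply spatial attention
#'
#' The channel-wise mean map and max map are concatenated, convolved with the
#' 7x7 kernel (padding preserves H x W) and squashed through a sigmoid; the
#' resulting mask in (0,1)^(H x W) multiplies every channel.
#'
#' @param f feature map, array `(C, H, W)`.
#' @param p a [spatial_params()] object.
#' @return gated feature map, same shape.
#' @export
spatial_forward <- function(f, p) {
  stopifnot(inherits(p, "spatial_params"))
  internal_to_chw(layer_forward(p$layer, chw_to_internal(f))$out)
}
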