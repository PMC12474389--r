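# Model profiling: trainable parameters, serialized size, approximate FLOPs,
# and measured latency.

#' Count trainable parameters
#'
#' Counts weights and biases of convolutional, linear, normalization and
#' attention layers. Normalization running statistics and other buffers are
#' excluded.
#' @param model a `bcs_model` or a single layer object.
#' @return integer count.
#' @export
count_parameters <- function(model) {
  if (inherits(model, "bcs_model"))
    return(n_params_layer(model$features) + n_params_layer(model$head))
  n_params_layer(model)
}

#' Serialized model size in MiB
#'
#' Float32 storage convention: `trainable parameters * 4 bytes / 2^20`,
#' rounded to 2 decimals.
#' @param model a `bcs_model` or layer, or a raw parameter count.
#' @export
model_size_mib <- function(model) {
  n <- if (is.numeric(model)) model else count_parameters(model)
  round(n * 4 / 2^20, 2)
}

#' Approximate multiply-accumulate count
#'
#' Sums `H_out * W_out * K_h * K_w * C_in/groups * C_out` over convolutions
#' and `in * out` over linear layers at the stated input size. The figure is
#' informational: published FLOP numbers depend on the counting tool's
#' convention.
#' @param model a `bcs_model`.
#' @param input_size spatial input size (default the model's own).
#' @return numeric MAC count.
#' @export
count_flops <- function(model, input_size = model$input_size) {
  shp <- c(input_size, input_size, 3)
  rf <- layer_shape_flops(model$features, shp)
  rh <- layer_shape_flops(model$head, rf$shape)
  rf$flops + rh$flops
}

#' Measure per-sample forward latency
#'
#' Median wall time of a batch-1 forward pass over `n_repeats` runs after
#' `n_warmup` discarded warmups. Hardware-dependent and informational only.
#' @param model a `bcs_model`.
#' @param input_size spatial input size.
#' @param n_repeats,n_warmup timing repetitions and warmups.
#' @return milliseconds per sample.
#' @export
latency_profile <- function(model, input_size = model$input_size,
                            n_repeats = 5L, n_warmup = 1L) {
  x <- array(0, c(input_size, input_size, 3, 1))
  for (i in seq_len(n_warmup)) model_forward(model, x)
  times <- vapply(seq_len(n_repeats), function(i) {
    t0 <- proc.time()[["elapsed"]]
    model_forward(model, x)
    (proc.time()[["elapsed"]] - t0) * 1000
  }, numeric(1))
  stats::median(times)
}

#' Profile a model
#'
#' @param model a `bcs_model`.
#' @param input_size spatial input size for FLOP counting (and latency).
#' @param latency measure forward latency too (slower).
#' @return a `data.frame` with one row: trainable parameter count, parameters
#'   in millions (2 decimals), approximate MFLOPs, serialized size in MiB and
#'   (optionally) per-sample latency in ms.
#' @export
profile_model <- function(model, input_size = model$input_size, latency = FALSE) {
  n <- count_parameters(model)
  data.frame(
    model = model$name,
    trainable_params = n,
    params_millions = round(n / 1e6, 2),
    flops_millions = round(count_flops(model, input_size) / 1e6, 2),
    size_mib = model_size_mib(n),
    latency_ms = if (latency) latency_profile(model, input_size) else NA_real_,
    stringsAsFactors = FALSE)
}
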