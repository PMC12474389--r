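# bcs_model methods: forward pass, prediction, printing.

#' Run a model forward
#'
#' @param model a `bcs_model`.
#' @param x input batch, array with dim `(H, W, 3, N)` of preprocessed pixels,
#'   or a single image `(H, W, 3)`.
#' @param train logical; use batch statistics in normalization layers and
#'   record caches for backpropagation.
#' @return list with `logits` (`N x num_classes` matrix), the (possibly
#'   updated) `model`, and forward `caches` when `train = TRUE`.
#' @export
model_forward <- function(model, x, train = FALSE) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  rf <- layer_forward(model$features, x, train = train)
  model$features <- rf$layer %||% model$features
  rh <- layer_forward(model$head, rf$out, train = train)
  model$head <- rh$layer %||% model$head
  list(logits = rh$out, model = model,
       caches = list(features = rf$cache, head = rh$cache))
}

#' Softmax over rows of a logit matrix
#' @param logits numeric matrix (N x K) or vector.
#' @return matrix of probabilities with rows summing to one.
#' @export
softmax <- function(logits) {
  if (is.null(dim(logits))) logits <- matrix(logits, 1)
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Predict BCS classes or probabilities
#'
#' @param object a `bcs_model`.
#' @param x preprocessed input array `(H, W, 3, N)` or `(H, W, 3)`.
#' @param type `"class"` for 0-based class indices, `"prob"` for softmax
#'   probabilities, `"score"` for BCS values.
#' @param ... unused.
#' @export
predict.bcs_model <- function(object, x, type = c("class", "prob", "score"), ...) {
  type <- match.arg(type)
  p <- softmax(model_forward(object, x, train = FALSE)$logits)
  if (type == "prob") return(p)
  idx <- max.col(p, ties.method = "first") - 1L
  if (type == "class") idx else bcs_levels()[idx + 1L]
}

#' @export
print.bcs_model <- function(x, ...) {
  cat("<bcs_model> ", x$name, "\n", sep = "")
  cat("  classes:    ", x$num_classes, "\n", sep = "")
  cat("  input size: ", x$input_size, "x", x$input_size, "\n", sep = "")
  cat("  parameters: ", format(count_parameters(x), big.mark = ","),
      " (", sprintf("%.2f", count_parameters(x) / 1e6), " M, ",
      sprintf("%.2f", model_size_mib(x)), " MiB)\n", sep = "")
  invisible(x)
}

#' The five BCS class values
#'
#' Ordinal body-condition scores from lean to fat, 0.25 apart. Class index
#' `i` (0-based) maps to `bcs_levels()[i + 1]`.
#' @return numeric vector `c(3.25, 3.50, 3.75, 4.00, 4.25)`.
#' @export
bcs_levels <- function() c(3.25, 3.50, 3.75, 4.00, 4.25)
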