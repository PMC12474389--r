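# Training: Adam optimization with early stopping, grid search over training
# configurations, and teacher-student distillation. Training is a pure
# function of (initial weights, config, data): a single seed drives batch
# shuffling, and every numerical step is deterministic.

#' Build a small reference CNN
#'
#' A compact three-block convolutional classifier (conv-relu-pool x2,
#' conv-relu, global average pool, linear) used for desk-scale experiments on
#' the synthetic corpus, where the full backbones would be needlessly large.
#'
#' @param num_classes class count.
#' @param input_size square input size (default 32).
#' @param channels widths of the three convolution blocks.
#' @param seed weight initialization seed.
#' @param batchnorm normalize each convolution's output with batch
#'   normalization. Recommended for harder inputs (for example full scenes,
#'   where the informative tail region is a small fraction of the image):
#'   it makes optimization much less sensitive to the initialization.
#' @param extra_pool add a third max-pooling stage, halving the final
#'   feature map once more. Useful at larger input sizes.
#' @return a `bcs_model`.
#' @export
build_small_cnn <- function(num_classes = 5L, input_size = 32L,
                            channels = c(8L, 16L, 32L), seed = 42L,
                            batchnorm = FALSE, extra_pool = FALSE) {
  set.seed(seed)
  block <- function(i, o) {
    if (batchnorm)
      list(layer_conv2d(i, o, 3, padding = 1, bias = FALSE),
           layer_batchnorm2d(o), layer_act("relu"))
    else
      list(layer_conv2d(i, o, 3, padding = 1), layer_act("relu"))
  }
  ls <- c(block(3, channels[1]), list(layer_maxpool2d(2)),
          block(channels[1], channels[2]), list(layer_maxpool2d(2)),
          block(channels[2], channels[3]))
  if (extra_pool) ls <- c(ls, list(layer_maxpool2d(2)))
  head <- layer_sequential(list(layer_global_avgpool(), layer_flatten(),
                                layer_linear(channels[3], num_classes)))
  new_bcs_model("small_cnn", layer_sequential(ls), head, channels[3],
                num_classes, input_size)
}

#' Training configuration
#'
#' @param learning_rate Adam step size (> 0; exactly 0 is allowed and makes
#'   training a no-op, useful as a control).
#' @param batch_size minibatch size (>= 1).
#' @param max_epochs maximum epochs.
#' @param early_stop_patience epochs without improvement before stopping.
#' @param min_delta required improvement of validation loss; an improvement
#'   of exactly `min_delta` counts as no improvement.
#' @param seed shuffling seed.
#' @param loss `"cross_entropy"` or `"label_smoothing"`.
#' @param epsilon label-smoothing coefficient.
#' @param optimizer only `"adam"` is provided.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 32L,
                         max_epochs = 20L, early_stop_patience = 10L,
                         min_delta = 1e-4, seed = 42L,
                         loss = c("cross_entropy", "label_smoothing"),
                         epsilon = 0.1, optimizer = "adam") {
  loss <- match.arg(loss)
  if (learning_rate < 0) stop("learning_rate must be >= 0")
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (early_stop_patience < 1) stop("early_stop_patience must be >= 1")
  if (!identical(optimizer, "adam")) stop("unsupported optimizer: ", optimizer)
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 min_delta = min_delta, seed = as.integer(seed), loss = loss,
                 epsilon = epsilon, optimizer = optimizer),
            class = "train_config")
}

#' Early-stopping state update
#'
#' @param state `NULL` to initialize, else the state returned by the previous
#'   call.
#' @param val_loss current validation loss.
#' @param patience consecutive non-improving updates tolerated.
#' @param min_delta improvement must exceed this to count.
#' @return list with the updated `state` and `stop_flag`.
#' @export
early_stop_update <- function(state, val_loss, patience, min_delta = 0) {
  if (patience < 1) stop("patience must be >= 1")
  if (is.null(state)) state <- list(best = Inf, wait = 0L)
  if (state$best - val_loss > min_delta) {
    state$best <- val_loss
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
  }
  list(state = state, stop_flag = state$wait >= patience)
}

# ---- internals --------------------------------------------------------------

model_params_tree <- function(model)
  list(features = params_tree(model$features), head = params_tree(model$head))

model_set_params <- function(model, tree) {
  model$features <- set_params_tree(model$features, tree$features)
  model$head <- set_params_tree(model$head, tree$head)
  model
}

unflatten_like <- function(template, flat) {
  i <- 0
  rec <- function(x) {
    if (is.list(x)) return(lapply(x, rec))
    i <<- i + 1
    v <- flat[[i]]
    if (!is.null(dim(x))) dim(v) <- dim(x) else v <- as.vector(v)
    v
  }
  rec(template)
}

model_backward <- function(model, caches, dlogits) {
  rh <- layer_backward(model$head, caches$head, dlogits)
  rf <- layer_backward(model$features, caches$features, rh$dx)
  list(grads = list(features = rf$grads, head = rh$grads), dx = rf$dx)
}

batched_logits <- function(model, x, chunk = 64L) {
  n <- dim(x)[4]
  out <- NULL
  for (at in seq(1, n, by = chunk)) {
    idx <- at:min(n, at + chunk - 1)
    lg <- model_forward(model, x[, , , idx, drop = FALSE])$logits
    out <- rbind(out, lg)
  }
  out
}

eval_loss_acc <- function(model, data, loss, epsilon) {
  lg <- batched_logits(model, data$x)
  la <- loss_and_grad(lg, data$y, loss, epsilon)
  pred <- max.col(lg, ties.method = "first") - 1L
  list(loss = la$value, acc = mean(pred == data$y))
}

check_dataset <- function(data, name) {
  if (is.null(data$x) || is.null(data$y) || length(data$y) == 0 ||
      dim(data$x)[4] != length(data$y))
    stop(name, " dataset is empty or malformed")
}

#' Train a model with Adam
#'
#' Minimizes the configured loss, tracks per-epoch training loss, validation
#' loss and validation accuracy, applies early stopping on the validation
#' loss, and restores the weights of the best validation epoch.
#'
#' @param model a `bcs_model` (initial weights).
#' @param train_data,val_data lists with `x` (`H x W x 3 x N` array) and `y`
#'   (0-based integer classes).
#' @param cfg a [train_config()].
#' @param teacher optional trained teacher `bcs_model`; when given together
#'   with `dspec` the distillation objective is minimized.
#' @param dspec a [distill_spec()] (only with `teacher`).
#' @return list of class `bcs_fit`: `model` (best weights), `history`
#'   (data.frame epoch/train_loss/val_loss/val_acc), `best_epoch`,
#'   `stopped_epoch`.
#' @export
train_model <- function(model, train_data, val_data, cfg = train_config(),
                        teacher = NULL, dspec = NULL) {
  check_dataset(train_data, "train"); check_dataset(val_data, "validation")
  stopifnot(inherits(cfg, "train_config"))
  if (!is.null(teacher) && teacher$num_classes != model$num_classes)
    stop("teacher and student class counts differ")
  n <- length(train_data$y)
  set.seed(cfg$seed)

  tree <- model_params_tree(model)
  flat <- flatten_arrays(tree)
  m1 <- lapply(flat, function(a) a * 0)
  m2 <- m1
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0

  hist_tl <- hist_vl <- hist_va <- numeric(0)
  es_state <- NULL
  best <- list(loss = Inf, epoch = 0L, tree = tree)
  stopped <- cfg$max_epochs

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0
    for (at in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[at:min(n, at + cfg$batch_size - 1)]
      xb <- train_data$x[, , , idx, drop = FALSE]
      yb <- train_data$y[idx]
      fw <- model_forward(model, xb, train = TRUE)
      model <- fw$model
      la <- if (is.null(teacher)) {
        loss_and_grad(fw$logits, yb, cfg$loss, cfg$epsilon)
      } else {
        tl <- model_forward(teacher, xb)$logits
        distill_loss_and_grad(fw$logits, tl, yb, dspec)
      }
      if (!is.finite(la$value))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      ep_loss <- ep_loss + la$value; nb <- nb + 1
      if (cfg$learning_rate > 0) {
        bw <- model_backward(model, fw$caches, la$grad)
        gflat <- flatten_arrays(bw$grads)
        t <- t + 1
        for (j in seq_along(flat)) {
          g <- gflat[[j]]
          m1[[j]] <- b1 * m1[[j]] + (1 - b1) * g
          m2[[j]] <- b2 * m2[[j]] + (1 - b2) * g^2
          flat[[j]] <- flat[[j]] - cfg$learning_rate *
            (m1[[j]] / (1 - b1^t)) / (sqrt(m2[[j]] / (1 - b2^t)) + eps)
        }
        model <- model_set_params(model, unflatten_like(tree, flat))
      }
    }
    vm <- eval_loss_acc(model, val_data,
                        if (is.null(teacher)) cfg$loss else "cross_entropy",
                        cfg$epsilon)
    hist_tl <- c(hist_tl, ep_loss / nb)
    hist_vl <- c(hist_vl, vm$loss)
    hist_va <- c(hist_va, vm$acc)
    if (vm$loss < best$loss) {
      best <- list(loss = vm$loss, epoch = epoch,
                   tree = model_params_tree(model))
    }
    es <- early_stop_update(es_state, vm$loss, cfg$early_stop_patience, cfg$min_delta)
    es_state <- es$state
    if (es$stop_flag) { stopped <- epoch; break }
    stopped <- epoch
  }
  model <- model_set_params(model, best$tree)
  structure(list(model = model,
                 history = data.frame(epoch = seq_along(hist_tl),
                                      train_loss = hist_tl, val_loss = hist_vl,
                                      val_acc = hist_va),
                 best_epoch = best$epoch, stopped_epoch = stopped),
            class = "bcs_fit")
}

#' @export
print.bcs_fit <- function(x, ...) {
  h <- x$history
  cat("<bcs_fit> ", x$model$name, ": ", nrow(h), " epochs (best ",
      x$best_epoch, ")\n", sep = "")
  cat(sprintf("  best val loss %.4f, val accuracy %.3f\n",
              min(h$val_loss), h$val_acc[x$best_epoch]))
  invisible(x)
}

#' Grid search over training configurations
#'
#' Trains one model per configuration and selects the one with the highest
#' validation accuracy (at its best epoch); ties go to the earlier
#' configuration in the grid.
#'
#' @param configs list of [train_config()] objects.
#' @param train_data,val_data datasets as in [train_model()].
#' @param model_builder function(cfg) returning a fresh initial `bcs_model`.
#' @return list with `best_config`, `best_fit`, and `results` (data.frame of
#'   per-config validation accuracy).
#' @export
grid_search <- function(configs, train_data, val_data,
                        model_builder = function(cfg) build_small_cnn(seed = cfg$seed)) {
  if (length(configs) == 0) stop("empty configuration grid")
  fits <- vector("list", length(configs))
  accs <- numeric(length(configs))
  for (i in seq_along(configs)) {
    fits[[i]] <- train_model(model_builder(configs[[i]]), train_data, val_data,
                             configs[[i]])
    accs[i] <- fits[[i]]$history$val_acc[fits[[i]]$best_epoch]
  }
  best <- which.max(accs)  # first maximum wins ties
  list(best_config = configs[[best]], best_fit = fits[[best]],
       results = data.frame(config = seq_along(configs), val_acc = accs))
}

#' Distill a teacher into a smaller student
#'
#' Trains the student against the frozen teacher with the
#' temperature-softened distillation objective and returns the
#' best-validation student.
#'
#' @param teacher trained teacher `bcs_model`.
#' @param student a `bcs_model` or a [model_config()] to build one from.
#' @param train_data,val_data datasets as in [train_model()].
#' @param dspec a [distill_spec()].
#' @param cfg a [train_config()].
#' @return a `bcs_fit` for the student.
#' @export
distill <- function(teacher, student, train_data, val_data,
                    dspec = distill_spec(), cfg = train_config()) {
  if (inherits(student, "model_config")) student <- build_composite(student, seed = cfg$seed)
  stopifnot(inherits(student, "bcs_model"), inherits(dspec, "distill_spec"))
  if (student$num_classes != teacher$num_classes)
    stop("teacher and student class counts differ")
  train_model(student, train_data, val_data, cfg, teacher = teacher, dspec = dspec)
}
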