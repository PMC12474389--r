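# Training mechanics: no-op control, determinism, early stopping, grid
# search, best-weight restoration, distillation plumbing.

test_that("zero learning rate leaves weights bit-identical", {
  co <- tiny_corpus()
  ds <- split_subsets(co)
  m0 <- build_small_cnn(input_size = 16, seed = 1)
  fit <- train_model(m0, ds$train, ds$val,
                     train_config(learning_rate = 0, max_epochs = 3, seed = 1))
  expect_identical(bcsnet:::model_params_tree(fit$model),
                   bcsnet:::model_params_tree(m0))
  expect_lt(diff(range(fit$history$train_loss)), 1e-12)
})

test_that("training is a pure function of config and seed", {
  co <- tiny_corpus()
  ds <- split_subsets(co)
  cfg <- fast_cfg()
  f1 <- train_model(build_small_cnn(input_size = 16, seed = 3), ds$train, ds$val, cfg)
  f2 <- train_model(build_small_cnn(input_size = 16, seed = 3), ds$train, ds$val, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(bcsnet:::model_params_tree(f1$model),
                   bcsnet:::model_params_tree(f2$model))
})

test_that("the reported best epoch attains the minimum validation loss", {
  co <- tiny_corpus()
  ds <- split_subsets(co)
  fit <- train_model(build_small_cnn(input_size = 16, seed = 4), ds$train,
                     ds$val, fast_cfg(max_epochs = 4))
  expect_equal(fit$history$val_loss[fit$best_epoch], min(fit$history$val_loss))
  expect_lte(fit$stopped_epoch, 4)
})

test_that("early stopping counts non-improvements as defined", {
  # strictly decreasing: never stops
  st <- NULL
  for (l in c(5, 4, 3, 2, 1)) {
    r <- early_stop_update(st, l, patience = 2, min_delta = 0.1)
    st <- r$state
    expect_false(r$stop_flag)
  }
  # constant losses, patience 3: stops on the 4th call
  st <- NULL; flags <- logical(0)
  for (i in 1:4) {
    r <- early_stop_update(st, 1, patience = 3, min_delta = 0)
    st <- r$state
    flags <- c(flags, r$stop_flag)
  }
  expect_identical(flags, c(FALSE, FALSE, FALSE, TRUE))
  # an improvement of exactly min_delta does not count
  st <- early_stop_update(NULL, 1.0, patience = 1, min_delta = 0.1)$state
  expect_true(early_stop_update(st, 0.9, patience = 1, min_delta = 0.1)$stop_flag)
  expect_error(early_stop_update(NULL, 1, patience = 0), "patience")
})

test_that("grid search picks the learning configuration over the no-op", {
  co <- tiny_corpus()
  ds <- split_subsets(co)
  grid <- list(fast_cfg(), train_config(learning_rate = 0, max_epochs = 3, seed = 42))
  gs <- grid_search(grid, ds$train, ds$val,
                    model_builder = function(cfg) build_small_cnn(input_size = 16,
                                                                  seed = cfg$seed))
  expect_identical(gs$best_config, grid[[1]])
  expect_equal(nrow(gs$results), 2)
  # tie between identical configs goes to the first
  gs2 <- grid_search(list(fast_cfg(), fast_cfg()), ds$train, ds$val,
                     model_builder = function(cfg) build_small_cnn(input_size = 16,
                                                                   seed = cfg$seed))
  expect_identical(gs2$best_config, fast_cfg())
  expect_equal(gs2$results$val_acc[1], gs2$results$val_acc[2])
  expect_error(grid_search(list(), ds$train, ds$val), "empty")
})

test_that("datasets and configs are validated", {
  co <- tiny_corpus()
  ds <- split_subsets(co)
  m <- build_small_cnn(input_size = 16)
  expect_error(train_model(m, list(x = NULL, y = integer(0)), ds$val, fast_cfg()),
               "empty or malformed")
  expect_error(train_config(batch_size = 0), "batch_size")
  expect_error(train_config(learning_rate = -1), "learning_rate")
  expect_error(train_config(optimizer = "sgd"), "unsupported optimizer")
})

test_that("distillation trains a student against a frozen teacher", {
  co <- tiny_corpus()
  ds <- split_subsets(co)
  teacher <- train_model(build_small_cnn(input_size = 16, seed = 2), ds$train,
                         ds$val, fast_cfg())$model
  student <- build_small_cnn(input_size = 16, channels = c(4L, 8L, 8L), seed = 2)
  expect_lt(count_parameters(student), count_parameters(teacher))
  fit <- distill(teacher, student, ds$train, ds$val,
                 distill_spec(T = 2, alpha = 0.7), fast_cfg())
  expect_s3_class(fit, "bcs_fit")
  expect_true(all(is.finite(fit$history$train_loss)))
  # teacher as its own student with alpha = 1: soft loss starts at zero
  z <- bcsnet:::batched_logits(teacher, ds$val$x)
  expect_equal(bcsnet:::distill_loss_and_grad(z, z, ds$val$y,
                                              distill_spec(alpha = 1))$value, 0)
  expect_true(all(abs(bcsnet:::distill_loss_and_grad(z, z, ds$val$y,
                                                     distill_spec(alpha = 1))$grad) < 1e-12))
  bad <- build_small_cnn(num_classes = 3, input_size = 16)
  expect_error(distill(teacher, bad, ds$train, ds$val), "class counts differ")
})

test_that("the default distillation student is the published architecture", {
  cfg <- model_config("mobilenet_v2", num_classes = 5)
  student <- build_composite(cfg)
  expect_equal(count_parameters(student), 2230277)
  expect_equal(round(count_parameters(student) / 1e6, 2), 2.23)
})
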