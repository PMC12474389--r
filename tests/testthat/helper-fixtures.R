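# Shared fixtures, built lazily and cached for the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Small cropped-tail corpus for fast training tests.
tiny_corpus <- function() cached("tiny", function() {
  generate_corpus(synthetic_spec(n_per_class = 6, seed = 5), input_size = 16)
})

split_subsets <- function(corpus, seed = 11) {
  sp <- split_dataset(length(corpus$y), seed = seed)
  sub <- function(i) list(x = corpus$x[, , , i + 1, drop = FALSE], y = corpus$y[i + 1])
  list(train = sub(sp$train), val = sub(sp$val), test = sub(sp$test))
}

fast_cfg <- function(max_epochs = 3) {
  train_config(learning_rate = 1e-2, batch_size = 16, max_epochs = max_epochs,
               seed = 42)
}

# One-hot helper.
onehot <- function(i, k) { y <- numeric(k); y[i] <- 1; y }

expect_scalar_equal <- function(object, expected, tol = 1e-6) {
  expect_equal(unname(object), expected, tolerance = tol)
}
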