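# Loss functions: closed forms forced by the definitions, hand-computed
# cases, and algebraic properties on random inputs.

test_that("label smoothing produces the expected soft targets", {
  sp <- smoothing_spec(0.1, 5)
  expect_equal(smooth_labels(onehot(3, 5), sp),
               c(0.02, 0.02, 0.92, 0.02, 0.02))
  expect_equal(smooth_labels(onehot(1, 5), smoothing_spec(0, 5)), onehot(1, 5))
  expect_equal(smooth_labels(onehot(1, 5), smoothing_spec(1, 5)), rep(0.2, 5))
  expect_equal(sum(smooth_labels(onehot(2, 5), sp)), 1)
  expect_error(smooth_labels(c(0.5, 0.5), smoothing_spec(K = 2)), "one-hot")
  expect_error(smoothing_spec(1.2), "epsilon")
})

test_that("closed-form loss values hold", {
  u <- rep(0.2, 5)
  y <- onehot(2, 5)
  expect_equal(label_smoothing_loss(u, y, smoothing_spec(0.1, 5)), log(5))
  expect_equal(cross_entropy(u, y), log(5))
  expect_equal(cross_entropy(onehot(2, 5), y), 0)
  expect_equal(cross_entropy(c(0.5, 0.3, 0.2), onehot(1, 3)), log(2))
  expect_equal(label_smoothing_loss(onehot(2, 5), y, smoothing_spec(0, 5)), 0)
  # p = ytilde at eps = 0.1: loss equals the entropy of ytilde
  yt <- smooth_labels(y, smoothing_spec(0.1, 5))
  expect_equal(label_smoothing_loss(yt, y, smoothing_spec(0.1, 5)),
               -sum(yt * log(yt)))
  expect_equal(label_smoothing_loss(yt, y, smoothing_spec(0.1, 5)), 0.38967,
               tolerance = 1e-5)
  expect_error(cross_entropy(c(0.5, 0.6), c(1, 0)), "summing to 1")
  expect_error(label_smoothing_loss(rep(0.25, 4), onehot(1, 5)), "equal length")
})

test_that("the smoothed loss obeys the Gibbs inequality", {
  set.seed(7)
  sp <- smoothing_spec(0.1, 5)
  y <- onehot(4, 5)
  yt <- smooth_labels(y, sp)
  h <- -sum(yt * log(yt))
  for (i in 1:25) {
    p <- stats::rgamma(5, 1); p <- p / sum(p)
    expect_gte(label_smoothing_loss(p, y, sp), h)
  }
  expect_equal(label_smoothing_loss(yt, y, sp), h)
})

test_that("zero smoothing reduces to cross entropy on random inputs", {
  set.seed(8)
  for (i in 1:20) {
    k <- sample(2:8, 1)
    p <- stats::rgamma(k, 1); p <- p / sum(p)
    y <- onehot(sample(k, 1), k)
    expect_equal(label_smoothing_loss(p, y, smoothing_spec(0, k)),
                 cross_entropy(p, y))
  }
})

test_that("losses are permutation-equivariant", {
  set.seed(9)
  p <- stats::rgamma(5, 1); p <- p / sum(p)
  y <- onehot(2, 5)
  for (i in 1:10) {
    pi <- sample(5)
    expect_equal(cross_entropy(p[pi], y[pi]), cross_entropy(p, y))
    expect_equal(label_smoothing_loss(p[pi], y[pi], smoothing_spec(0.1, 5)),
                 label_smoothing_loss(p, y, smoothing_spec(0.1, 5)))
  }
})

test_that("distillation loss behaves at its boundary settings", {
  y <- onehot(1, 5)
  z <- c(0.3, -1, 2, 0.1, 0)
  # identical logits, alpha = 1: KL of identical distributions
  expect_equal(distillation_loss(z, z, y, distill_spec(T = 4, alpha = 1)), 0)
  # alpha = 0 reduces exactly to cross entropy of the student softmax
  expect_equal(distillation_loss(z, rnorm(5), y, distill_spec(T = 2, alpha = 0)),
               cross_entropy(exp(z) / sum(exp(z)), y))
  expect_error(distillation_loss(z, z[1:3], y), "equal length")
  expect_error(distill_spec(T = 0), "T must be")
})

test_that("hand-computed KL case: student uniform, teacher (0.25, 0.75)", {
  v <- distillation_loss(c(0, 0), c(0, log(3)), onehot(1, 2),
                         distill_spec(T = 1, alpha = 1))
  expect_equal(v, 0.25 * log(0.5) + 0.75 * log(1.5), tolerance = 1e-12)
  expect_equal(v, 0.13081, tolerance = 1e-4)
})

test_that("distillation equals its alpha-weighted decomposition and is continuous in T", {
  set.seed(10)
  y <- onehot(3, 5)
  s <- rnorm(5); t <- rnorm(5)
  for (i in 1:10) {
    a <- runif(1); Tt <- runif(1, 0.5, 8)
    soft <- distillation_loss(s, t, y, distill_spec(T = Tt, alpha = 1))
    hard <- distillation_loss(s, t, y, distill_spec(T = Tt, alpha = 0))
    expect_equal(distillation_loss(s, t, y, distill_spec(T = Tt, alpha = a)),
                 a * soft + (1 - a) * hard)
    eps <- 1e-6
    expect_equal(distillation_loss(s, t, y, distill_spec(T = Tt + eps, alpha = 0.7)),
                 distillation_loss(s, t, y, distill_spec(T = Tt, alpha = 0.7)),
                 tolerance = 1e-4)
  }
})
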