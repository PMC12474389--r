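# Evaluation metrics: confusion matrices, macro averaging, tolerance
# accuracy, and a brute-force per-sample oracle.

test_that("confusion matrix counts actual rows x predicted columns", {
  y <- c(0, 1, 2, 3, 4, 0, 1)
  cm <- confusion_matrix(y, y, 5)
  expect_equal(unname(diag(cm)), c(2, 2, 1, 1, 1))
  expect_equal(sum(cm), length(y))
  cm1 <- confusion_matrix(1, 3, 5)
  expect_equal(cm1[2, 4], 1L)
  expect_equal(sum(cm1), 1)
  expect_error(confusion_matrix(c(0, 5), c(0, 0), 5), "0..K-1")
  expect_error(confusion_matrix(0, c(0, 1), 5), "equal length")
})

test_that("row sums are invariant under any permutation of predictions", {
  set.seed(31)
  y <- sample(0:4, 60, replace = TRUE)
  p <- sample(0:4, 60, replace = TRUE)
  r1 <- rowSums(confusion_matrix(y, p, 5))
  r2 <- rowSums(confusion_matrix(y, sample(p), 5))
  expect_equal(r1, r2)
})

test_that("classification report matches hand-computed macro metrics", {
  cm <- matrix(c(8, 1, 2, 9), 2, 2, byrow = FALSE)
  # rows actual: ((8, 2), (1, 9))
  cm <- matrix(c(8, 2, 1, 9), 2, 2, byrow = TRUE)
  r <- classification_report(cm)
  expect_equal(r$accuracy, 85.00)
  expect_equal(r$macro_precision, 85.35)
  expect_equal(r$macro_recall, 85.00)
  expect_equal(r$macro_f1, 84.96)
  # perfect diagonal
  p <- classification_report(diag(c(5, 3, 2)))
  expect_equal(unlist(p), c(accuracy = 100, macro_precision = 100,
                            macro_recall = 100, macro_f1 = 100))
  # all predictions in one column of a balanced 2-class problem
  one_col <- matrix(c(10, 0, 10, 0), 2, 2, byrow = TRUE)
  expect_equal(classification_report(one_col)$macro_recall, 50.00)
  expect_error(classification_report(matrix(0, 2, 2)), "empty")
})

test_that("report agrees with a brute-force per-sample oracle", {
  set.seed(32)
  y <- sample(0:4, 1000, replace = TRUE)
  p <- ifelse(runif(1000) < 0.7, y, sample(0:4, 1000, replace = TRUE))
  r <- classification_report(confusion_matrix(y, p, 5))
  # oracle: direct per-sample computation, no confusion matrix
  acc <- 100 * mean(y == p)
  prec <- mean(sapply(0:4, function(k) {
    if (sum(p == k) == 0) 0 else sum(y == k & p == k) / sum(p == k)
  }))
  rec <- mean(sapply(0:4, function(k) {
    if (sum(y == k) == 0) 0 else sum(y == k & p == k) / sum(y == k)
  }))
  f1 <- mean(sapply(0:4, function(k) {
    pr <- if (sum(p == k) == 0) 0 else sum(y == k & p == k) / sum(p == k)
    rc <- if (sum(y == k) == 0) 0 else sum(y == k & p == k) / sum(y == k)
    if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
  }))
  expect_equal(r$accuracy, round(acc, 2))
  expect_equal(r$macro_precision, round(100 * prec, 2))
  expect_equal(r$macro_recall, round(100 * rec, 2))
  expect_equal(r$macro_f1, round(100 * f1, 2))
})

test_that("tolerance accuracy counts near-misses by class spacing", {
  lv <- bcs_levels()
  expect_equal(tolerance_accuracy(lv, lv, 0), 100)
  # every prediction one class step off
  shifted <- lv[c(2, 3, 4, 5, 4)]
  expect_equal(tolerance_accuracy(lv, shifted, 0.25), 100)
  expect_equal(tolerance_accuracy(lv, shifted, 0), 0)
  # hand-counted mixed case: |diffs| = 0.25, 0, 1.0, 0
  tr <- c(3.25, 3.50, 4.25, 4.00)
  pr <- c(3.50, 3.50, 3.25, 4.00)
  expect_equal(tolerance_accuracy(tr, pr, 0.25), 75)
  expect_equal(tolerance_accuracy(tr, pr, 0.5), 75)
  expect_error(tolerance_accuracy(c(3.3), c(3.25), 0.25), "five-value")
  expect_error(tolerance_accuracy(lv, lv, -1), "tol")
})

test_that("tolerance accuracy is monotone in tol and saturates at 1.0", {
  set.seed(33)
  lv <- bcs_levels()
  tr <- lv[sample(5, 200, replace = TRUE)]
  pr <- lv[sample(5, 200, replace = TRUE)]
  tols <- c(0, 0.25, 0.5, 0.75, 1.0)
  vals <- sapply(tols, function(t) tolerance_accuracy(tr, pr, t))
  expect_true(all(diff(vals) >= 0))
  expect_equal(vals[5], 100)  # max class gap is 1.0
  # tol = 0 equals plain accuracy
  expect_equal(vals[1], 100 * mean(tr == pr))
})

test_that("evaluate_model ties the metrics together consistently", {
  co <- tiny_corpus()
  ds <- split_subsets(co)
  m <- build_small_cnn(input_size = 16, seed = 6)
  ev <- evaluate_model(m, ds$test)
  expect_s3_class(ev, "eval_report")
  expect_equal(sum(ev$confusion), length(ds$test$y))
  expect_lte(ev$accuracy, ev$tolerance_accuracy_025)
  expect_lte(ev$tolerance_accuracy_025, ev$tolerance_accuracy_05)
  expect_lte(ev$tolerance_accuracy_05, 100)
})

test_that("latency profiling returns a positive per-sample time", {
  m <- build_small_cnn(input_size = 16)
  t1 <- latency_profile(m, 16, n_repeats = 3, n_warmup = 1)
  expect_gt(t1, 0)
})
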