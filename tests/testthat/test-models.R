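# Backbone zoo, composite variants and profiling arithmetic.

# Published trainable-parameter counts of the reference 1000-class
# architectures; the builders must reproduce them from per-layer arithmetic.
REFERENCE_1000 <- c(efficientnet_b0 = 5288548, mobilenet_v3_large = 5483032,
                    mobilenet_v2 = 3504872, mobilenet_v3_small = 2542856,
                    squeezenet_1_1 = 1235496, shufflenet_v2_x1_0 = 2278604)

# Final-classifier sizes (in, out-replaced) used by the 5-class head swap.
HEAD_IN <- c(efficientnet_b0 = 1280, mobilenet_v3_large = 1280,
             mobilenet_v2 = 1280, mobilenet_v3_small = 1024,
             squeezenet_1_1 = 512, shufflenet_v2_x1_0 = 1024)

test_that("all six backbones reproduce the reference parameter counts", {
  for (nm in names(REFERENCE_1000)) {
    n1000 <- count_parameters(build_backbone(nm, 1000))
    expect_equal(n1000, REFERENCE_1000[[nm]])
    n5 <- count_parameters(build_backbone(nm, 5))
    # head swap changes exactly the final classifier
    expect_equal(n5, n1000 - (HEAD_IN[[nm]] * 1000 + 1000) +
                           (HEAD_IN[[nm]] * 5 + 5))
  }
})

test_that("5-class parameter counts round to the published millions", {
  printed <- c(efficientnet_b0 = 4.01, mobilenet_v3_large = 4.21,
               mobilenet_v2 = 2.23, mobilenet_v3_small = 1.52,
               squeezenet_1_1 = 0.73, shufflenet_v2_x1_0 = 1.26)
  for (nm in names(printed)) {
    expect_equal(round(count_parameters(build_backbone(nm, 5)) / 1e6, 2),
                 printed[[nm]])
  }
  expect_equal(count_parameters(build_backbone("efficientnet_b0", 5)),
                   4013953)
  expect_equal(count_parameters(build_backbone("mobilenet_v2", 5)), 2230277)
  expect_error(build_backbone("resnet50"), "unknown backbone")
  expect_error(build_backbone("mobilenet_v2", 1), "num_classes")
})

test_that("model size follows the float32 MiB convention", {
  expect_equal(model_size_mib(build_backbone("efficientnet_b0", 5)), 15.31)
  expect_equal(model_size_mib(262144), 1.00)
  expect_equal(model_size_mib(0), 0.00)
  m <- build_backbone("squeezenet_1_1", 5)
  expect_equal(model_size_mib(m), round(count_parameters(m) * 4 / 2^20, 2))
})

test_that("FLOP counting matches per-layer hand arithmetic", {
  lin <- bcsnet:::layer_sequential(list(bcsnet:::layer_flatten(),
                                        bcsnet:::layer_linear(1280, 5)))
  m <- bcsnet:::new_bcs_model("toy", bcsnet:::layer_sequential(list()),
                              lin, 1280, 5, 1)
  # a single linear 1280 -> 5: need shape (1, 1, 1280) going in
  expect_equal(bcsnet:::layer_shape_flops(bcsnet:::layer_linear(1280, 5), 1280)$flops,
               6400)
  conv <- bcsnet:::layer_conv2d(1, 1, 3)
  expect_equal(bcsnet:::layer_shape_flops(conv, c(6, 6, 1))$flops, 144) # 9 * 16
  # two-layer toy CNN, independent hand count:
  #   conv 3x3 2->4 on 8x8 pad 1 -> 64 * 9 * 2 * 4 = 4608
  #   conv 1x1 4->3 on 8x8       -> 64 * 1 * 4 * 3 = 768
  two <- bcsnet:::layer_sequential(list(
    bcsnet:::layer_conv2d(2, 4, 3, padding = 1),
    bcsnet:::layer_conv2d(4, 3, 1)))
  expect_equal(bcsnet:::layer_shape_flops(two, c(8, 8, 2))$flops, 4608 + 768)
})

test_that("ablation variants change parameters exactly as built", {
  a1 <- build_composite("A1")
  a2 <- build_composite("A2")
  a3 <- build_composite("A3")
  # SE on the 1280-channel map, r = 16, biases: 1280*80+80 + 80*1280+1280
  expect_equal(count_parameters(a2) - count_parameters(a1), 206160)
  expect_equal(round((count_parameters(a2) - count_parameters(a1)) / 1e6, 2), 0.21)
  # spatial kernel 7x7x2 + bias
  expect_equal(count_parameters(a3) - count_parameters(a1), 99)
  # loss-only variants do not change the architecture
  expect_equal(count_parameters(build_composite("A4")), count_parameters(a1))
  a5 <- build_composite("A5"); a6 <- build_composite("A6"); a8 <- build_composite("A8")
  expect_lt(count_parameters(a1), count_parameters(a2))
  expect_lt(count_parameters(a1), count_parameters(a5))
  expect_lt(count_parameters(a6), count_parameters(a8))
})

test_that("the convolutional head matches its closed-form parameter count", {
  head <- build_yolo_head(1280, 5)
  closed <- (1280 * 512 + 2 * 512) +      # pointwise + bn
            (9 * 512 + 2 * 512) +         # depthwise 3x3 + bn
            (512 * 1280 + 2 * 1280) +     # pointwise expansion + bn
            (1280 * 5 + 5)                # linear
  expect_equal(bcsnet:::n_params_layer(head), closed)
  expect_error(build_yolo_head(3, 5), "at least num_classes")
  # swapping heads leaves the backbone untouched
  a1 <- build_composite("A1"); a5 <- build_composite("A5")
  expect_equal(bcsnet:::n_params_layer(a1$features),
                   bcsnet:::n_params_layer(a5$features))
})

test_that("head logits have length num_classes for any input spatial size", {
  head <- build_yolo_head(8, 5)
  for (s in c(1, 3, 7)) {
    x <- array(rnorm(s * s * 8), c(s, s, 8, 1))
    expect_length(bcsnet:::layer_forward(head, x)$out, 5)
  }
})

test_that("a composite forward pass yields finite logits of length 5", {
  a1 <- build_composite("A1")
  x <- preprocess(array(runif(64 * 64 * 3), c(64, 64, 3)), 64)
  lg <- model_forward(a1, x)$logits
  expect_length(lg, 5)
  expect_true(all(is.finite(lg)))
})
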