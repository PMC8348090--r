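test_that("all builders produce valid softmax networks near the target sizes", {
  for (arch in c("conv1d", "conv2d", "lstm")) {
    spec <- classifier_spec(arch, seed = 4)
    net <- switch(arch, conv1d = build_conv1d(spec),
                  conv2d = build_conv2d(spec), lstm = build_lstm(spec))
    expect_gt(net$parameter_count, 0)
    x <- array(rnorm(2 * 98 * 26), c(2, 98, 26))
    xx <- jawdio:::stack_inputs(x, net$input_dims)
    out <- jawdio:::network_forward(net$layers, xx, FALSE)$out
    probs <- jawdio:::softmax_rows(out)
    expect_equal(dim(probs), c(2L, 3L))
    expect_equal(rowSums(probs), c(1, 1), tolerance = 1e-6)
  }
  # widths were chosen to land near the published model sizes
  expect_lt(abs(build_conv1d(classifier_spec("conv1d"))$parameter_count - 348770) / 348770, 0.02)
  expect_lt(abs(build_conv2d(classifier_spec("conv2d"))$parameter_count - 431290) / 431290, 0.02)
  expect_lt(abs(build_lstm(classifier_spec("lstm"))$parameter_count - 392050) / 392050, 0.02)
})

test_that("building twice with the same seed gives identical parameters", {
  a <- build_lstm(classifier_spec("lstm", seed = 9))
  b <- build_lstm(classifier_spec("lstm", seed = 9))
  expect_identical(a$layers, b$layers)
  c_ <- build_lstm(classifier_spec("lstm", seed = 10))
  expect_false(identical(a$layers, c_$layers))
})

test_that("training runs the configured epochs deterministically", {
  set <- tiny_feature_set(n_per_class = 6, t_fixed = 12)
  fit1 <- jaw_classifier(set$x, set$y, arch = "conv1d", epochs = 3,
                         input_shape = c(12L, 26L), seed = 2)
  fit2 <- jaw_classifier(set$x, set$y, arch = "conv1d", epochs = 3,
                         input_shape = c(12L, 26L), seed = 2)
  expect_equal(nrow(fit1$history), 3L)
  expect_identical(fit1$history, fit2$history)
  expect_identical(predict(fit1, set$x, type = "prob"),
                   predict(fit2, set$x, type = "prob"))
  expect_true(all(is.finite(fit1$history$loss)))

  expect_error(train_classifier(build_conv1d(classifier_spec("conv1d")),
                                list(), character(0)), "empty")
})

test_that("prediction preserves batch order and is repeatable", {
  set <- tiny_feature_set(n_per_class = 5, t_fixed = 12)
  fit <- jaw_classifier(set$x, set$y, arch = "lstm", epochs = 2,
                        input_shape = c(12L, 26L), seed = 3)
  p_all <- predict(fit, set$x, type = "prob")
  expect_equal(rowSums(p_all), rep(1, length(set$x)), tolerance = 1e-9)
  p_sub <- predict(fit, set$x[c(3, 1)], type = "prob")
  expect_equal(p_sub, p_all[c(3, 1), ], tolerance = 1e-12)
  expect_identical(predict(fit, set$x), predict(fit, set$x))

  # reversed-time input still yields a valid distribution from the BiLSTM
  rev_x <- lapply(set$x, function(m) m[rev(seq_len(nrow(m))), ])
  p_rev <- predict(fit, rev_x, type = "prob")
  expect_equal(rowSums(p_rev), rep(1, length(rev_x)), tolerance = 1e-9)

  # shape mismatch is an error
  expect_error(predict(fit, list(matrix(0, 7, 26))), "shape")
})

test_that("a trained model round-trips through serialization", {
  set <- tiny_feature_set(n_per_class = 4, t_fixed = 12)
  fit <- jaw_classifier(set$x, set$y, arch = "conv2d", epochs = 2,
                        input_shape = c(12L, 26L), seed = 5)
  f <- withr::local_tempfile(fileext = ".rds")
  saveRDS(fit, f)
  back <- readRDS(f)
  expect_identical(predict(back, set$x, type = "prob"),
                   predict(fit, set$x, type = "prob"))
})

test_that("config constructors validate their invariants", {
  expect_error(classifier_spec("lstm", n_classes = 4L), "fixed at 3")
  expect_error(classifier_spec("lstm", dropout = 1), "dropout")
  expect_error(train_config(epochs = 0), "epochs")
  expect_equal(train_config()$epochs, 30L)
  expect_equal(classifier_spec("lstm")$dropout, 0.1)
})
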