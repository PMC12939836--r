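sep_fixture <- function(n_per_class = 20L, ts = 16L, seed = 5) {
  with_seed(seed, {
    xs <- c(lapply(seq_len(n_per_class), function(i) fixture_tensor(0, ts)),
            lapply(seq_len(n_per_class), function(i) fixture_tensor(1, ts)))
    list(x = xs, y = rep(c(0L, 1L), each = n_per_class))
  })
}

test_that("the small CNN fits separable data to perfect training accuracy", {
  fx <- sep_fixture()
  cfg <- training_config(input_size = 16L, total_epochs = 25L,
                         learning_rate = 0.1, seed = 7)
  fit <- train_classifier(fx$x, fx$y, fx$x, fx$y, cfg)
  expect_equal(fit$history$train_acc[25], 1)
  expect_identical(predict(fit, fx$x), fx$y)
  probs <- predict(fit, fx$x, type = "prob")
  expect_true(all(probs >= 0 & probs <= 1))
  expect_identical(nrow(fit$history), 25L)
  expect_true(all(c("train_loss", "val_acc") %in% names(fit$history)))
})

test_that("training is deterministic given the seed", {
  fx <- sep_fixture(8L)
  cfg <- training_config(input_size = 16L, total_epochs = 5L, seed = 42)
  f1 <- train_classifier(fx$x, fx$y, fx$x, fx$y, cfg)
  f2 <- train_classifier(fx$x, fx$y, fx$x, fx$y, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$weights, f2$weights)
  cfg2 <- cfg; cfg2$seed <- 43L
  f3 <- train_classifier(fx$x, fx$y, config = cfg2)
  expect_false(identical(f1$weights$Wd, f3$weights$Wd))
})

test_that("the convolutional base is bit-frozen during frozen epochs", {
  fx <- sep_fixture(8L)
  cfg <- training_config(input_size = 16L, freeze_epochs = 4L,
                         total_epochs = 4L, seed = 9)
  fit <- train_classifier(fx$x, fx$y, config = cfg)
  # the seeded init is reproducible: conv weights must equal it bit-for-bit
  w0 <- with_seed(9, bandelet:::init_small_cnn(4L, 16L))
  for (nm in c("W1", "b1", "W2", "b2", "W3", "b3"))
    expect_identical(fit$weights[[nm]], w0[[nm]])
  # the head trained
  expect_false(identical(fit$weights$Wd, w0$Wd))
  # unfreezing moves the base
  cfg2 <- training_config(input_size = 16L, freeze_epochs = 2L,
                          total_epochs = 4L, seed = 9)
  fit2 <- train_classifier(fx$x, fx$y, config = cfg2)
  expect_false(identical(fit2$weights$W1, w0$W1))
})

test_that("the mixed transfer loss interpolates between source and target", {
  expect_equal(bandelet:::mixed_loss(2, 6, 0), 6)     # pure target
  expect_equal(bandelet:::mixed_loss(2, 6, 1), 2)     # pure source
  expect_equal(bandelet:::mixed_loss(2, 6, 0.25), 0.25 * 2 + 0.75 * 6)
  expect_error(bandelet:::mixed_loss(1, 1, 2), "0, 1")
  # lambda_mix = 0 ignores supplied source data entirely
  fx <- sep_fixture(6L)
  src <- sep_fixture(6L, seed = 99)
  cfg0 <- training_config(input_size = 16L, total_epochs = 3L, seed = 4,
                          lambda_mix = 0,
                          source_data = list(tensors = src$x, labels = src$y))
  cfg_plain <- training_config(input_size = 16L, total_epochs = 3L, seed = 4)
  f0 <- train_classifier(fx$x, fx$y, config = cfg0)
  fp <- train_classifier(fx$x, fx$y, config = cfg_plain)
  expect_identical(f0$weights, fp$weights)
  # lambda_mix = 1 descends only the source loss: target-only signal is gone
  cfg1 <- training_config(input_size = 16L, total_epochs = 3L, seed = 4,
                          lambda_mix = 1,
                          source_data = list(tensors = src$x, labels = src$y))
  f1 <- train_classifier(fx$x, fx$y, config = cfg1)
  expect_false(identical(f1$weights, fp$weights))
})

test_that("training rejects malformed inputs", {
  fx <- sep_fixture(4L)
  expect_error(train_classifier(list(), integer(0)), "empty")
  expect_error(train_classifier(fx$x, fx$y[-1]), "differ")
  bad <- fx$x
  bad[[1]] <- structure(array(0, c(3, 16, 16)), class = "bandelet_tensor")
  expect_error(train_classifier(bad, fx$y), "4-channel")
  expect_error(training_config(freeze_epochs = 5, total_epochs = 3), "exceed")
  expect_error(training_config(lambda_mix = 1.5), "0, 1")
})

test_that("label permutation destroys learnability on balanced data", {
  fx <- sep_fixture(12L)
  perm_y <- with_seed(31, sample(fx$y))
  cfg <- training_config(input_size = 16L, total_epochs = 10L,
                         learning_rate = 0.05, seed = 8)
  hold <- sep_fixture(10L, seed = 77)
  fit <- train_classifier(fx$x, perm_y, config = cfg)
  acc <- mean(predict(fit, hold$x) == hold$y)
  # within 3 sigma of chance on n = 20 held-out items
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / length(hold$y)) + 1e-9)
})

test_that("cross-validation partitions folds and aggregates metrics", {
  fx <- sep_fixture(10L)
  cfg <- training_config(input_size = 16L, total_epochs = 12L,
                         learning_rate = 0.1, seed = 13)
  cv <- cross_validate(fx$x, fx$y, k = 4, repeats = 2, config = cfg)
  expect_identical(nrow(cv$folds), 8L)
  expect_named(cv$stats, c("Acc", "Sen", "Spe", "P", "F1"))
  expect_s3_class(cv$stats$Acc, "fold_statistics")
  expect_true(cv$stats$Acc[["min"]] <= cv$stats$Acc[["max"]])
  # separable fixture: high mean validation accuracy
  expect_gt(cv$stats$Acc[["mean"]], 90)
  expect_error(cross_validate(fx$x, fx$y, k = 30, config = cfg), "at least k")
})
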