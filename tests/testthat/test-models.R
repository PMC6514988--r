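# Network construction, the convolution arithmetic, training mechanics and
# feature extraction.

test_that("conv_output_length matches a brute-force placement count", {
  brute <- function(len, H, s) length(seq.int(1L, len - H + 1L, by = s))
  expect_identical(conv_output_length(63, 20, 1), 44L)
  expect_identical(conv_output_length(44, 20, 1), 25L)
  expect_identical(conv_output_length(25, 20, 1), 6L)
  expect_identical(conv_output_length(189, 20, 2), 85L)
  for (H in c(1L, 7L, 20L)) {
    expect_identical(conv_output_length(H, H, 3), 1L)
    for (s in 1:3) {
      for (len in seq.int(H, 400L, by = 7L)) {
        expect_identical(conv_output_length(len, H, s), brute(len, H, s))
      }
    }
  }
  expect_error(conv_output_length(19, 20, 1), "shorter than the filter")
})

test_that("single-modal networks have the documented geometry", {
  net <- build_single_modal("pressure", k = 1, seed = 1)
  expect_identical(net$feature_length, 768L)       # 6 positions x 128 filters
  expect_identical(net$stride, 1L)
  expect_identical(dim(net$layers[[1]]$w), c(20L, 16L, 32L))
  expect_identical(dim(net$layers[[7]]$w), c(128L, 7L))

  net3 <- build_single_modal("accel", k = 3, seed = 1)
  expect_identical(net3$stride, 2L)                 # s = 2 for k in 3..5
  expect_identical(net3$feature_lengths[1], 85L * 32L)

  # too-short input for the filter stack
  expect_error(build_single_modal("accel", k = 1, t = 40), "shorter than the filter")
})

test_that("prediction yields row-stochastic probabilities with stable ties", {
  std <- small_split()
  net <- build_single_modal("gyro", k = 1, seed = 2)
  pred <- predict(net, std$test)
  expect_equal(rowSums(pred$prob), rep(1, n_samples(std$test)), tolerance = 1e-6)
  expect_identical(colnames(pred$prob), gait_types())

  # zeroed output layer -> exactly uniform probabilities, argmax tie -> code 0
  net$layers[[7]]$w[] <- 0
  net$layers[[7]]$b[] <- 0
  pred0 <- predict(net, std$test)
  expect_equal(unname(pred0$prob), matrix(1 / 7, n_samples(std$test), 7),
               tolerance = 1e-12)
  expect_true(all(pred0$code == 0L))

  # duplicated inputs give identical rows
  two <- subset_samples(std$test, c(1, 1))
  predd <- predict(net, two)
  expect_identical(predd$prob[1, ], predd$prob[2, ])
})

test_that("training reduces the loss and beats chance on separable data", {
  std <- small_split()
  net <- build_single_modal("accel", k = 1, seed = 3)
  net <- train_model(net, std$train, train_config(epochs = 5, seed = 3))
  expect_length(net$loss_history, 5)
  expect_lt(net$loss_history[5], net$loss_history[1])
  pred <- predict(net, std$train)
  expect_gt(evaluate_accuracy(pred$code, std$train$label), 1 / 7)
})

test_that("a zero learning rate leaves the network and its loss unchanged", {
  std <- small_split()
  train20 <- subset_samples(std$train, 1:20)
  net <- build_single_modal("accel", k = 1, dropout = 0, seed = 4)
  w_before <- net$layers[[1]]$w
  cfg <- train_config(learning_rate = 0, batch_size = 20, epochs = 3, seed = 4)
  net <- train_model(net, train20, cfg)
  expect_identical(net$layers[[1]]$w, w_before)
  expect_lt(diff(range(net$loss_history)), 1e-6)
})

test_that("training is deterministic for a fixed seed", {
  std <- small_split()
  train40 <- subset_samples(std$train, 1:40)
  cfg <- train_config(epochs = 2, seed = 11)
  a <- train_model(build_single_modal("gyro", k = 1, seed = 11), train40, cfg)
  b <- train_model(build_single_modal("gyro", k = 1, seed = 11), train40, cfg)
  expect_identical(a$layers[[1]]$w, b$layers[[1]]$w)
  expect_identical(a$layers[[7]]$w, b$layers[[7]]$w)
  expect_identical(a$loss_history, b$loss_history)
})

test_that("feature extraction returns the flattened conv activations", {
  std <- small_split()
  net <- build_single_modal("pressure", k = 1, seed = 5)
  feats <- extract_features(net, std$test)
  expect_identical(dim(feats), c(n_samples(std$test), 768L))
  expect_identical(extract_features(net, std$test)[3, ], feats[3, ])

  # an all-zero input through a zero-bias ReLU stack stays (post-BN) constant
  # across samples; and multi-modal handles refuse per-modality extraction
  multi <- build_multi_modal(list(net, build_single_modal("accel", k = 1, seed = 6)))
  expect_error(extract_features(multi, std$test), "per-modality")
})

test_that("multi-modal fusion concatenates features and enforces contracts", {
  std <- small_split()
  cfg <- train_config(epochs = 2, seed = 7)
  nets <- lapply(c("pressure", "accel", "gyro"), function(m) {
    train_model(build_single_modal(m, k = 1, seed = 7), std$train, cfg)
  })
  fused <- build_multi_modal(nets, seed = 7)
  expect_identical(fused$feature_length, 3L * 768L)
  fused <- train_model(fused, std$train, cfg)
  pred <- predict(fused, std$test)
  expect_equal(rowSums(pred$prob), rep(1, n_samples(std$test)), tolerance = 1e-6)

  # mismatched k across parts
  expect_error(build_multi_modal(list(nets[[1]],
                                      build_single_modal("accel", k = 2))),
               "share k")
  # missing modality in the samples
  nogyro <- std$test
  nogyro$gyro <- NULL
  expect_error(predict(fused, nogyro), "modality 'gyro'")
  expect_error(build_multi_modal(nets[1]), "at least two")
})

test_that("early stopping on a held-out split can end training early", {
  std <- small_split()
  cfg <- train_config(epochs = 30, seed = 8, validation_split = 0.2,
                      early_stopping_patience = 2)
  net <- train_model(build_single_modal("accel", k = 1, seed = 8),
                     subset_samples(std$train, 1:60), cfg)
  expect_true(length(net$val_loss_history) >= 3)
  expect_true(length(net$loss_history) <= 30)
})
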