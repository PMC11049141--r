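# Training harness: schedule, optimisation, reproducibility, evaluation.

test_that("cosine schedule hits both endpoints", {
  expect_equal(cosine_lr(0, 400), 1e-4)
  expect_equal(cosine_lr(399, 400), 1e-5)
  mid <- cosine_lr(0:399, 400)
  expect_true(all(diff(mid) < 0))                        # strictly decaying
  expect_equal(cosine_lr(0, 1), 1e-4)                    # degenerate 1-epoch run
})

test_that("one optimiser step decreases the loss on a fixed batch", {
  for (seed in 1:5) {
    model <- tiny_model(3L, size = 32L, seed = seed)
    samples <- smoke_samples(n = 2L, size = 32L, seed = seed)
    batch <- pisnet:::samples_to_batch(samples, 1L)
    cfg <- train_config(learning_rate = 1e-3, min_learning_rate = 1e-4,
                        batch_size = 2L, epochs = 1L, seed = seed)
    loss0 <- model_loss(model, pisnet:::batch_to_ts(batch$x),
                        pisnet:::batch_to_ts(batch$y))
    state <- pisnet:::adam_state(model)
    r <- pisnet:::train_step(model, batch, cfg, state, 1L, cfg$learning_rate)
    loss1 <- model_loss(model, pisnet:::batch_to_ts(batch$x),
                        pisnet:::batch_to_ts(batch$y))
    expect_lt(loss1, loss0)
    expect_equal(r$loss, loss0, tolerance = 1e-10)
  }
})

test_that("identical seed and config give identical first-epoch loss", {
  run <- function() {
    model <- tiny_model(3L, size = 32L, seed = 31L)
    pisnet_train(model, smoke_samples(4L, 32L, seed = 8L),
                 config = train_config(epochs = 1L, batch_size = 2L,
                                       seed = 77L))$history$train_loss[1]
  }
  expect_identical(run(), run())
})

test_that("training logs epochs and retains the best validation weights", {
  model <- tiny_model(3L, size = 32L, seed = 19L)
  samples <- smoke_samples(6L, 32L, seed = 21L)
  fit <- pisnet_train(model, samples[1:4], samples[5:6],
                      config = train_config(learning_rate = 1e-3,
                                            min_learning_rate = 1e-4,
                                            epochs = 3L, batch_size = 4L,
                                            seed = 5L))
  expect_equal(nrow(fit$history), 3L)
  expect_named(fit$history, c("epoch", "lr", "train_loss", "val_iou",
                              "val_dice"))
  expect_equal(fit$history$lr[1], 1e-3)
  best <- evaluate_samples(fit$model, samples[5:6])$summary[["mean_dice"]]
  expect_equal(best, max(fit$history$val_dice), tolerance = 1e-9)
})

test_that("non-finite loss aborts with a diagnostic", {
  model <- tiny_model(3L, size = 32L, seed = 23L)
  model$blocks$final$params$w[1] <- NaN
  expect_error(pisnet_train(model, smoke_samples(2L, 32L, seed = 2L),
                            config = train_config(epochs = 1L,
                                                  batch_size = 2L, seed = 1L)),
               "diverged")
})

test_that("an oracle predictor scores perfect metrics", {
  set.seed(33)
  masks <- lapply(1:3, function(i) matrix(rbinom(64, 1, 0.3), 8))
  oracle <- segmentation_metrics(masks, masks)
  expect_equal(oracle$summary[["mean_iou"]], 1, tolerance = 1e-5)
  expect_equal(oracle$summary[["mean_dice"]], 1, tolerance = 1e-5)

  # constant 0.5 with threshold 0.5 predicts all-foreground
  m <- masks[[1]]
  const <- segmentation_metrics(matrix(0.5, 8, 8), m)
  tp <- sum(m); fp <- 64 - sum(m)
  expect_equal(const$per_image$iou, tp / (tp + fp), tolerance = 1e-4)
  expect_equal(const$per_image$dice, 2 * tp / (2 * tp + fp), tolerance = 1e-4)
})
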