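# Assembled network: variants, shapes, determinism, checkpoints.

test_that("configuration validates variants and sizes", {
  expect_error(pisnet_config(7L), "1..6")
  expect_error(pisnet_config(0L), "1..6")
  expect_error(pisnet_config(6L, input_size = 100L), "divisible")
  expect_error(pisnet_config(6L, in_channels = 2L), "1 or 3")
  expect_error(pisnet_config(6L, widths = c(16L, 8L, 4L, 2L, 1L)), "increasing")
  cfg <- pisnet_config(5L)
  expect_true(cfg$use_hbds); expect_false(cfg$use_drspp); expect_false(cfg$use_mixer)
  cfg6 <- pisnet_config(6L)
  expect_true(cfg6$use_hbds && cfg6$use_drspp && cfg6$use_mixer)
})

test_that("forward maps a batch to logits of identical spatial size", {
  m <- tiny_model(6L, size = 64L)
  x <- rand_batch(2, 1, 64, 64)
  p <- predict(m, x)
  expect_equal(dim(p), c(2L, 1L, 64L, 64L))
  expect_true(all(p > 0 & p < 1))
  # same model, other compliant size: geometry adapts without reconfiguration
  p2 <- predict(m, rand_batch(1, 1, 32, 32, seed = 2))
  expect_equal(dim(p2), c(1L, 1L, 32L, 32L))
  expect_error(predict(m, rand_batch(1, 1, 48, 48)), "divisible")
  expect_error(predict(m, rand_batch(1, 3, 64, 64)), "channels")
})

test_that("prediction is deterministic in evaluation mode", {
  m <- tiny_model(3L, size = 32L)
  x <- rand_batch(2, 1, 32, 32, seed = 5)
  expect_identical(predict(m, x), predict(m, x))
  msk <- predict(m, x, type = "mask")
  expect_true(all(msk %in% c(0, 1)))
})

test_that("variants 2 and 3 differ only in their MLP-stage blocks", {
  m2 <- pisnet(2L, input_size = 64L, widths = tiny_widths, seed = 3L)
  m3 <- pisnet(3L, input_size = 64L, widths = tiny_widths, seed = 3L)
  conv_names <- c("enc1", "enc2", "enc3", "pe3", "pe4", "norm3", "norm4",
                  "dec1", "dec2", "dec3", "dec4", "dec5", "dnorm3", "dnorm4",
                  "final")
  expect_setequal(setdiff(names(m2$blocks), names(m3$blocks)), character(0))
  for (nm in conv_names)
    expect_identical(names(m2$blocks[[nm]]$params),
                     names(m3$blocks[[nm]]$params))
  for (nm in c("blk4", "blk5", "dblk1", "dblk2")) {
    expect_identical(m2$blocks[[nm]]$type, "tok_block")
    expect_identical(m3$blocks[[nm]]$type, "da_block")
  }
})

test_that("parameter counting is an exact element sum", {
  # a lone 10 -> 5 linear map with bias has 55 parameters
  blk <- pisnet:::pw_block(10L, 5L)
  expect_identical(sum(vapply(blk$params, length, numeric(1))), 55)
  m <- tiny_model(2L)
  expect_identical(count_trainable_parameters(m),
                   sum(vapply(pisnet:::model_params(m), length, numeric(1))))
})

test_that("checkpoints rebuild the model bit-identically", {
  m <- tiny_model(6L, size = 32L, seed = 13L)
  samples <- smoke_samples(n = 2L, size = 32L, seed = 3L)
  fit <- pisnet_train(m, samples,
                      config = train_config(epochs = 2L, batch_size = 2L,
                                            seed = 1L))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(fit$model, path)
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- load_checkpoint(path)
  x <- rand_batch(1, 1, 32, 32, seed = 6)
  expect_identical(predict(fit$model, x), predict(m2, x))
  e1 <- evaluate_samples(fit$model, samples)
  e2 <- evaluate_samples(m2, samples)
  expect_identical(e1$summary, e2$summary)
})

test_that("every weight array receives gradient after one step", {
  m <- tiny_model(6L, size = 32L, seed = 17L)
  samples <- smoke_samples(n = 4L, size = 32L, seed = 5L)
  fit <- pisnet_train(m, samples,
                      config = train_config(learning_rate = 1e-3,
                                            min_learning_rate = 1e-4,
                                            epochs = 1L, batch_size = 4L,
                                            seed = 2L))
  grads <- pisnet:::model_grads(fit$model)
  nonzero <- vapply(grads, function(g) any(g != 0), logical(1))
  expect_true(all(nonzero),
              info = paste("dead arrays:",
                           paste(names(grads)[!nonzero], collapse = ", ")))
})

test_that("seeded construction is reproducible", {
  a <- pisnet(4L, input_size = 64L, widths = tiny_widths, seed = 9L)
  b <- pisnet(4L, input_size = 64L, widths = tiny_widths, seed = 9L)
  expect_identical(pisnet:::model_params(a), pisnet:::model_params(b))
})

test_that("print and summary report the architecture", {
  m <- tiny_model(2L)
  expect_output(print(m), "variant 2")
  expect_output(print(m), "trainable parameters")
  s <- summary(m)
  expect_true(is.data.frame(s) && all(c("block", "parameters") %in% names(s)))
})
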