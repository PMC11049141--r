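# Shared fixtures: tiny models, random feature maps, numerical gradients.

tiny_widths <- c(5L, 6L, 7L, 8L, 10L)

tiny_model <- function(variant, size = 32L, seed = 7L,
                       widths = if (variant == 1L) c(4L, 5L, 6L, 7L, 8L)
                                else tiny_widths) {
  if (variant == 1L && size %% 16L != 0L) size <- 16L
  pisnet(variant, input_size = size, widths = widths, seed = seed)
}

rand_fm <- function(C, H, W, seed = 1L) {
  set.seed(seed)
  array(rnorm(C * H * W), dim = c(C, H, W))
}

rand_batch <- function(n, C, H, W, seed = 1L) {
  set.seed(seed)
  array(runif(n * C * H * W), dim = c(n, C, H, W))
}

# loss of a model on a fixed batch (training mode), for gradient checks
model_loss <- function(model, x, y) {
  logits <- pisnet:::model_forward(model, x, train = TRUE)
  probs <- pisnet:::sigmoid(logits)
  combined_loss(probs, y)
}

# central finite difference on selected entries of every parameter array
check_model_gradients <- function(model, size = 32L, n = 2L, eps = 1e-5,
                                  tol = 1e-3) {
  set.seed(99)
  x <- pisnet:::batch_to_ts(rand_batch(n, model$config$in_channels, size, size,
                                       seed = 3L))
  y <- pisnet:::batch_to_ts(array(rbinom(n * size * size, 1, 0.3),
                                  c(n, 1, size, size)))
  logits <- pisnet:::model_forward(model, x, train = TRUE)
  probs <- pisnet:::sigmoid(logits)
  dprob <- pisnet:::combined_loss_grad(probs, y)
  pisnet:::model_backward(model, dprob * probs * (1 - probs))
  worst <- 0
  for (nm in names(model$blocks)) {
    blk <- model$blocks[[nm]]
    for (pn in names(blk$params)) {
      len <- length(blk$params[[pn]])
      ii <- if (len > 2L) sample.int(len, 1L) else 1L
      v0 <- blk$params[[pn]][ii]
      blk$params[[pn]][ii] <- v0 + eps
      lp <- model_loss(model, x, y)
      blk$params[[pn]][ii] <- v0 - eps
      lm <- model_loss(model, x, y)
      blk$params[[pn]][ii] <- v0
      num <- (lp - lm) / (2 * eps)
      ana <- blk$grads[[pn]][ii]
      worst <- max(worst, abs(num - ana) / max(1e-4, abs(num) + abs(ana)))
    }
  }
  worst
}

# build a batch of synthetic training samples quickly
smoke_samples <- function(n = 16L, size = 64L, seed = 7L,
                          preset = "ultrasound_blob") {
  generate_dataset(synthetic_spec(n, size = size, modality_preset = preset,
                                  seed = seed))
}
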