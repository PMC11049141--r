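# Training harness: Adam with cosine-annealed learning rate, per-epoch
# logging, best-validation checkpointing, and evaluation reports.

#' Training configuration
#'
#' Defaults follow the reference recipe: Adam with learning rate 1e-4 and
#' first-moment coefficient `beta1 = 0.9`, a cosine-annealing schedule
#' decaying to 1e-5, batch size 8 and 400 epochs. Epochs and batch size
#' are configurable for desk-scale runs.
#'
#' @param learning_rate Initial learning rate.
#' @param min_learning_rate Final learning rate of the cosine schedule
#'   (must be below `learning_rate`).
#' @param beta1,beta2 Adam moment coefficients.
#' @param batch_size Batch size (>= 1).
#' @param epochs Number of epochs (>= 1).
#' @param seed Integer seed controlling initialisation and batch order.
#' @param loss_weights A [loss_weights()] object.
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(learning_rate = 1e-4, min_learning_rate = 1e-5,
                         beta1 = 0.9, beta2 = 0.999, batch_size = 8L,
                         epochs = 400L, seed = 1L,
                         loss_weights = pisnet::loss_weights()) {
  if (min_learning_rate >= learning_rate)
    stop("min_learning_rate must be below learning_rate", call. = FALSE)
  if (batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  structure(list(learning_rate = learning_rate,
                 min_learning_rate = min_learning_rate,
                 beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 loss_weights = loss_weights),
            class = "train_config")
}

#' Cosine-annealed learning rate
#'
#' `lr(e) = min + (max - min) * (1 + cos(pi * e / (E - 1))) / 2` for epoch
#' `e` in `0 .. E-1`: the initial rate at epoch 0, the minimum at the
#' final epoch.
#'
#' @param epoch Zero-based epoch index (vectorised).
#' @param total_epochs Total epoch count `E`.
#' @param lr_max,lr_min Schedule endpoints.
#' @return Learning rate(s).
#' @examples
#' cosine_lr(0, 400)   # 1e-4
#' cosine_lr(399, 400) # 1e-5
#' @export
cosine_lr <- function(epoch, total_epochs, lr_max = 1e-4, lr_min = 1e-5) {
  if (total_epochs <= 1L) return(rep(lr_max, length(epoch)))
  lr_min + (lr_max - lr_min) * (1 + cos(pi * epoch / (total_epochs - 1))) / 2
}

# ---- Adam -----------------------------------------------------------------

adam_state <- function(model) {
  lapply(model$blocks, function(blk)
    list(m = lapply(blk$params, function(p) p * 0),
         v = lapply(blk$params, function(p) p * 0)))
}

adam_step <- function(model, state, lr, beta1, beta2, t, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (nm in names(model$blocks)) {
    blk <- model$blocks[[nm]]
    st <- state[[nm]]
    for (pn in names(blk$params)) {
      g <- blk$grads[[pn]]
      st$m[[pn]] <- beta1 * st$m[[pn]] + (1 - beta1) * g
      st$v[[pn]] <- beta2 * st$v[[pn]] + (1 - beta2) * g * g
      mhat <- st$m[[pn]] / bc1
      vhat <- st$v[[pn]] / bc2
      blk$params[[pn]] <- blk$params[[pn]] - lr * mhat / (sqrt(vhat) + eps)
    }
    state[[nm]] <- st
  }
  state
}

# stack a list of samples into a (N, C, H, W) batch plus (N, 1, H, W) masks
samples_to_batch <- function(samples, in_channels) {
  hw <- spatial_dims(samples[[1L]]$image)
  n <- length(samples)
  x <- array(0, dim = c(n, in_channels, hw[1L], hw[2L]))
  y <- array(0, dim = c(n, 1L, hw[1L], hw[2L]))
  for (i in seq_len(n)) {
    img <- samples[[i]]$image
    if (length(dim(img)) == 2L) {
      for (c_ in seq_len(in_channels)) x[i, c_, , ] <- img
    } else {
      x[i, , , ] <- img[seq_len(in_channels), , ]
    }
    y[i, 1L, , ] <- samples[[i]]$mask
  }
  list(x = x, y = y)
}

# single optimisation step on one batch; returns the loss
train_step <- function(model, batch, cfg, state, t, lr) {
  xt <- batch_to_ts(batch$x)
  logits <- model_forward(model, xt, train = TRUE)
  probs <- sigmoid(logits)
  tt <- batch_to_ts(batch$y)
  loss <- combined_loss(probs, tt, cfg$loss_weights)
  if (!is.finite(loss))
    stop("training diverged: non-finite loss at step ", t, call. = FALSE)
  dprob <- combined_loss_grad(probs, tt, cfg$loss_weights)
  dlogits <- dprob * probs * (1 - probs)   # chain through the sigmoid
  model_backward(model, dlogits)
  st <- adam_step(model, state, lr, cfg$beta1, cfg$beta2, t)
  list(loss = loss, state = st)
}

#' Train a segmentation model
#'
#' Mini-batch training with Adam and a cosine-annealed learning rate.
#' Per-epoch training loss and validation IoU/Dice are logged; the
#' weights with the best validation Dice are retained (and written to
#' `checkpoint` when given). Runs are fully reproducible for a fixed
#' config seed. A non-finite loss aborts with a diagnostic.
#'
#' @param model A [pisnet()] model (modified in place and returned).
#' @param train_samples,val_samples Lists of [segmentation_sample()]
#'   objects; when `val_samples` is `NULL` the training samples are also
#'   used for validation (a held-out split is preferable whenever the
#'   dataset allows one).
#' @param config A [train_config()].
#' @param checkpoint Optional path for the best-validation checkpoint.
#' @param verbose Print a line per epoch.
#' @return An object of class `"pisnet_fit"`: the trained model, the
#'   epoch log (`history`), per-step losses and the best epoch.
#' @export
pisnet_train <- function(model, train_samples, val_samples = NULL,
                         config = train_config(), checkpoint = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(model, "pisnet"), length(train_samples) >= 1L)
  cfg <- config
  if (is.null(val_samples)) val_samples <- train_samples
  state <- adam_state(model)
  n <- length(train_samples)
  history <- data.frame()
  step_losses <- numeric(0)
  best <- list(dice = -Inf, epoch = NA_integer_, params = NULL,
               buffers = NULL)
  t <- 0L
  with_local_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs) - 1L) {
      lr <- cosine_lr(epoch, cfg$epochs, cfg$learning_rate,
                      cfg$min_learning_rate)
      perm <- sample.int(n)
      epoch_loss <- 0
      nb <- 0L
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- perm[start:min(start + cfg$batch_size - 1L, n)]
        batch <- samples_to_batch(train_samples[idx],
                                  model$config$in_channels)
        t <- t + 1L
        r <- train_step(model, batch, cfg, state, t, lr)
        state <- r$state
        step_losses <- c(step_losses, r$loss)
        epoch_loss <- epoch_loss + r$loss
        nb <- nb + 1L
      }
      val <- evaluate_samples(model, val_samples)
      history <- rbind(history,
                       data.frame(epoch = epoch, lr = lr,
                                  train_loss = epoch_loss / nb,
                                  val_iou = val$summary[["mean_iou"]],
                                  val_dice = val$summary[["mean_dice"]]))
      if (val$summary[["mean_dice"]] > best$dice) {
        best <- list(dice = val$summary[["mean_dice"]], epoch = epoch,
                     params = model_params(model),
                     buffers = lapply(model$blocks, function(b) b$buffers))
      }
      if (verbose)
        message(sprintf("epoch %3d lr %.2e loss %.4f val dice %.4f",
                        epoch, lr, epoch_loss / nb,
                        val$summary[["mean_dice"]]))
    }
  })
  # restore the best-validation weights
  for (nm in names(model$blocks)) {
    blk <- model$blocks[[nm]]
    for (pn in names(blk$params))
      blk$params[[pn]] <- best$params[[paste(nm, pn, sep = ".")]]
    if (length(blk$buffers)) blk$buffers <- best$buffers[[nm]]
  }
  if (!is.null(checkpoint)) save_checkpoint(model, checkpoint)
  structure(list(model = model, history = history,
                 step_losses = step_losses, best_epoch = best$epoch,
                 config = cfg),
            class = "pisnet_fit")
}

#' Evaluate a model on samples
#'
#' Predicts every sample in evaluation mode and computes per-image and
#' mean IoU/Dice.
#'
#' @param model A [pisnet()] model or a checkpoint path.
#' @param samples List of [segmentation_sample()] objects.
#' @param threshold Binarisation threshold (default 0.5).
#' @return As [segmentation_metrics()].
#' @export
evaluate_samples <- function(model, samples, threshold = 0.5) {
  if (is.character(model)) model <- load_checkpoint(model)
  probs <- lapply(samples, function(s) {
    b <- samples_to_batch(list(s), model$config$in_channels)
    p <- predict(model, b$x)
    p[1L, 1L, , ]
  })
  masks <- lapply(samples, function(s) s$mask)
  segmentation_metrics(probs, masks,
                       ids = vapply(samples, function(s) s$id, character(1L)),
                       threshold = threshold)
}

#' @export
print.pisnet_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("Trained %d epochs (%d steps); best val Dice %.4f at epoch %d\n",
              nrow(h), length(x$step_losses), max(h$val_dice), x$best_epoch))
  invisible(x)
}

#' @export
summary.pisnet_fit <- function(object, ...) {
  print(object)
  print(utils::tail(object$history, 5L), row.names = FALSE)
  invisible(object$history)
}

#' Plot the training curves
#'
#' Training loss and validation Dice against the epoch index.
#'
#' @param x A `"pisnet_fit"` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pisnet_fit <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "training loss", ...)
  graphics::plot(h$epoch, h$val_dice, type = "l", xlab = "epoch",
                 ylab = "validation Dice", ...)
  invisible(x)
}
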