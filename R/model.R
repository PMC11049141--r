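# Model assembly: the five-stage encoder-decoder, its six ablation
# variants, forward/backward passes, prediction and parameter counting.

VARIANT_TABLE <- data.frame(
  variant = 1:6,
  label = c("U-Net (64-channel first stage)",
            "Conv stages + tokenized axial MLP (baseline)",
            "Conv stages + diagonal-axial MLP",
            "Conv stages + diagonal-axial MLP + DR-SPP",
            "Conv stages + diagonal-axial MLP + HBDS",
            "Conv stages + diagonal-axial MLP + DR-SPP + HBDS (full model)"),
  mlp_kind = c(NA, "tok", "da", "da", "da", "da"),
  use_drspp = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE),
  use_hbds = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
  stringsAsFactors = FALSE
)

#' Model configuration
#'
#' Describes one of the six architecture variants. The stage widths
#' default to the calibrated values `(16, 32, 128, 160, 256)`: three
#' convolutional stages followed by two tokenized MLP stages. The variant
#' id fully determines the stage kinds and which of the pyramid-pooling
#' (DR-SPP) and hybrid-downsampling (HBDS) modules are active:
#' 1 = classic U-Net, 2 = baseline with tokenized axial-MLP stages,
#' 3 = diagonal-axial MLP stages, 4 = 3 + DR-SPP, 5 = 3 + HBDS,
#' 6 = the full model (3 + DR-SPP + HBDS, plus the full-width
#' cross-branch mixer at the concatenated bottleneck).
#'
#' @param variant Integer 1-6.
#' @param input_size Nominal square input size in pixels, divisible by 32
#'   (16 for variant 1). Any compliant size can be fed at run time; the
#'   shift-window and pyramid geometries adapt.
#' @param in_channels 1 (grayscale) or 3 (RGB).
#' @param out_channels Fixed at 1 (binary masks).
#' @param widths Five increasing stage widths; defaults to the calibrated
#'   `(16, 32, 128, 160, 256)` (variant 1: `(64, 128, 256, 512, 1024)`).
#' @return A list of class `"pisnet_config"`.
#' @export
pisnet_config <- function(variant = 6L, input_size = 256L, in_channels = 1L,
                          widths = NULL, out_channels = 1L) {
  variant <- as.integer(variant)
  if (length(variant) != 1L || is.na(variant) || variant < 1L || variant > 6L)
    stop("variant must be an integer in 1..6", call. = FALSE)
  if (is.null(widths))
    widths <- if (variant == 1L) c(64L, 128L, 256L, 512L, 1024L)
              else c(16L, 32L, 128L, 160L, 256L)
  if (!in_channels %in% c(1L, 3L))
    stop("in_channels must be 1 or 3", call. = FALSE)
  if (out_channels != 1L) stop("out_channels is fixed at 1", call. = FALSE)
  if (length(widths) != 5L || any(diff(widths) <= 0))
    stop("widths must be 5 strictly increasing channel counts", call. = FALSE)
  div <- if (variant == 1L) 16L else 32L
  if (input_size %% div != 0L)
    stop("input_size must be divisible by ", div, call. = FALSE)
  row <- VARIANT_TABLE[variant, ]
  structure(list(variant = variant, input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 widths = as.integer(widths),
                 mlp_kind = row$mlp_kind, use_drspp = row$use_drspp,
                 use_hbds = row$use_hbds,
                 use_mixer = row$use_drspp && row$use_hbds,
                 label = row$label),
            class = "pisnet_config")
}

#' Build a segmentation model
#'
#' Constructs the encoder-decoder network of the requested ablation
#' variant: three convolutional stages (conv-BN-maxpool-ReLU), two
#' tokenized MLP stages entered through stride-2 token projections, a
#' decoder mirroring the encoder with bilinear upsampling and additive
#' skip connections, and a 1x1 output head producing one logit per pixel.
#' Variant 5/6 replace the plain stage-4 to stage-5 projection with the
#' hybrid downsampling transition (parallel max-pooled branch, channel
#' concat, squeeze); variants 4/6 insert dynamic residual spatial pyramid
#' pooling at the end of the encoder; variant 6 additionally mixes the
#' concatenated transition channels with a full-width axial-MLP block.
#'
#' @param variant Integer 1-6, or a full [pisnet_config()] via `config`.
#' @param config Optional [pisnet_config()]; overrides `variant`.
#' @param seed Optional integer seed making the weight initialisation
#'   reproducible.
#' @param ... Passed to [pisnet_config()] when `config` is not given.
#' @return An object of class `"pisnet"`.
#' @examples
#' m <- pisnet(2, input_size = 64, seed = 1)
#' count_trainable_parameters(m)
#' @export
pisnet <- function(variant = 6L, ..., config = NULL, seed = NULL) {
  cfg <- if (is.null(config)) pisnet_config(variant, ...) else config
  if (!is.null(seed)) set.seed(seed)
  blocks <- if (cfg$variant == 1L) unet_blocks(cfg) else hybrid_blocks(cfg)
  structure(list(config = cfg, blocks = blocks), class = "pisnet")
}

hybrid_blocks <- function(cfg) {
  w <- cfg$widths
  b <- list(
    enc1 = conv_stage(cfg$in_channels, w[1L]),
    enc2 = conv_stage(w[1L], w[2L]),
    enc3 = conv_stage(w[2L], w[3L]),
    pe3 = patch_embed(w[3L], w[4L]),
    blk4 = mlp_block(cfg$mlp_kind, w[4L]),
    norm3 = ln_block(w[4L]),
    pe4 = patch_embed(w[4L], w[5L]))
  if (cfg$use_hbds) {
    b$mixed <- mixed_branch(w[4L], w[5L])
    if (cfg$use_mixer) b$mixer <- tok_block(2L * w[5L])
    b$squeeze <- pw_block(2L * w[5L], w[5L])
  }
  b$blk5 <- mlp_block(cfg$mlp_kind, w[5L])
  b$norm4 <- ln_block(w[5L])
  if (cfg$use_drspp) b$drspp <- drspp_block(w[5L])
  b <- c(b, list(
    dec1 = up_stage(w[5L], w[4L]),
    dblk1 = mlp_block(cfg$mlp_kind, w[4L]),
    dnorm3 = ln_block(w[4L]),
    dec2 = up_stage(w[4L], w[3L]),
    dblk2 = mlp_block(cfg$mlp_kind, w[3L]),
    dnorm4 = ln_block(w[3L]),
    dec3 = up_stage(w[3L], w[2L]),
    dec4 = up_stage(w[2L], w[1L]),
    dec5 = up_stage(w[1L], w[1L]),
    final = pw_block(w[1L], cfg$out_channels)))
  b
}

mlp_block <- function(kind, C) {
  switch(kind, tok = tok_block(C), da = da_block(C),
         stop("unknown MLP block kind: ", kind))
}

unet_blocks <- function(cfg) {
  w <- cfg$widths
  list(e1 = double_conv(cfg$in_channels, w[1L]),
       e2 = double_conv(w[1L], w[2L]),
       e3 = double_conv(w[2L], w[3L]),
       e4 = double_conv(w[3L], w[4L]),
       bott = double_conv(w[4L], w[5L]),
       d1 = double_conv(w[5L] + w[4L], w[4L]),
       d2 = double_conv(w[4L] + w[3L], w[3L]),
       d3 = double_conv(w[3L] + w[2L], w[2L]),
       d4 = double_conv(w[2L] + w[1L], w[1L]),
       final = pw_block(w[1L], cfg$out_channels))
}

# ---- forward / backward ---------------------------------------------------

model_forward <- function(model, x, train = FALSE) {
  if (model$config$variant == 1L) unet_forward(model, x, train)
  else hybrid_forward(model, x, train)
}

hybrid_forward <- function(model, x, train) {
  b <- model$blocks
  cfg <- model$config
  t1 <- block_fwd(b$enc1, x, train)
  t2 <- block_fwd(b$enc2, t1, train)
  t3 <- block_fwd(b$enc3, t2, train)
  t4 <- block_fwd(b$norm3, block_fwd(b$blk4, block_fwd(b$pe3, t3, train),
                                     train), train)
  bt <- block_fwd(b$pe4, t4, train)
  if (cfg$use_hbds) {
    mx <- block_fwd(b$mixed, t4, train)
    bt <- cat_c(bt, mx)
    if (cfg$use_mixer) bt <- block_fwd(b$mixer, bt, train)
    bt <- block_fwd(b$squeeze, bt, train)
  }
  bt <- block_fwd(b$norm4, block_fwd(b$blk5, bt, train), train)
  if (cfg$use_drspp) bt <- block_fwd(b$drspp, bt, train)
  d1 <- block_fwd(b$dec1, bt, train) + t4
  d1 <- block_fwd(b$dnorm3, block_fwd(b$dblk1, d1, train), train)
  d2 <- block_fwd(b$dec2, d1, train) + t3
  d2 <- block_fwd(b$dnorm4, block_fwd(b$dblk2, d2, train), train)
  d3 <- block_fwd(b$dec3, d2, train) + t2
  d4 <- block_fwd(b$dec4, d3, train) + t1
  d5 <- block_fwd(b$dec5, d4, train)
  block_fwd(b$final, d5, train)
}

hybrid_backward <- function(model, dlogits) {
  b <- model$blocks
  cfg <- model$config
  d5 <- block_bwd(b$final, dlogits)
  d4 <- block_bwd(b$dec5, d5)
  dt1 <- d4
  d3 <- block_bwd(b$dec4, d4)
  dt2 <- d3
  d2 <- block_bwd(b$dec3, d3)
  d2 <- block_bwd(b$dblk2, block_bwd(b$dnorm4, d2))
  dt3 <- d2
  d1 <- block_bwd(b$dec2, d2)
  d1 <- block_bwd(b$dblk1, block_bwd(b$dnorm3, d1))
  dt4 <- d1
  dbt <- block_bwd(b$dec1, d1)
  if (cfg$use_drspp) dbt <- block_bwd(b$drspp, dbt)
  dbt <- block_bwd(b$blk5, block_bwd(b$norm4, dbt))
  if (cfg$use_hbds) {
    dbt <- block_bwd(b$squeeze, dbt)
    if (cfg$use_mixer) dbt <- block_bwd(b$mixer, dbt)
    w5 <- cfg$widths[5L]
    parts <- split_c(dbt, c(w5, w5))
    dbt <- parts[[1L]]
    dt4 <- dt4 + block_bwd(b$mixed, parts[[2L]])
  }
  dt4 <- dt4 + block_bwd(b$pe4, dbt)
  dt3 <- dt3 + block_bwd(b$pe3, block_bwd(b$blk4, block_bwd(b$norm3, dt4)))
  dt2 <- dt2 + block_bwd(b$enc3, dt3)
  dt1 <- dt1 + block_bwd(b$enc2, dt2)
  block_bwd(b$enc1, dt1)
}

unet_forward <- function(model, x, train) {
  b <- model$blocks
  e1 <- block_fwd(b$e1, x, train)
  p1 <- maxpool2_fwd(e1); b$e1$meta$pool <- p1
  e2 <- block_fwd(b$e2, p1$y, train)
  p2 <- maxpool2_fwd(e2); b$e2$meta$pool <- p2
  e3 <- block_fwd(b$e3, p2$y, train)
  p3 <- maxpool2_fwd(e3); b$e3$meta$pool <- p3
  e4 <- block_fwd(b$e4, p3$y, train)
  p4 <- maxpool2_fwd(e4); b$e4$meta$pool <- p4
  bt <- block_fwd(b$bott, p4$y, train)
  u1 <- upsample2_fwd(bt); b$bott$meta$up <- u1
  d1 <- block_fwd(b$d1, cat_c(u1$y, e4), train)
  u2 <- upsample2_fwd(d1); b$d1$meta$up <- u2
  d2 <- block_fwd(b$d2, cat_c(u2$y, e3), train)
  u3 <- upsample2_fwd(d2); b$d2$meta$up <- u3
  d3 <- block_fwd(b$d3, cat_c(u3$y, e2), train)
  u4 <- upsample2_fwd(d3); b$d3$meta$up <- u4
  d4 <- block_fwd(b$d4, cat_c(u4$y, e1), train)
  block_fwd(b$final, d4, train)
}

unet_backward <- function(model, dlogits) {
  b <- model$blocks
  w <- model$config$widths
  dd4 <- block_bwd(b$final, dlogits)
  dc4 <- block_bwd(b$d4, dd4)
  p <- split_c(dc4, c(w[2L], w[1L])); du4 <- p[[1L]]; de1 <- p[[2L]]
  dd3 <- upsample2_bwd(du4, b$d3$meta$up$Ar, b$d3$meta$up$Ac)
  dc3 <- block_bwd(b$d3, dd3)
  p <- split_c(dc3, c(w[3L], w[2L])); du3 <- p[[1L]]; de2 <- p[[2L]]
  dd2 <- upsample2_bwd(du3, b$d2$meta$up$Ar, b$d2$meta$up$Ac)
  dc2 <- block_bwd(b$d2, dd2)
  p <- split_c(dc2, c(w[4L], w[3L])); du2 <- p[[1L]]; de3 <- p[[2L]]
  dd1 <- upsample2_bwd(du2, b$d1$meta$up$Ar, b$d1$meta$up$Ac)
  dc1 <- block_bwd(b$d1, dd1)
  p <- split_c(dc1, c(w[5L], w[4L])); du1 <- p[[1L]]; de4 <- p[[2L]]
  dbt <- upsample2_bwd(du1, b$bott$meta$up$Ar, b$bott$meta$up$Ac)
  dp4 <- block_bwd(b$bott, dbt)
  de4 <- de4 + maxpool2_bwd(dp4, b$e4$meta$pool$arg, b$e4$meta$pool$H,
                            b$e4$meta$pool$W)
  dp3 <- block_bwd(b$e4, de4)
  de3 <- de3 + maxpool2_bwd(dp3, b$e3$meta$pool$arg, b$e3$meta$pool$H,
                            b$e3$meta$pool$W)
  dp2 <- block_bwd(b$e3, de3)
  de2 <- de2 + maxpool2_bwd(dp2, b$e2$meta$pool$arg, b$e2$meta$pool$H,
                            b$e2$meta$pool$W)
  dp1 <- block_bwd(b$e2, de2)
  de1 <- de1 + maxpool2_bwd(dp1, b$e1$meta$pool$arg, b$e1$meta$pool$H,
                            b$e1$meta$pool$W)
  block_bwd(b$e1, de1)
}

model_backward <- function(model, dlogits) {
  if (model$config$variant == 1L) unet_backward(model, dlogits)
  else hybrid_backward(model, dlogits)
}

# ---- parameters -----------------------------------------------------------

model_params <- function(model) {
  out <- list()
  for (nm in names(model$blocks)) {
    blk <- model$blocks[[nm]]
    for (pn in names(blk$params))
      out[[paste(nm, pn, sep = ".")]] <- blk$params[[pn]]
  }
  out
}

model_grads <- function(model) {
  out <- list()
  for (nm in names(model$blocks)) {
    blk <- model$blocks[[nm]]
    for (pn in names(blk$grads))
      out[[paste(nm, pn, sep = ".")]] <- blk$grads[[pn]]
  }
  out
}

#' Count trainable parameters
#'
#' Exact integer sum of element counts over every trainable weight array
#' (convolution kernels, linear maps, biases, normalisation scales and
#' shifts; batch-norm running statistics are not trainable and are not
#' counted).
#'
#' @param model A [pisnet()] model.
#' @return Integer parameter count.
#' @export
count_trainable_parameters <- function(model) {
  stopifnot(inherits(model, "pisnet"))
  sum(vapply(model_params(model), length, numeric(1L)))
}

# ---- prediction -----------------------------------------------------------

# images: numeric array (N, C, H, W) or (H, W) / (C, H, W) for one image
as_batch <- function(images, in_channels) {
  d <- dim(images)
  if (is.null(d)) stop("images must be an array", call. = FALSE)
  if (length(d) == 2L) dim(images) <- c(1L, 1L, d)
  else if (length(d) == 3L) dim(images) <- c(1L, d)
  d <- dim(images)
  if (d[2L] != in_channels)
    stop("batch has ", d[2L], " channels, model expects ", in_channels,
         call. = FALSE)
  images
}

batch_to_ts <- function(batch) aperm(batch, c(3L, 4L, 1L, 2L))
ts_to_batch <- function(x) aperm(x, c(3L, 4L, 1L, 2L))

#' Predict per-pixel foreground probabilities
#'
#' Runs the network in evaluation mode (deterministic for fixed weights:
#' batch norms use running statistics) and applies a sigmoid to the logit
#' map, so all values lie strictly in (0, 1).
#'
#' @param object A [pisnet()] model.
#' @param images Numeric array `(N, C, H, W)`; a single `(H, W)` or
#'   `(C, H, W)` image is promoted to a batch of one. `H` and `W` must be
#'   divisible by 32 (16 for variant 1).
#' @param type `"prob"` (default) for probabilities, `"logit"` for raw
#'   logits, `"mask"` for the 0/1 map thresholded at 0.5.
#' @param ... Unused.
#' @return Array `(N, 1, H, W)`.
#' @export
predict.pisnet <- function(object, images, type = c("prob", "logit", "mask"),
                           ...) {
  type <- match.arg(type)
  batch <- as_batch(images, object$config$in_channels)
  d <- dim(batch)
  div <- if (object$config$variant == 1L) 16L else 32L
  if (d[3L] %% div != 0L || d[4L] %% div != 0L)
    stop("spatial size must be divisible by ", div, call. = FALSE)
  logits <- ts_to_batch(model_forward(object, batch_to_ts(batch),
                                      train = FALSE))
  switch(type,
         logit = logits,
         prob = sigmoid(logits),
         mask = (sigmoid(logits) >= 0.5) * 1)
}

#' @export
print.pisnet <- function(x, ...) {
  cfg <- x$config
  cat("Point-of-care segmentation network\n")
  cat(sprintf("  variant %d: %s\n", cfg$variant, cfg$label))
  cat(sprintf("  input: %dx%d, %d channel(s); stage widths: %s\n",
              cfg$input_size, cfg$input_size, cfg$in_channels,
              paste(cfg$widths, collapse = "-")))
  np <- count_trainable_parameters(x)
  cat(sprintf("  trainable parameters: %s (%.2f M)\n",
              format(np, big.mark = ","), np / 1e6))
  invisible(x)
}

#' @export
summary.pisnet <- function(object, ...) {
  counts <- vapply(object$blocks, function(blk)
    sum(vapply(blk$params, length, numeric(1L))), numeric(1L))
  out <- data.frame(block = names(counts), parameters = as.integer(counts),
                    row.names = NULL)
  print.pisnet(object)
  cat("\n")
  print(out, row.names = FALSE)
  invisible(out)
}

#' @export
coef.pisnet <- function(object, ...) model_params(object)

# ---- checkpointing --------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint is a flat named-weight archive plus the model
#' configuration (also written alongside as JSON), sufficient to rebuild
#' the model bit-identically, including batch-norm running statistics.
#'
#' @param model A [pisnet()] model.
#' @param path File path for the checkpoint (`.rds`); a sibling
#'   `<path>.json` holds the human-readable configuration.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the rebuilt model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "pisnet"))
  buffers <- lapply(model$blocks, function(b) b$buffers)
  state <- list(config = unclass(model$config), params = model_params(model),
                buffers = buffers)
  saveRDS(state, path)
  jsonlite::write_json(unclass(model$config),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  state <- readRDS(path)
  cfg <- structure(state$config, class = "pisnet_config")
  model <- pisnet(config = cfg)
  for (nm in names(model$blocks)) {
    blk <- model$blocks[[nm]]
    for (pn in names(blk$params))
      blk$params[[pn]] <- state$params[[paste(nm, pn, sep = ".")]]
    if (length(blk$buffers)) blk$buffers <- state$buffers[[nm]]
  }
  model
}
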