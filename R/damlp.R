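# Public surface of the diagonal-axial MLP block.

#' Configure a diagonal-axial MLP block
#'
#' The diagonal-axial MLP block is a residual token mixer: a grouped
#' height shift introduces window locality, a pointwise linear projects
#' pixels-as-tokens, a depthwise 3x3 convolution encodes position, two
#' parameter-free diagonal content shifts (up-right and up-left, half a
#' window each) create overlapping windows along both diagonals, and a
#' fusion linear maps the concatenated `2C` channels back to `C` before
#' the residual addition.
#'
#' @param in_channels Input channel count `C`.
#' @param out_channels Output channel count; must equal `C` (ratio 1), `2C`
#'   or `4C` (downsampling ratios). Ratios above 1 imply a stride-2 block.
#' @param token_embed_dim Embedding width of the token projection; defaults
#'   to `out_channels`.
#' @param dwconv_kernel Odd kernel size of the depthwise positional
#'   encoding (default 3).
#' @param height_shift_offsets Integer per-group row offsets of the first
#'   shift (default `-2:2`, five groups).
#' @return A list of class `"damlp_config"`.
#' @export
damlp_config <- function(in_channels, out_channels = in_channels,
                         token_embed_dim = out_channels, dwconv_kernel = 3L,
                         height_shift_offsets = -2:2) {
  ratio <- out_channels / in_channels
  if (!ratio %in% c(1, 2, 4))
    stop("out_channels / in_channels must be 1, 2 or 4", call. = FALSE)
  if (dwconv_kernel %% 2L != 1L)
    stop("dwconv_kernel must be odd", call. = FALSE)
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 token_embed_dim = as.integer(token_embed_dim),
                 dwconv_kernel = as.integer(dwconv_kernel),
                 height_shift_offsets = as.integer(height_shift_offsets)),
            class = "damlp_config")
}

#' Build a diagonal-axial MLP block
#'
#' @param cfg A [damlp_config()]; ratio-1 configs give the residual
#'   stride-1 block, ratios 2 and 4 the stride-2 downsampling form.
#' @param seed Optional integer seed for reproducible initialisation.
#' @return A block object usable with [da_mlp_forward()].
#' @export
da_mlp_block <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "damlp_config"))
  if (!is.null(seed)) set.seed(seed)
  blk <- if (cfg$out_channels == cfg$in_channels) da_block(cfg$in_channels)
         else ds_da_block(cfg$in_channels, cfg$out_channels)
  blk$meta$cfg <- cfg
  blk
}

#' Run a diagonal-axial MLP block
#'
#' Applies the full pipeline of the block to a feature map: height shift,
#' token projection, position-encoding depthwise convolution, the two
#' diagonal branches concatenated to `2C` channels, the fusion linear and
#' (for ratio-1 blocks) the residual addition. Output shape equals input
#' shape for ratio-1 blocks.
#'
#' @param x A `(C, H, W)` feature map with `C` equal to the block's
#'   configured input channels.
#' @param block A block from [da_mlp_block()].
#' @param train Logical; use batch statistics (`TRUE`) or running
#'   statistics (`FALSE`) in the internal batch norm.
#' @return The output feature map.
#' @export
da_mlp_forward <- function(x, block, train = FALSE) {
  check_fm(x)
  cfg <- block$meta$cfg
  if (dim(x)[1L] != cfg$in_channels)
    stop("feature map has ", dim(x)[1L], " channels, block expects ",
         cfg$in_channels, call. = FALSE)
  ts_to_fm(block_fwd(block, fm_to_ts(x), train = train))
}

#' Enumerate the trainable weight arrays of a block or model
#'
#' @param x A block object or a [pisnet()] model.
#' @return Named list of numeric arrays (weights, biases, norm scales).
#' @export
weight_arrays <- function(x) {
  if (inherits(x, "pisnet_block")) return(x$params)
  if (inherits(x, "pisnet")) return(model_params(x))
  stop("no weight arrays for this object", call. = FALSE)
}
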