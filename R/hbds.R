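# Hybrid downsampling: parallel linear and max-pooled feature paths.

#' Configure the hybrid downsampler
#'
#' The hybrid downsampling module complements the purely linear token
#' projection path with a nonlinear max-pooled path. In its generic form
#' the linear branch stacks two downsampling diagonal-axial blocks with
#' channel ratio 1:2 each (`c -> 2c -> 4c`, spatial `/4`), the mixed
#' branch max-pools by 2 and applies one ratio-1:4 downsampling block
#' (`c -> 4c`, spatial `/4`), and the two branches are concatenated to
#' `8c` channels. An optional pointwise squeeze restores `4c` so a
#' mirrored decoder is unaffected.
#'
#' @param in_channels Input channel count `c`.
#' @param squeeze Logical; append the 1x1 squeeze `8c -> 4c` (default
#'   `FALSE`, exposing the raw `8c` concat).
#' @return A list of class `"hbds_config"`.
#' @export
hbds_config <- function(in_channels, squeeze = FALSE) {
  structure(list(in_channels = as.integer(in_channels), squeeze = squeeze),
            class = "hbds_config")
}

#' Build a hybrid downsampling module
#'
#' @param cfg An [hbds_config()].
#' @param seed Optional integer seed for reproducible initialisation.
#' @return A list of blocks of class `"hbds_module"`.
#' @export
hbds_module <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "hbds_config"))
  if (!is.null(seed)) set.seed(seed)
  c0 <- cfg$in_channels
  mod <- list(cfg = cfg,
              lin1 = ds_da_block(c0, 2L * c0),
              lin2 = ds_da_block(2L * c0, 4L * c0),
              mix = ds_da_block(c0, 4L * c0),
              squeeze = if (cfg$squeeze) pw_block(8L * c0, 4L * c0))
  class(mod) <- "hbds_module"
  mod
}

#' Run the hybrid downsampler
#'
#' The linear branch output `F_L` (first `4c` channels of the concat) is
#' the twice-downsampled token path; the mixed branch output `F_M` (last
#' `4c` channels) is the max-pooled path. Input height and width must be
#' divisible by 4.
#'
#' @param x A `(c, h, w)` feature map.
#' @param module An [hbds_module()].
#' @param train Logical; batch-norm mode as in [da_mlp_forward()].
#' @return A `(8c, h/4, w/4)` feature map (or `(4c, h/4, w/4)` when the
#'   module was built with `squeeze = TRUE`).
#' @export
hbds_forward <- function(x, module, train = FALSE) {
  check_fm(x)
  stopifnot(inherits(module, "hbds_module"))
  d <- dim(x)
  if (d[1L] != module$cfg$in_channels)
    stop("channel mismatch: map has ", d[1L], ", module expects ",
         module$cfg$in_channels, call. = FALSE)
  if (d[2L] %% 4L != 0L || d[3L] %% 4L != 0L)
    stop("height and width must be divisible by 4", call. = FALSE)
  xt <- fm_to_ts(x)
  fl <- block_fwd(module$lin2, block_fwd(module$lin1, xt, train), train)
  fm <- block_fwd(module$mix, maxpool2_fwd(xt)$y, train)
  if (!identical(dim(fl)[1:2], dim(fm)[1:2]))
    stop("branch spatial sizes disagree; invalid input size", call. = FALSE)
  out <- cat_c(fl, fm)
  if (!is.null(module$squeeze)) out <- block_fwd(module$squeeze, out, train)
  ts_to_fm(out)
}
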