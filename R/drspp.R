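# Dynamic residual spatial pyramid pooling.

#' Input-adaptive pyramid kernel sizes
#'
#' The three pyramid levels pool with stride 1 and kernel sizes that adapt
#' to the feature-map size: with `base = max(1, floor(floor(sqrt(H*W))/4))`
#' (a quarter of the geometric-mean side), level `i` uses
#' `k_i = odd(i * base)` where even values are rounded up to the next odd
#' integer, so same-padding `p_i = floor(k_i / 2)` preserves the spatial
#' size. At a 16x16 bottleneck this yields the classic 5/9/13 pyramid.
#'
#' @param H_prime,W_prime Feature-map height and width (positive).
#' @return List with integer vectors `kernels` and `paddings` (length 3).
#' @examples
#' drspp_kernels(16, 16) # kernels 5, 9, 13
#' drspp_kernels(8, 8)   # kernels 3, 5, 7
#' @export
drspp_kernels <- function(H_prime, W_prime) {
  if (H_prime < 1L || W_prime < 1L)
    stop("H and W must be positive", call. = FALSE)
  base <- max(1L, floor(floor(sqrt(H_prime * W_prime)) / 4))
  k <- vapply(1:3, function(i) {
    ki <- as.integer(i * base)
    if (ki %% 2L == 0L) ki + 1L else ki
  }, integer(1L))
  list(kernels = k, paddings = k %/% 2L)
}

#' Build a dynamic residual spatial pyramid pooling module
#'
#' Three parallel stride-1 max-pool branches (kernel sizes from
#' [drspp_kernels()], hence adapting to the input resolution at run time)
#' each followed by a 1x1 projection, plus a 3x3 convolutional residual
#' branch, concatenated to `4C'` channels and fused back to `C'` by a 3x3
#' convolution. The pooling layers themselves contribute no trainable
#' parameters.
#'
#' @param channels Channel count `C'` of the bottleneck feature map.
#' @param seed Optional integer seed for reproducible initialisation.
#' @return A block object usable with [drspp_forward()].
#' @export
drspp_module <- function(channels, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  drspp_block(as.integer(channels))
}

#' Run dynamic residual spatial pyramid pooling
#'
#' @param x A `(C', H', W')` feature map.
#' @param module A [drspp_module()].
#' @param train Unused (the module is norm-free); kept for interface
#'   symmetry.
#' @param return_concat Logical; also return the pre-fusion `(4C', H', W')`
#'   concatenation of pooled branches and residual.
#' @return The fused `(C', H', W')` feature map, or when
#'   `return_concat = TRUE` a list with `fused` and `concat`.
#' @export
drspp_forward <- function(x, module, train = FALSE, return_concat = FALSE) {
  check_fm(x)
  stopifnot(inherits(module, "pisnet_block"), module$type == "drspp")
  y <- block_fwd(module, fm_to_ts(x), train = train)
  if (!return_concat) return(ts_to_fm(y))
  cc <- module$cache
  list(fused = ts_to_fm(y),
       concat = ts_to_fm(cat_c(cc$c1$y, cc$c2$y, cc$c3$y, cc$rs$y)))
}

#' Raw pooled pyramid branches
#'
#' Returns the three stride-1 max-pooled maps themselves (before the 1x1
#' projections), useful for verifying the pooling geometry.
#'
#' @param x A `(C', H', W')` feature map.
#' @return List of three feature maps, same shape as `x`.
#' @export
drspp_pooled_branches <- function(x) {
  check_fm(x)
  d <- dim(x)
  ks <- drspp_kernels(d[2L], d[3L])$kernels
  xt <- fm_to_ts(x)
  lapply(ks, function(k) ts_to_fm(pool2d_s1_fwd(xt, k)$y))
}
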