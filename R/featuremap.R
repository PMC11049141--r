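# Feature maps and the elementary token-mixing operators.
#
# A feature map is a numeric array indexed (channel, row, col). The
# operators in this file are the building blocks of the diagonal-axial MLP
# stage: adaptive shift-window geometry, grouped height shifts, tokenized
# projection, depthwise positional encoding and the two diagonal content
# shifts.

#' Construct and validate a feature map
#'
#' A feature map is a finite numeric array with dimensions
#' (channels, height, width), the unit of data flowing between network
#' blocks.
#'
#' @param data Numeric array with `dim` of length 3, `(C, H, W)`, all values
#'   finite.
#' @return The validated array with class `"featuremap"`.
#' @examples
#' x <- featuremap(array(rnorm(2 * 4 * 4), dim = c(2, 4, 4)))
#' dim(x)
#' @export
featuremap <- function(data) {
  if (!is.numeric(data) || length(dim(data)) != 3L)
    stop("a feature map must be a numeric (C, H, W) array", call. = FALSE)
  if (any(dim(data) < 1L))
    stop("feature map dimensions must be strictly positive", call. = FALSE)
  if (!all(is.finite(data)))
    stop("feature map values must all be finite", call. = FALSE)
  structure(data, class = c("featuremap", class(data)))
}

# internal: (C,H,W) feature map <-> (H,W,N=1,C) tensor
fm_to_ts <- function(x) {
  d <- dim(x)
  y <- aperm(array(as.numeric(x), d), c(2L, 3L, 1L))
  dim(y) <- c(d[2L], d[3L], 1L, d[1L])
  y
}

ts_to_fm <- function(x) {
  d <- dim(x)
  stopifnot(d[3L] == 1L)
  y <- aperm(array(x, d[c(1L, 2L, 4L)]), c(3L, 1L, 2L))
  y
}

check_fm <- function(x) {
  if (inherits(x, "featuremap")) return(invisible(x))
  featuremap(x)
}

#' Adaptive shift-window geometry
#'
#' The MLP stage mixes features through windows slid along the two
#' diagonals. The window edge adapts to the feature-map size: one quarter of
#' the geometric-mean side length, `max(1, floor(floor(sqrt(H * W)) / 4))`,
#' with padding half the window. The shift distance applied by
#' [diagonal_shift()] is half the window size, so consecutive windows
#' overlap and exchange information.
#'
#' @param H,W Feature-map height and width in pixels (both >= 4).
#' @return A list with `window_size` and `pad` (pixels).
#' @examples
#' compute_shift_geometry(16, 16) # window 4, pad 2
#' compute_shift_geometry(5, 7)   # window 1, pad 0
#' @export
compute_shift_geometry <- function(H, W) {
  if (H < 1L || W < 1L) stop("H and W must be positive", call. = FALSE)
  window <- max(1L, floor(floor(sqrt(H * W)) / 4))
  list(window_size = as.integer(window), pad = as.integer(window %/% 2L))
}

#' Grouped vertical shift of a feature map
#'
#' Channels are partitioned into `length(offsets)` contiguous groups (sizes
#' as equal as possible, ceil-sized leading groups) and group `g` is
#' translated vertically by `offsets[g]` pixels, with zeros filling the
#' vacated rows. A positive offset moves content towards larger row
#' indices. This is the "shift in height" that gives the first MLP layer a
#' window-local receptive field.
#'
#' @param x A `(C, H, W)` feature map.
#' @param offsets Integer vector of per-group row offsets; every
#'   `|offset|` must be smaller than the height.
#' @return The shifted feature map, same shape.
#' @examples
#' x <- array(1:9, dim = c(1, 3, 3))
#' shift_height(x, 1)[1, , ] # rows (0, a, b)
#' @export
shift_height <- function(x, offsets) {
  check_fm(x)
  d <- dim(x)
  C <- d[1L]; H <- d[2L]
  offsets <- as.integer(offsets)
  if (any(abs(offsets) >= H))
    stop("|offset| must be smaller than the feature-map height", call. = FALSE)
  sizes <- chunk_sizes(C, length(offsets))
  out <- array(0, dim = d)
  at <- 0L
  for (g in seq_along(sizes)) {
    ch <- (at + 1L):(at + sizes[g])
    o <- offsets[g]
    if (o == 0L) {
      out[ch, , ] <- x[ch, , ]
    } else if (o > 0L) {
      out[ch, (1L + o):H, ] <- x[ch, 1L:(H - o), ]
    } else {
      out[ch, 1L:(H + o), ] <- x[ch, (1L - o):H, ]
    }
    at <- at + sizes[g]
  }
  out
}

#' Tokenized projection of a feature map
#'
#' Projects local patches into an embedding of `embed_dim` channels with a
#' 3x3 convolution; `stride = 2` halves the spatial size (used between
#' stages), `stride = 1` preserves it. The map is linear in its input when
#' the bias is zero.
#'
#' @param x A `(C, H, W)` feature map.
#' @param embed_dim Number of output channels (>= 1).
#' @param stride 1 or 2; spatial size must be divisible by the stride.
#' @param weights Optional projection parameters, as returned by
#'   [token_project_init()]; freshly initialised when omitted.
#' @return A `(embed_dim, H/stride, W/stride)` feature map with the
#'   parameters used attached as attribute `"weights"`.
#' @export
token_project <- function(x, embed_dim, stride = 1L, weights = NULL) {
  check_fm(x)
  d <- dim(x)
  if (embed_dim < 1L) stop("embed_dim must be >= 1", call. = FALSE)
  if (!stride %in% c(1L, 2L)) stop("stride must be 1 or 2", call. = FALSE)
  if (d[2L] %% stride != 0L || d[3L] %% stride != 0L)
    stop("spatial size must be divisible by the stride", call. = FALSE)
  if (is.null(weights)) weights <- token_project_init(d[1L], embed_dim)
  r <- conv2d_fwd(fm_to_ts(x), weights$w, weights$b, stride = as.integer(stride))
  out <- ts_to_fm(r$y)
  attr(out, "weights") <- weights
  out
}

#' @rdname token_project
#' @param in_channels Number of input channels.
#' @param seed Optional integer seed for reproducible initialisation.
#' @export
token_project_init <- function(in_channels, embed_dim, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  list(w = he_init(c(3L, 3L, in_channels, embed_dim)),
       b = numeric(embed_dim))
}

#' Depthwise positional encoding
#'
#' Applies one independent 3x3 spatial kernel per channel (a depthwise
#' convolution). Because zero padding breaks translation symmetry at the
#' borders, the operation encodes absolute position implicitly, at a cost
#' of only `9C + C` parameters; each output channel depends on the same
#' input channel only.
#'
#' @param x A `(C, H, W)` feature map.
#' @param weights Optional list with `w` (3 x 3 x C) and `b` (length C);
#'   freshly initialised when omitted.
#' @return Feature map of identical shape, parameters attached as
#'   attribute `"weights"`.
#' @export
dwconv_encode <- function(x, weights = NULL) {
  check_fm(x)
  C <- dim(x)[1L]
  if (is.null(weights))
    weights <- list(w = he_init(c(3L, 3L, C), fan_in = 9), b = numeric(C))
  r <- dwconv_fwd(fm_to_ts(x), weights$w, weights$b)
  out <- ts_to_fm(r$y)
  attr(out, "weights") <- weights
  out
}

#' Diagonal content shift
#'
#' Realises the two diagonally slid window branches as content
#' translations: windows moved from the bottom-left towards the top-right
#' corner (`"lr"`) translate the map up-and-right by `s = floor(window/2)`
#' pixels; windows moved from the bottom-right towards the top-left
#' (`"rl"`) translate up-and-left. Vacated positions are zero-filled. The
#' half-window distance makes consecutive windows overlap, which is what
#' couples neighbouring windows.
#'
#' @param x A `(C, H, W)` feature map.
#' @param spec Shift geometry from [compute_shift_geometry()]; computed
#'   from the map size when omitted.
#' @param direction `"lr"` (up-and-right) or `"rl"` (up-and-left).
#' @param inverse Apply the inverse translation instead (routes content
#'   back; the adjoint used during backpropagation). Content farther than
#'   the shift distance from every border survives a shift followed by
#'   its inverse exactly.
#' @return The translated feature map, same shape.
#' @examples
#' x <- array(0, dim = c(1, 4, 4)); x[1, 3, 2] <- 1
#' which(diagonal_shift(x, list(window_size = 2, pad = 1), "lr") == 1)
#' @export
diagonal_shift <- function(x, spec = NULL, direction = c("lr", "rl"),
                           inverse = FALSE) {
  check_fm(x)
  direction <- match.arg(direction)
  d <- dim(x)
  if (is.null(spec)) spec <- compute_shift_geometry(d[2L], d[3L])
  s <- spec$window_size %/% 2L
  dc <- if (direction == "lr") s else -s
  dr <- -s
  if (inverse) { dr <- -dr; dc <- -dc }
  ts_to_fm(shift_hw(fm_to_ts(x), dr = dr, dc = dc))
}

#' Halving max pool
#'
#' 2x2 max pooling with stride 2: each output value is the maximum of its
#' 2x2 input block. Used by the nonlinear branch of the hybrid
#' downsampling stage.
#'
#' @param x A `(C, H, W)` feature map with even height and width.
#' @return A `(C, H/2, W/2)` feature map.
#' @examples
#' max_pool_halve(array(1:4, dim = c(1, 2, 2)))
#' @export
max_pool_halve <- function(x) {
  check_fm(x)
  d <- dim(x)
  if (d[2L] %% 2L != 0L || d[3L] %% 2L != 0L)
    stop("height and width must be even", call. = FALSE)
  ts_to_fm(maxpool2_fwd(fm_to_ts(x))$y)
}

# He-style initialisation for conv / linear weight arrays
he_init <- function(dims, fan_in = NULL) {
  if (is.null(fan_in)) {
    fan_in <- if (length(dims) == 4L) dims[1L] * dims[2L] * dims[3L]
              else if (length(dims) == 3L) dims[1L] * dims[2L]
              else dims[1L]
  }
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}
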