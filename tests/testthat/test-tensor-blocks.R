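# Elementary operators of the diagonal-axial MLP stage.

test_that("shift-window geometry follows the quarter-side rule", {
  expect_equal(compute_shift_geometry(16, 16), list(window_size = 4L, pad = 2L))
  expect_equal(compute_shift_geometry(8, 8), list(window_size = 2L, pad = 1L))
  expect_equal(compute_shift_geometry(5, 7), list(window_size = 1L, pad = 0L))
  expect_error(compute_shift_geometry(0, 8), "positive")
})

test_that("height shift translates channel groups with zero fill", {
  x <- array(0, dim = c(1, 3, 3))
  x[1, 1, ] <- 1; x[1, 2, ] <- 2; x[1, 3, ] <- 3   # rows a, b, c
  y <- shift_height(x, 1L)
  expect_equal(y[1, 1, ], rep(0, 3))
  expect_equal(y[1, 2, ], rep(1, 3))
  expect_equal(y[1, 3, ], rep(2, 3))

  z <- rand_fm(4, 6, 5)
  expect_equal(shift_height(z, c(0L, 0L)), z)

  w <- rand_fm(3, 5, 5)
  s <- shift_height(w, c(-1L, 0L, 1L))
  expect_equal(s[2, , ], w[2, , ])                        # middle unchanged
  expect_equal(s[1, 1:4, ], w[1, 2:5, ])                  # shifted up
  expect_equal(s[1, 5, ], rep(0, 5))
  expect_equal(s[3, 2:5, ], w[3, 1:4, ])                  # shifted down
  expect_equal(s[3, 1, ], rep(0, 5))

  expect_error(shift_height(w, 5L), "smaller than")
})

test_that("token projection honours its shape and linearity contract", {
  w <- token_project_init(8L, 32L, seed = 1L)
  x <- rand_fm(8, 16, 16)
  y <- token_project(x, 32L, stride = 2L, weights = w)
  expect_equal(dim(y), c(32L, 8L, 8L))

  z <- token_project(array(0, dim = c(8, 16, 16)), 32L, 2L, weights = w)
  expect_equal(max(abs(z)), 0)                            # zero bias, zero in

  y2 <- token_project(2.5 * x, 32L, 2L, weights = w)
  expect_equal(as.numeric(y2), 2.5 * as.numeric(y), tolerance = 1e-12)

  expect_error(token_project(rand_fm(8, 15, 16), 32L, 2L), "divisible")
})

test_that("depthwise encoding is shape-preserving and channel-separable", {
  x <- rand_fm(6, 12, 12, seed = 2)
  set.seed(3)
  y <- dwconv_encode(x)
  w <- attr(y, "weights")
  expect_equal(dim(y), dim(x))

  x2 <- x
  x2[4, , ] <- x2[4, , ] + rnorm(144)
  y2 <- dwconv_encode(x2, weights = w)
  changed <- vapply(1:6, function(c_) any(abs(y2[c_, , ] - y[c_, , ]) > 1e-12),
                    logical(1))
  expect_equal(changed, 1:6 == 4)

  idw <- list(w = array(0, dim = c(3, 3, 6)), b = numeric(6))
  idw$w[2, 2, ] <- 1
  expect_equal(as.numeric(dwconv_encode(x, weights = idw)), as.numeric(x))
})

test_that("diagonal shifts translate content by half a window", {
  x <- array(0, dim = c(1, 4, 4))
  x[1, 3, 2] <- 1                                          # row 2, col 1 (0-based)
  spec <- list(window_size = 2L, pad = 1L)                 # s = 1
  lr <- diagonal_shift(x, spec, "lr")
  expect_equal(lr[1, 2, 3], 1)                             # row 1, col 2
  expect_equal(sum(lr), 1)
  rl <- diagonal_shift(x, spec, "rl")
  expect_equal(rl[1, 2, 1], 1)                             # row 1, col 0
  expect_equal(sum(rl), 1)

  z <- array(0, dim = c(2, 5, 5))
  expect_equal(diagonal_shift(z, spec, "lr"), z, ignore_attr = TRUE)
  expect_equal(diagonal_shift(z, spec, "rl"), z, ignore_attr = TRUE)
})

test_that("diagonal shift agrees with brute-force index remapping", {
  set.seed(11)
  for (rep in 1:5) {
    x <- rand_fm(1, 8, 8, seed = rep)
    spec <- compute_shift_geometry(8, 8)
    s <- spec$window_size %/% 2L
    lr <- diagonal_shift(x, spec, "lr")
    rl <- diagonal_shift(x, spec, "rl")
    # out[c, r, k] = in[c, r + s, k - s] (lr), zero outside
    for (r in 1:8) for (k in 1:8) {
      elr <- if (r + s <= 8 && k - s >= 1) x[1, r + s, k - s] else 0
      erl <- if (r + s <= 8 && k + s <= 8) x[1, r + s, k + s] else 0
      expect_identical(lr[1, r, k], elr)
      expect_identical(rl[1, r, k], erl)
    }
  }
})

test_that("interior content survives a diagonal shift and its inverse", {
  spec <- compute_shift_geometry(12, 12)                   # window 3, s = 1
  s <- spec$window_size %/% 2L
  x <- array(0, dim = c(2, 12, 12))
  x[, (2 + s):(11 - s), (2 + s):(11 - s)] <-
    rnorm(2 * length((2 + s):(11 - s))^2)
  for (dir in c("lr", "rl")) {
    back <- diagonal_shift(diagonal_shift(x, spec, dir), spec, dir,
                           inverse = TRUE)
    expect_equal(back, x, ignore_attr = TRUE)
  }
})

test_that("the diagonal-axial block preserves shape and its residual path", {
  cfg <- damlp_config(32L)
  blk <- da_mlp_block(cfg, seed = 5L)
  x <- rand_fm(32, 16, 16, seed = 6)
  y <- da_mlp_forward(x, blk)
  expect_equal(dim(y), c(32L, 16L, 16L))

  # zeroed fusion linear turns the block into the identity
  blk$params$w2[] <- 0
  blk$params$b2[] <- 0
  expect_equal(as.numeric(da_mlp_forward(x, blk)), as.numeric(x),
               tolerance = 1e-12)

  expect_error(da_mlp_forward(rand_fm(16, 16, 16), blk), "channels")
})

test_that("block parameter count equals the enumerated weight arrays", {
  blk <- da_mlp_block(damlp_config(32L), seed = 1L)
  arrays <- weight_arrays(blk)
  enumerated <- sum(vapply(arrays, length, numeric(1)))
  # independent oracle: count each constituent array from its known shape
  C <- 32L
  by_shape <- (2 * C) + (C * C + C) + (2 * C) + (9 * C + C) + (2 * C * C + C)
  expect_identical(enumerated, as.numeric(by_shape))
  # parameters are untouched by evaluating the block (no hidden state)
  x <- rand_fm(32, 8, 8)
  before <- unlist(arrays)
  invisible(da_mlp_forward(x, blk))
  expect_identical(unlist(weight_arrays(blk)), before)
})

test_that("block output dims equal input dims across random sizes", {
  set.seed(4)
  for (rep in 1:4) {
    C <- sample(c(5L, 8L, 12L), 1)
    H <- sample(c(6L, 10L, 16L), 1)
    W <- sample(c(6L, 12L, 20L), 1)
    blk <- da_mlp_block(damlp_config(C))
    y <- da_mlp_forward(rand_fm(C, H, W, seed = rep), blk)
    expect_equal(dim(y), c(C, H, W))
  }
})
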