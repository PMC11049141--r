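# Low-level tensor kernels.
#
# Activation tensors are numeric arrays with dim (H, W, N, C): spatial and
# batch axes first, channels last, so that matrix(x, H*W*N, C) exposes
# channels as columns and every pointwise / convolutional op reduces to
# BLAS matrix products. All kernels come in forward/backward pairs; the
# backward of every op is the exact adjoint of its forward (verified by
# finite differences in the test suite).

ts_dims <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 4L)
  d
}

ts_zeros <- function(H, W, N, C) array(0, dim = c(H, W, N, C))

as_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1L] * d[2L] * d[3L], d[4L])
  x
}

as_ts <- function(m, H, W, N, C) {
  dim(m) <- c(H, W, N, C)
  m
}

# zero padding / cropping on the two spatial axes
pad_hw <- function(x, p, value = 0) {
  if (p == 0L) return(x)
  d <- ts_dims(x)
  out <- array(value, dim = c(d[1L] + 2L * p, d[2L] + 2L * p, d[3L], d[4L]))
  out[(p + 1L):(p + d[1L]), (p + 1L):(p + d[2L]), , ] <- x
  out
}

crop_hw <- function(x, p, H, W) {
  if (p == 0L) return(x)
  x[(p + 1L):(p + H), (p + 1L):(p + W), , , drop = FALSE]
}

# content translation with zero fill: out[r, c] = in[r - dr, c - dc]
shift_hw <- function(x, dr, dc) {
  d <- ts_dims(x)
  H <- d[1L]; W <- d[2L]
  if (abs(dr) >= H || abs(dc) >= W) return(ts_zeros(d[1L], d[2L], d[3L], d[4L]))
  out <- ts_zeros(d[1L], d[2L], d[3L], d[4L])
  rdst <- max(1L, 1L + dr):min(H, H + dr)
  cdst <- max(1L, 1L + dc):min(W, W + dc)
  out[rdst, cdst, , ] <- x[rdst - dr, cdst - dc, , , drop = FALSE]
  out
}

# torch.chunk-style channel partition: ceil-sized chunks, short remainder last
chunk_sizes <- function(C, groups) {
  size <- ceiling(C / groups)
  full <- C %/% size
  rem <- C - full * size
  c(rep(size, full), if (rem > 0L) rem)
}

# ---- dense 2-D convolution (stride 1 or 2, same padding) -----------------

conv2d_fwd <- function(x, w, b, stride = 1L) {
  d <- ts_dims(x)
  H <- d[1L]; W <- d[2L]; N <- d[3L]; Cin <- d[4L]
  k <- dim(w)[1L]
  Cout <- dim(w)[4L]
  p <- (k - 1L) %/% 2L
  xp <- pad_hw(x, p)
  out <- matrix(0, H * W * N, Cout)
  for (dh in seq_len(k)) {
    for (dw in seq_len(k)) {
      win <- xp[dh:(dh + H - 1L), dw:(dw + W - 1L), , , drop = FALSE]
      out <- out + as_mat(win) %*% matrix(w[dh, dw, , ], Cin, Cout)
    }
  }
  out <- out + rep(b, each = H * W * N)
  y <- as_ts(out, H, W, N, Cout)
  if (stride == 2L) y <- y[seq(1L, H, 2L), seq(1L, W, 2L), , , drop = FALSE]
  list(y = y, xp = xp)
}

conv2d_bwd <- function(dy, xp, w, stride = 1L) {
  k <- dim(w)[1L]
  Cin <- dim(w)[3L]
  Cout <- dim(w)[4L]
  p <- (k - 1L) %/% 2L
  dp <- dim(xp)
  H <- dp[1L] - 2L * p; W <- dp[2L] - 2L * p; N <- dp[3L]
  if (stride == 2L) {
    full <- ts_zeros(H, W, N, Cout)
    full[seq(1L, H, 2L), seq(1L, W, 2L), , ] <- dy
    dy <- full
  }
  dym <- as_mat(dy)
  db <- colSums(dym)
  dw_ <- array(0, dim = dim(w))
  dxp <- array(0, dim = dp)
  for (dh in seq_len(k)) {
    for (dw in seq_len(k)) {
      win <- xp[dh:(dh + H - 1L), dw:(dw + W - 1L), , , drop = FALSE]
      dw_[dh, dw, , ] <- crossprod(as_mat(win), dym)
      dwin <- dym %*% t(matrix(w[dh, dw, , ], Cin, Cout))
      dxp[dh:(dh + H - 1L), dw:(dw + W - 1L), , ] <-
        dxp[dh:(dh + H - 1L), dw:(dw + W - 1L), , , drop = FALSE] +
        as_ts(dwin, H, W, N, Cin)
    }
  }
  list(dx = crop_hw(dxp, p, H, W), dw = dw_, db = db)
}

# ---- depthwise 3x3 convolution (one spatial kernel per channel) ----------

dwconv_fwd <- function(x, w, b) {
  d <- ts_dims(x)
  H <- d[1L]; W <- d[2L]; N <- d[3L]; C <- d[4L]
  k <- dim(w)[1L]
  p <- (k - 1L) %/% 2L
  xp <- pad_hw(x, p)
  out <- matrix(0, H * W * N, C)
  for (dh in seq_len(k)) {
    for (dw in seq_len(k)) {
      win <- xp[dh:(dh + H - 1L), dw:(dw + W - 1L), , , drop = FALSE]
      out <- out + t(t(as_mat(win)) * w[dh, dw, ])
    }
  }
  out <- out + rep(b, each = H * W * N)
  list(y = as_ts(out, H, W, N, C), xp = xp)
}

dwconv_bwd <- function(dy, xp, w) {
  k <- dim(w)[1L]
  p <- (k - 1L) %/% 2L
  dp <- dim(xp)
  H <- dp[1L] - 2L * p; W <- dp[2L] - 2L * p
  dym <- as_mat(dy)
  db <- colSums(dym)
  dw_ <- array(0, dim = dim(w))
  dxp <- array(0, dim = dp)
  C <- dp[4L]
  for (dh in seq_len(k)) {
    for (dw in seq_len(k)) {
      win <- xp[dh:(dh + H - 1L), dw:(dw + W - 1L), , , drop = FALSE]
      dw_[dh, dw, ] <- colSums(as_mat(win) * dym)
      dwin <- t(t(dym) * w[dh, dw, ])
      dxp[dh:(dh + H - 1L), dw:(dw + W - 1L), , ] <-
        dxp[dh:(dh + H - 1L), dw:(dw + W - 1L), , , drop = FALSE] +
        as_ts(dwin, H, W, dp[3L], C)
    }
  }
  list(dx = crop_hw(dxp, p, H, W), dw = dw_, db = db)
}

# ---- normalisation --------------------------------------------------------

bn_fwd <- function(x, gamma, beta, run_mean, run_var, train, eps = 1e-5,
                   momentum = 0.1) {
  xm <- as_mat(x)
  m <- nrow(xm)
  if (train) {
    mu <- colMeans(xm)
    xc <- t(t(xm) - mu)
    v <- colMeans(xc * xc)
    new_mean <- (1 - momentum) * run_mean + momentum * mu
    unbias <- if (m > 1L) m / (m - 1L) else 1
    new_var <- (1 - momentum) * run_var + momentum * v * unbias
  } else {
    mu <- run_mean
    v <- run_var
    xc <- t(t(xm) - mu)
    new_mean <- run_mean
    new_var <- run_var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- t(t(xc) * inv)
  y <- t(t(xhat) * gamma + beta)
  d <- dim(x)
  list(y = as_ts(y, d[1L], d[2L], d[3L], d[4L]), xhat = xhat, inv = inv,
       run_mean = new_mean, run_var = new_var)
}

bn_bwd <- function(dy, xhat, inv, gamma, train) {
  dym <- as_mat(dy)
  m <- nrow(dym)
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  if (train) {
    dxm <- t((t(dym) - dbeta / m) * gamma * inv) - t(t(xhat) * (dgamma * gamma * inv / m))
  } else {
    dxm <- t(t(dym) * (gamma * inv))
  }
  d <- dim(dy)
  list(dx = as_ts(dxm, d[1L], d[2L], d[3L], d[4L]), dgamma = dgamma,
       dbeta = dbeta)
}

# layer norm across the channel axis at each spatial/batch position
ln_fwd <- function(x, gamma, beta, eps = 1e-6) {
  xm <- as_mat(x)
  C <- ncol(xm)
  mu <- rowMeans(xm)
  xc <- xm - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- t(t(xhat) * gamma + beta)
  d <- dim(x)
  list(y = as_ts(y, d[1L], d[2L], d[3L], d[4L]), xhat = xhat, inv = inv)
}

ln_bwd <- function(dy, xhat, inv, gamma) {
  dym <- as_mat(dy)
  C <- ncol(dym)
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  dxhat <- t(t(dym) * gamma)
  dxm <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  d <- dim(dy)
  list(dx = as_ts(dxm, d[1L], d[2L], d[3L], d[4L]), dgamma = dgamma,
       dbeta = dbeta)
}

# ---- activations ----------------------------------------------------------

relu_fwd <- function(x) {
  mask <- x > 0
  list(y = x * mask, mask = mask)
}

gelu_fwd <- function(x) {
  ph <- stats::pnorm(x)
  list(y = x * ph, x = x, ph = ph)
}

gelu_bwd <- function(dy, x, ph) dy * (ph + x * stats::dnorm(x))

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- pooling --------------------------------------------------------------

# 2x2 max pool, stride 2; argmax retained for gradient routing (first-max ties)
maxpool2_fwd <- function(x) {
  d <- ts_dims(x)
  H <- d[1L]; W <- d[2L]
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  ro <- seq(1L, H, 2L); re <- ro + 1L
  co <- seq(1L, W, 2L); ce <- co + 1L
  cand <- list(x[ro, co, , , drop = FALSE], x[ro, ce, , , drop = FALSE],
               x[re, co, , , drop = FALSE], x[re, ce, , , drop = FALSE])
  y <- cand[[1L]]
  arg <- array(1L, dim = dim(y))
  for (i in 2:4) {
    upd <- cand[[i]] > y
    y[upd] <- cand[[i]][upd]
    arg[upd] <- i
  }
  list(y = y, arg = arg, H = H, W = W)
}

maxpool2_bwd <- function(dy, arg, H, W) {
  d <- dim(dy)
  dx <- ts_zeros(H, W, d[3L], d[4L])
  ro <- seq(1L, H, 2L); re <- ro + 1L
  co <- seq(1L, W, 2L); ce <- co + 1L
  idx <- list(list(ro, co), list(ro, ce), list(re, co), list(re, ce))
  for (i in 1:4) {
    m <- dy * (arg == i)
    dx[idx[[i]][[1L]], idx[[i]][[2L]], , ] <-
      dx[idx[[i]][[1L]], idx[[i]][[2L]], , , drop = FALSE] + m
  }
  dx
}

# stride-1 max pool along the first axis, kernel k, same padding (-Inf fill)
pool1d_s1_fwd <- function(x, k) {
  d <- ts_dims(x)
  H <- d[1L]
  p <- (k - 1L) %/% 2L
  xp <- if (p > 0L) {
    tmp <- array(-Inf, dim = c(H + 2L * p, d[2L], d[3L], d[4L]))
    tmp[(p + 1L):(p + H), , , ] <- x
    tmp
  } else x
  y <- xp[1L:H, , , , drop = FALSE]
  arg <- array(0L, dim = d)
  for (off in seq_len(k - 1L)) {
    cand <- xp[(1L + off):(H + off), , , , drop = FALSE]
    upd <- cand > y
    y[upd] <- cand[upd]
    arg[upd] <- off
  }
  list(y = y, arg = arg, p = p, H = H)
}

pool1d_s1_bwd <- function(dy, arg, k, p, H) {
  d <- dim(dy)
  dxp <- array(0, dim = c(H + 2L * p, d[2L], d[3L], d[4L]))
  for (off in 0L:(k - 1L)) {
    m <- dy * (arg == off)
    dxp[(1L + off):(H + off), , , ] <-
      dxp[(1L + off):(H + off), , , , drop = FALSE] + m
  }
  if (p > 0L) dxp[(p + 1L):(p + H), , , , drop = FALSE] else dxp
}

perm_hw <- function(x) aperm(x, c(2L, 1L, 3L, 4L))

# stride-1 k x k max pool with same padding; separable (max over rows, then
# columns), with per-pass argmax kept for the backward routing
pool2d_s1_fwd <- function(x, k) {
  if (k == 1L) return(list(y = x, k = 1L))
  r <- pool1d_s1_fwd(x, k)
  xt <- perm_hw(r$y)
  c_ <- pool1d_s1_fwd(xt, k)
  list(y = perm_hw(c_$y), k = k, row = r, col = c_)
}

pool2d_s1_bwd <- function(dy, cache) {
  if (cache$k == 1L) return(dy)
  dyt <- perm_hw(dy)
  dxt <- pool1d_s1_bwd(dyt, cache$col$arg, cache$k, cache$col$p, cache$col$H)
  dx1 <- perm_hw(dxt)
  pool1d_s1_bwd(dx1, cache$row$arg, cache$k, cache$row$p, cache$row$H)
}

# ---- bilinear interpolation ----------------------------------------------

# dense interpolation matrix (half-pixel centres, edge-clamped), n_out x n_in
interp_matrix <- function(n_out, n_in) {
  A <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * scale + 0.5
    lo <- floor(src)
    a <- src - lo
    lo <- min(max(lo, 1L), n_in)
    hi <- min(lo + 1L, n_in)
    if (src < 1) { lo <- 1L; hi <- 1L; a <- 0 }
    A[i, lo] <- A[i, lo] + (1 - a)
    A[i, hi] <- A[i, hi] + a
  }
  A
}

apply_rows <- function(x, A) {
  d <- ts_dims(x)
  y <- A %*% matrix(x, d[1L], d[2L] * d[3L] * d[4L])
  array(y, dim = c(nrow(A), d[2L], d[3L], d[4L]))
}

bilinear_resize <- function(x, H2, W2) {
  d <- ts_dims(x)
  Ar <- interp_matrix(H2, d[1L])
  Ac <- interp_matrix(W2, d[2L])
  y <- apply_rows(x, Ar)
  perm_hw(apply_rows(perm_hw(y), Ac))
}

upsample2_fwd <- function(x) {
  d <- ts_dims(x)
  Ar <- interp_matrix(2L * d[1L], d[1L])
  Ac <- interp_matrix(2L * d[2L], d[2L])
  y <- perm_hw(apply_rows(perm_hw(apply_rows(x, Ar)), Ac))
  list(y = y, Ar = Ar, Ac = Ac)
}

upsample2_bwd <- function(dy, Ar, Ac) {
  apply_rows(perm_hw(apply_rows(perm_hw(dy), t(Ac))), t(Ar))
}

# ---- channel concat / split ----------------------------------------------

cat_c <- function(...) {
  xs <- list(...)
  d <- ts_dims(xs[[1L]])
  Cs <- vapply(xs, function(z) dim(z)[4L], integer(1L))
  out <- array(0, dim = c(d[1L], d[2L], d[3L], sum(Cs)))
  at <- 0L
  for (x in xs) {
    C <- dim(x)[4L]
    out[, , , (at + 1L):(at + C)] <- x
    at <- at + C
  }
  out
}

split_c <- function(x, Cs) {
  out <- vector("list", length(Cs))
  at <- 0L
  for (i in seq_along(Cs)) {
    out[[i]] <- x[, , , (at + 1L):(at + Cs[i]), drop = FALSE]
    at <- at + Cs[i]
  }
  out
}
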