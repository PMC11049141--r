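# Network blocks: parameterised building units with explicit
# forward/backward pairs. Each block is an environment holding `params`
# (named numeric arrays), `grads` (filled by the backward pass), `buffers`
# (batch-norm running statistics) and `cache` (forward intermediates used
# by the backward pass). Blocks are assembled into models in model.R.

new_block <- function(type, params, buffers = list(), meta = list()) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- params
  e$grads <- lapply(params, function(p) p * 0)
  e$buffers <- buffers
  e$meta <- meta
  e$cache <- NULL
  class(e) <- "pisnet_block"
  e
}

zero_grads <- function(blk) {
  blk$grads <- lapply(blk$params, function(p) p * 0)
  invisible(blk)
}

bn_params <- function(C) list(gamma = rep(1, C), beta = numeric(C))
bn_buffers <- function(C) list(mean = numeric(C), var = rep(1, C))
ln_params <- function(C) list(gamma = rep(1, C), beta = numeric(C))

# grouped zero-fill shift along rows (axis = "h") or columns (axis = "w");
# backward is the same op with negated offsets
shift_groups <- function(x, offsets, axis = "h") {
  d <- ts_dims(x)
  sizes <- chunk_sizes(d[4L], length(offsets))
  out <- array(0, dim = d)
  at <- 0L
  for (g in seq_along(sizes)) {
    ch <- (at + 1L):(at + sizes[g])
    o <- offsets[g]
    seg <- x[, , , ch, drop = FALSE]
    out[, , , ch] <- if (axis == "h") shift_hw(seg, o, 0L) else shift_hw(seg, 0L, o)
    at <- at + sizes[g]
  }
  out
}

AXIAL_OFFSETS <- -2:2

# ---- convolutional encoder / decoder stages ------------------------------

conv_stage <- function(cin, cout) {
  new_block("conv_stage",
            params = c(list(w = he_init(c(3L, 3L, cin, cout)), b = numeric(cout)),
                       bn_params(cout)),
            buffers = bn_buffers(cout))
}

conv_stage_fwd <- function(blk, x, train) {
  cv <- conv2d_fwd(x, blk$params$w, blk$params$b)
  bn <- bn_fwd(cv$y, blk$params$gamma, blk$params$beta,
               blk$buffers$mean, blk$buffers$var, train)
  if (train) { blk$buffers$mean <- bn$run_mean; blk$buffers$var <- bn$run_var }
  pl <- maxpool2_fwd(bn$y)
  rl <- relu_fwd(pl$y)
  blk$cache <- list(cv = cv, bn = bn, pl = pl, rl = rl, train = train)
  rl$y
}

conv_stage_bwd <- function(blk, dy) {
  cc <- blk$cache
  d1 <- dy * cc$rl$mask
  d2 <- maxpool2_bwd(d1, cc$pl$arg, cc$pl$H, cc$pl$W)
  bb <- bn_bwd(d2, cc$bn$xhat, cc$bn$inv, blk$params$gamma, cc$train)
  cb <- conv2d_bwd(bb$dx, cc$cv$xp, blk$params$w)
  blk$grads <- list(w = cb$dw, b = cb$db, gamma = bb$dgamma, beta = bb$dbeta)
  cb$dx
}

up_stage <- function(cin, cout) {
  new_block("up_stage",
            params = c(list(w = he_init(c(3L, 3L, cin, cout)), b = numeric(cout)),
                       bn_params(cout)),
            buffers = bn_buffers(cout))
}

up_stage_fwd <- function(blk, x, train) {
  cv <- conv2d_fwd(x, blk$params$w, blk$params$b)
  bn <- bn_fwd(cv$y, blk$params$gamma, blk$params$beta,
               blk$buffers$mean, blk$buffers$var, train)
  if (train) { blk$buffers$mean <- bn$run_mean; blk$buffers$var <- bn$run_var }
  up <- upsample2_fwd(bn$y)
  rl <- relu_fwd(up$y)
  blk$cache <- list(cv = cv, bn = bn, up = up, rl = rl, train = train)
  rl$y
}

up_stage_bwd <- function(blk, dy) {
  cc <- blk$cache
  d1 <- dy * cc$rl$mask
  d2 <- upsample2_bwd(d1, cc$up$Ar, cc$up$Ac)
  bb <- bn_bwd(d2, cc$bn$xhat, cc$bn$inv, blk$params$gamma, cc$train)
  cb <- conv2d_bwd(bb$dx, cc$cv$xp, blk$params$w)
  blk$grads <- list(w = cb$dw, b = cb$db, gamma = bb$dgamma, beta = bb$dbeta)
  cb$dx
}

# ---- stage-transition token projection (patch embedding) -----------------

patch_embed <- function(cin, cout) {
  new_block("patch_embed",
            params = c(list(w = he_init(c(3L, 3L, cin, cout)), b = numeric(cout)),
                       ln_params(cout)))
}

patch_embed_fwd <- function(blk, x, train) {
  cv <- conv2d_fwd(x, blk$params$w, blk$params$b, stride = 2L)
  ln <- ln_fwd(cv$y, blk$params$gamma, blk$params$beta)
  blk$cache <- list(cv = cv, ln = ln)
  ln$y
}

patch_embed_bwd <- function(blk, dy) {
  cc <- blk$cache
  lb <- ln_bwd(dy, cc$ln$xhat, cc$ln$inv, blk$params$gamma)
  cb <- conv2d_bwd(lb$dx, cc$cv$xp, blk$params$w, stride = 2L)
  blk$grads <- list(w = cb$dw, b = cb$db, gamma = lb$dgamma, beta = lb$dbeta)
  cb$dx
}

# ---- tokenized axial-MLP block (baseline mixer) --------------------------
# residual block: LN -> width shift -> fc1 -> DWConv -> GELU -> height
# shift -> fc2 -> + input. Pointwise linears treat pixels as tokens.

tok_block <- function(C) {
  new_block("tok_block",
            params = c(ln_params(C),
                       list(w1 = he_init(c(1L, 1L, C, C)), b1 = numeric(C),
                            wd = he_init(c(3L, 3L, C), fan_in = 9), bd = numeric(C),
                            w2 = he_init(c(1L, 1L, C, C)), b2 = numeric(C))))
}

tok_block_fwd <- function(blk, x, train) {
  p <- blk$params
  ln <- ln_fwd(x, p$gamma, p$beta)
  s1 <- shift_groups(ln$y, AXIAL_OFFSETS, axis = "w")
  f1 <- conv2d_fwd(s1, p$w1, p$b1)
  dw <- dwconv_fwd(f1$y, p$wd, p$bd)
  gl <- gelu_fwd(dw$y)
  s2 <- shift_groups(gl$y, AXIAL_OFFSETS, axis = "h")
  f2 <- conv2d_fwd(s2, p$w2, p$b2)
  blk$cache <- list(ln = ln, f1 = f1, dw = dw, gl = gl, f2 = f2)
  x + f2$y
}

tok_block_bwd <- function(blk, dy) {
  cc <- blk$cache
  p <- blk$params
  c2 <- conv2d_bwd(dy, cc$f2$xp, p$w2)
  ds2 <- shift_groups(c2$dx, -AXIAL_OFFSETS, axis = "h")
  dgl <- gelu_bwd(ds2, cc$gl$x, cc$gl$ph)
  db <- dwconv_bwd(dgl, cc$dw$xp, p$wd)
  c1 <- conv2d_bwd(db$dx, cc$f1$xp, p$w1)
  ds1 <- shift_groups(c1$dx, -AXIAL_OFFSETS, axis = "w")
  lb <- ln_bwd(ds1, cc$ln$xhat, cc$ln$inv, p$gamma)
  blk$grads <- list(gamma = lb$dgamma, beta = lb$dbeta,
                    w1 = c1$dw, b1 = c1$db, wd = db$dw, bd = db$db,
                    w2 = c2$dw, b2 = c2$db)
  dy + lb$dx
}

# ---- diagonal-axial MLP block --------------------------------------------
# residual block: LN -> height shift -> fc1 -> BN -> GELU -> DWConv ->
# {diagonal shift lr, diagonal shift rl} -> channel concat (2C) ->
# fc2 (2C -> C) -> + input. The two diagonal branches are parameter-free
# translations; all trainable weight sits in the shared layers and the
# fusion linear. Parameter slots: gL/bL layer norm, gB/bB batch norm.

da_block <- function(C) {
  new_block("da_block",
            params = list(gL = rep(1, C), bL = numeric(C),
                          w1 = he_init(c(1L, 1L, C, C)), b1 = numeric(C),
                          gB = rep(1, C), bB = numeric(C),
                          wd = he_init(c(3L, 3L, C), fan_in = 9), bd = numeric(C),
                          w2 = he_init(c(1L, 1L, 2L * C, C)), b2 = numeric(C)),
            buffers = bn_buffers(C))
}

# shared trunk of the stride-1 and downsampling variants: projected
# features -> BN -> GELU -> DWConv -> dual diagonal shift -> fusion linear
da_core_fwd <- function(blk, y0, train) {
  p <- blk$params
  bn <- bn_fwd(y0, p$gB, p$bB, blk$buffers$mean, blk$buffers$var, train)
  if (train) { blk$buffers$mean <- bn$run_mean; blk$buffers$var <- bn$run_var }
  gl <- gelu_fwd(bn$y)
  dw <- dwconv_fwd(gl$y, p$wd, p$bd)
  d <- ts_dims(dw$y)
  s <- compute_shift_geometry(d[1L], d[2L])$window_size %/% 2L
  lr <- shift_hw(dw$y, -s, s)
  rl <- shift_hw(dw$y, -s, -s)
  f2 <- conv2d_fwd(cat_c(lr, rl), p$w2, p$b2)
  list(y = f2$y, bn = bn, gl = gl, dw = dw, f2 = f2, s = s, train = train)
}

da_core_bwd <- function(blk, core, dy) {
  p <- blk$params
  c2 <- conv2d_bwd(dy, core$f2$xp, p$w2)
  C <- dim(core$dw$y)[4L]
  parts <- split_c(c2$dx, c(C, C))
  s <- core$s
  ddw <- shift_hw(parts[[1L]], s, -s) + shift_hw(parts[[2L]], s, s)
  db <- dwconv_bwd(ddw, core$dw$xp, p$wd)
  dgl <- gelu_bwd(db$dx, core$gl$x, core$gl$ph)
  bb <- bn_bwd(dgl, core$bn$xhat, core$bn$inv, p$gB, core$train)
  list(dy0 = bb$dx,
       grads = list(gB = bb$dgamma, bB = bb$dbeta, wd = db$dw, bd = db$db,
                    w2 = c2$dw, b2 = c2$db))
}

da_block_fwd <- function(blk, x, train) {
  p <- blk$params
  ln <- ln_fwd(x, p$gL, p$bL)
  sh <- shift_groups(ln$y, AXIAL_OFFSETS, axis = "h")
  f1 <- conv2d_fwd(sh, p$w1, p$b1)
  core <- da_core_fwd(blk, f1$y, train)
  blk$cache <- list(ln = ln, f1 = f1, core = core)
  x + core$y
}

da_block_bwd <- function(blk, dy) {
  cc <- blk$cache
  p <- blk$params
  cb <- da_core_bwd(blk, cc$core, dy)
  c1 <- conv2d_bwd(cb$dy0, cc$f1$xp, p$w1)
  dsh <- shift_groups(c1$dx, -AXIAL_OFFSETS, axis = "h")
  lb <- ln_bwd(dsh, cc$ln$xhat, cc$ln$inv, p$gL)
  blk$grads <- c(list(gL = lb$dgamma, bL = lb$dbeta, w1 = c1$dw, b1 = c1$db),
                 cb$grads)
  dy + lb$dx
}

# ---- downsampling diagonal-axial block (used by the generic hybrid
# downsampler): stride-2 3x3 token projection sets the channel ratio and
# halves the spatial size; no residual (shapes differ across the block)

ds_da_block <- function(cin, cout) {
  new_block("ds_da_block",
            params = list(gL = rep(1, cin), bL = numeric(cin),
                          w1 = he_init(c(3L, 3L, cin, cout)), b1 = numeric(cout),
                          gB = rep(1, cout), bB = numeric(cout),
                          wd = he_init(c(3L, 3L, cout), fan_in = 9),
                          bd = numeric(cout),
                          w2 = he_init(c(1L, 1L, 2L * cout, cout)),
                          b2 = numeric(cout)),
            buffers = bn_buffers(cout))
}

ds_da_block_fwd <- function(blk, x, train) {
  p <- blk$params
  ln <- ln_fwd(x, p$gL, p$bL)
  sh <- shift_groups(ln$y, AXIAL_OFFSETS, axis = "h")
  f1 <- conv2d_fwd(sh, p$w1, p$b1, stride = 2L)
  core <- da_core_fwd(blk, f1$y, train)
  blk$cache <- list(ln = ln, f1 = f1, core = core)
  core$y
}

ds_da_block_bwd <- function(blk, dy) {
  cc <- blk$cache
  p <- blk$params
  cb <- da_core_bwd(blk, cc$core, dy)
  c1 <- conv2d_bwd(cb$dy0, cc$f1$xp, p$w1, stride = 2L)
  dsh <- shift_groups(c1$dx, -AXIAL_OFFSETS, axis = "h")
  lb <- ln_bwd(dsh, cc$ln$xhat, cc$ln$inv, p$gL)
  blk$grads <- c(list(gL = lb$dgamma, bL = lb$dbeta, w1 = c1$dw, b1 = c1$db),
                 cb$grads)
  lb$dx
}

# ---- hybrid-downsampling mixed branch: 2x2 max pool, then a
# depthwise-separable projection (3x3 depthwise + pointwise linear) with BN

mixed_branch <- function(cin, cout) {
  new_block("mixed_branch",
            params = c(list(wd = he_init(c(3L, 3L, cin), fan_in = 9),
                            bd = numeric(cin),
                            w = he_init(c(1L, 1L, cin, cout)), b = numeric(cout)),
                       bn_params(cout)),
            buffers = bn_buffers(cout))
}

mixed_branch_fwd <- function(blk, x, train) {
  p <- blk$params
  pl <- maxpool2_fwd(x)
  dw <- dwconv_fwd(pl$y, p$wd, p$bd)
  pw <- conv2d_fwd(dw$y, p$w, p$b)
  bn <- bn_fwd(pw$y, p$gamma, p$beta, blk$buffers$mean, blk$buffers$var, train)
  if (train) { blk$buffers$mean <- bn$run_mean; blk$buffers$var <- bn$run_var }
  blk$cache <- list(pl = pl, dw = dw, pw = pw, bn = bn, train = train)
  bn$y
}

mixed_branch_bwd <- function(blk, dy) {
  cc <- blk$cache
  p <- blk$params
  bb <- bn_bwd(dy, cc$bn$xhat, cc$bn$inv, p$gamma, cc$train)
  cw <- conv2d_bwd(bb$dx, cc$pw$xp, p$w)
  db <- dwconv_bwd(cw$dx, cc$dw$xp, p$wd)
  dx <- maxpool2_bwd(db$dx, cc$pl$arg, cc$pl$H, cc$pl$W)
  blk$grads <- list(wd = db$dw, bd = db$db, w = cw$dw, b = cw$db,
                    gamma = bb$dgamma, beta = bb$dbeta)
  dx
}

# ---- plain pointwise (1x1) convolution block ------------------------------

pw_block <- function(cin, cout, kernel = 1L) {
  new_block("pw_block",
            params = list(w = he_init(c(kernel, kernel, cin, cout)),
                          b = numeric(cout)))
}

pw_block_fwd <- function(blk, x, train) {
  cv <- conv2d_fwd(x, blk$params$w, blk$params$b)
  blk$cache <- list(cv = cv)
  cv$y
}

pw_block_bwd <- function(blk, dy) {
  cb <- conv2d_bwd(dy, blk$cache$cv$xp, blk$params$w)
  blk$grads <- list(w = cb$dw, b = cb$db)
  cb$dx
}

# ---- dynamic residual spatial pyramid pooling -----------------------------
# three stride-1 max-pool branches with input-adaptive odd kernels, each
# followed by a 1x1 projection; a 3x3 convolutional residual branch; channel
# concat to 4C'; 3x3 fusion back to C'.

drspp_block <- function(C) {
  new_block("drspp",
            params = list(wb1 = he_init(c(1L, 1L, C, C)), bb1 = numeric(C),
                          wb2 = he_init(c(1L, 1L, C, C)), bb2 = numeric(C),
                          wb3 = he_init(c(1L, 1L, C, C)), bb3 = numeric(C),
                          wr = he_init(c(3L, 3L, C, C)), br = numeric(C),
                          wf = he_init(c(3L, 3L, 4L * C, C)), bf = numeric(C)))
}

drspp_block_fwd <- function(blk, x, train) {
  p <- blk$params
  d <- ts_dims(x)
  ks <- drspp_kernels(d[1L], d[2L])$kernels
  p1 <- pool2d_s1_fwd(x, ks[1L]); c1 <- conv2d_fwd(p1$y, p$wb1, p$bb1)
  p2 <- pool2d_s1_fwd(x, ks[2L]); c2 <- conv2d_fwd(p2$y, p$wb2, p$bb2)
  p3 <- pool2d_s1_fwd(x, ks[3L]); c3 <- conv2d_fwd(p3$y, p$wb3, p$bb3)
  rs <- conv2d_fwd(x, p$wr, p$br)
  fu <- conv2d_fwd(cat_c(c1$y, c2$y, c3$y, rs$y), p$wf, p$bf)
  blk$cache <- list(p1 = p1, p2 = p2, p3 = p3, c1 = c1, c2 = c2, c3 = c3,
                    rs = rs, fu = fu, C = d[4L])
  fu$y
}

drspp_block_bwd <- function(blk, dy) {
  cc <- blk$cache
  p <- blk$params
  fb <- conv2d_bwd(dy, cc$fu$xp, p$wf)
  parts <- split_c(fb$dx, rep(cc$C, 4L))
  b1 <- conv2d_bwd(parts[[1L]], cc$c1$xp, p$wb1)
  b2 <- conv2d_bwd(parts[[2L]], cc$c2$xp, p$wb2)
  b3 <- conv2d_bwd(parts[[3L]], cc$c3$xp, p$wb3)
  rb <- conv2d_bwd(parts[[4L]], cc$rs$xp, p$wr)
  dx <- pool2d_s1_bwd(b1$dx, cc$p1) + pool2d_s1_bwd(b2$dx, cc$p2) +
    pool2d_s1_bwd(b3$dx, cc$p3) + rb$dx
  blk$grads <- list(wb1 = b1$dw, bb1 = b1$db, wb2 = b2$dw, bb2 = b2$db,
                    wb3 = b3$dw, bb3 = b3$db, wr = rb$dw, br = rb$db,
                    wf = fb$dw, bf = fb$db)
  dx
}

# ---- standalone layer norm (stage outputs) --------------------------------

ln_block <- function(C) new_block("ln_block", params = ln_params(C))

ln_block_fwd <- function(blk, x, train) {
  r <- ln_fwd(x, blk$params$gamma, blk$params$beta)
  blk$cache <- r
  r$y
}

ln_block_bwd <- function(blk, dy) {
  r <- ln_bwd(dy, blk$cache$xhat, blk$cache$inv, blk$params$gamma)
  blk$grads <- list(gamma = r$dgamma, beta = r$dbeta)
  r$dx
}

# ---- classic double 3x3 conv (U-Net stages) -------------------------------

double_conv <- function(cin, cout) {
  new_block("double_conv",
            params = list(w1 = he_init(c(3L, 3L, cin, cout)), b1 = numeric(cout),
                          g1 = rep(1, cout), be1 = numeric(cout),
                          w2 = he_init(c(3L, 3L, cout, cout)), b2 = numeric(cout),
                          g2 = rep(1, cout), be2 = numeric(cout)),
            buffers = list(mean1 = numeric(cout), var1 = rep(1, cout),
                           mean2 = numeric(cout), var2 = rep(1, cout)))
}

double_conv_fwd <- function(blk, x, train) {
  p <- blk$params
  c1 <- conv2d_fwd(x, p$w1, p$b1)
  n1 <- bn_fwd(c1$y, p$g1, p$be1, blk$buffers$mean1, blk$buffers$var1, train)
  r1 <- relu_fwd(n1$y)
  c2 <- conv2d_fwd(r1$y, p$w2, p$b2)
  n2 <- bn_fwd(c2$y, p$g2, p$be2, blk$buffers$mean2, blk$buffers$var2, train)
  r2 <- relu_fwd(n2$y)
  if (train) {
    blk$buffers$mean1 <- n1$run_mean; blk$buffers$var1 <- n1$run_var
    blk$buffers$mean2 <- n2$run_mean; blk$buffers$var2 <- n2$run_var
  }
  blk$cache <- list(c1 = c1, n1 = n1, r1 = r1, c2 = c2, n2 = n2, r2 = r2,
                    train = train)
  r2$y
}

double_conv_bwd <- function(blk, dy) {
  cc <- blk$cache
  p <- blk$params
  d2 <- dy * cc$r2$mask
  b2 <- bn_bwd(d2, cc$n2$xhat, cc$n2$inv, p$g2, cc$train)
  k2 <- conv2d_bwd(b2$dx, cc$c2$xp, p$w2)
  d1 <- k2$dx * cc$r1$mask
  b1 <- bn_bwd(d1, cc$n1$xhat, cc$n1$inv, p$g1, cc$train)
  k1 <- conv2d_bwd(b1$dx, cc$c1$xp, p$w1)
  blk$grads <- list(w1 = k1$dw, b1 = k1$db, g1 = b1$dgamma, be1 = b1$dbeta,
                    w2 = k2$dw, b2 = k2$db, g2 = b2$dgamma, be2 = b2$dbeta)
  k1$dx
}

# ---- dispatch -------------------------------------------------------------

block_fwd <- function(blk, x, train = FALSE) {
  switch(blk$type,
         conv_stage = conv_stage_fwd(blk, x, train),
         up_stage = up_stage_fwd(blk, x, train),
         patch_embed = patch_embed_fwd(blk, x, train),
         tok_block = tok_block_fwd(blk, x, train),
         da_block = da_block_fwd(blk, x, train),
         ds_da_block = ds_da_block_fwd(blk, x, train),
         mixed_branch = mixed_branch_fwd(blk, x, train),
         pw_block = pw_block_fwd(blk, x, train),
         drspp = drspp_block_fwd(blk, x, train),
         ln_block = ln_block_fwd(blk, x, train),
         double_conv = double_conv_fwd(blk, x, train),
         stop("unknown block type: ", blk$type))
}

block_bwd <- function(blk, dy) {
  switch(blk$type,
         conv_stage = conv_stage_bwd(blk, dy),
         up_stage = up_stage_bwd(blk, dy),
         patch_embed = patch_embed_bwd(blk, dy),
         tok_block = tok_block_bwd(blk, dy),
         da_block = da_block_bwd(blk, dy),
         ds_da_block = ds_da_block_bwd(blk, dy),
         mixed_branch = mixed_branch_bwd(blk, dy),
         pw_block = pw_block_bwd(blk, dy),
         drspp = drspp_block_bwd(blk, dy),
         ln_block = ln_block_bwd(blk, dy),
         double_conv = double_conv_bwd(blk, dy),
         stop("unknown block type: ", blk$type))
}
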