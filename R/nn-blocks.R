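# Building blocks of the segmentation network: convolution + batchnorm +
# ReLU units, residual blocks, spatial and channel attention, and their
# fusion (SCAB) with a residual variant (RSCAB).
#
# Parameters are kept in environments so the optimizer can update weights
# in place and batch-norm running statistics persist across forward
# passes.  Each block has an internal *_fw / *_bw pair operating on the
# (H, W, B, C) layout, plus an exported single-map wrapper taking the
# conventional channels-first (G, P, Q) feature-map array.

new_penv <- function(...) list2env(list(...), parent = emptyenv())

conv_params <- function(k, c_in, c_out, zero = FALSE) {
  W <- if (zero) matrix(0, k * k * c_in, c_out)
       else matrix(init_weights(c(k * k * c_in, c_out), kernel_size = k,
                                prev_kernels = c_in),
                   k * k * c_in, c_out)
  new_penv(W = W, b = numeric(c_out), k = as.integer(k),
           c_in = as.integer(c_in), c_out = as.integer(c_out))
}

bn_params <- function(c_out, eps = 1e-5) {
  new_penv(gamma = rep(1, c_out), beta = numeric(c_out),
           run_mean = numeric(c_out), run_var = rep(1, c_out), eps = eps)
}

# --- convolution + batchnorm + ReLU unit -----------------------------------

cbr_params <- function(k, c_in, c_out) {
  list(conv = conv_params(k, c_in, c_out), bn = bn_params(c_out))
}

cbr_fw <- function(p, x, training) {
  cv <- conv2d_fw(x, p$conv$W, p$conv$b, p$conv$k)
  pe <- p$bn
  bn <- bn_fw(cv$out, pe$gamma, pe$beta, pe$run_mean, pe$run_var,
              training, eps = pe$eps)
  if (training) {
    pe$run_mean <- bn$run_mean
    pe$run_var <- bn$run_var
  }
  rl <- relu_fw(bn$out)
  list(out = rl$out, cv = cv, bn = bn, rl = rl)
}

cbr_bw <- function(p, cache, gout) {
  g <- relu_bw(cache$rl, gout)
  gb <- bn_bw(cache$bn, g, p$bn$gamma)
  gc <- conv2d_bw(cache$cv, gb$dx, p$conv$W)
  list(dx = gc$dx,
       grads = list(conv = list(W = gc$dW, b = gc$db),
                    bn = list(gamma = gb$dgamma, beta = gb$dbeta)))
}

# --- residual block ---------------------------------------------------------

#' Residual block parameters
#'
#' Creates the weights of a residual block: a residual branch of two
#' convolution + batch-normalization + ReLU layers, plus a 1x1 projection
#' convolution on the identity path when the channel counts differ (or
#' when forced), so the element-wise addition type-checks.
#'
#' @param in_channels,out_channels Input/output channel counts.
#' @param kernel_size Side of the residual-branch convolution kernels in
#'   pixels (default 3; even sizes are supported with left-biased padding).
#' @param force_projection Insert the 1x1 projection even when
#'   `in_channels == out_channels`.
#' @return A parameter list consumable by [residual_block()].
#' @export
residual_block_params <- function(in_channels, out_channels, kernel_size = 3L,
                                  force_projection = FALSE) {
  if (in_channels < 1L || out_channels < 1L)
    stop("channel counts must be >= 1")
  p <- list(cbr1 = cbr_params(kernel_size, in_channels, out_channels),
            cbr2 = cbr_params(kernel_size, out_channels, out_channels))
  if (in_channels != out_channels || force_projection)
    p$proj <- conv_params(1L, in_channels, out_channels)
  p
}

rb_fw <- function(p, x, training) {
  u1 <- cbr_fw(p$cbr1, x, training)
  u2 <- cbr_fw(p$cbr2, u1$out, training)
  if (!is.null(p$proj)) {
    pj <- conv2d_fw(x, p$proj$W, p$proj$b, 1L)
    out <- u2$out + pj$out
  } else {
    pj <- NULL
    out <- u2$out + x
  }
  list(out = out, u1 = u1, u2 = u2, pj = pj)
}

rb_bw <- function(p, cache, gout) {
  g2 <- cbr_bw(p$cbr2, cache$u2, gout)
  g1 <- cbr_bw(p$cbr1, cache$u1, g2$dx)
  grads <- list(cbr1 = g1$grads, cbr2 = g2$grads)
  if (!is.null(p$proj)) {
    gp <- conv2d_bw(cache$pj, gout, p$proj$W)
    dx <- g1$dx + gp$dx
    grads$proj <- list(W = gp$dW, b = gp$db)
  } else {
    dx <- g1$dx + gout
  }
  list(dx = dx, grads = grads)
}

# --- spatial attention ------------------------------------------------------

#' Spatial attention parameters
#'
#' The spatial gate is computed from the channel-wise mean and max maps
#' passed through a single `kernel_size` convolution and a sigmoid, the
#' standard convolutional spatial-attention construction.
#'
#' @param kernel_size Side of the gate convolution kernel (default 7).
#' @return Parameter list for [spatial_attention()].
#' @export
spatial_attention_params <- function(kernel_size = 7L) {
  list(conv = conv_params(kernel_size, 2L, 1L))
}

sa_fw <- function(p, x, training) {
  cp <- chanpool_fw(x)
  cv <- conv2d_fw(cp$out, p$conv$W, p$conv$b, p$conv$k)
  sg <- sigmoid_fw(cv$out)
  gt <- gate_spatial_fw(x, sg$out)
  list(out = gt$out, gate = sg$out, cp = cp, cv = cv, sg = sg, gt = gt)
}

sa_bw <- function(p, cache, gout) {
  gg <- gate_spatial_bw(cache$gt, gout)
  gs <- sigmoid_bw(cache$sg, gg$dg)
  gc <- conv2d_bw(cache$cv, gs, p$conv$W)
  dx <- gg$dx + chanpool_bw(cache$cp, gc$dx)
  list(dx = dx, grads = list(conv = list(W = gc$dW, b = gc$db)))
}

# --- channel attention ------------------------------------------------------

#' Channel attention parameters
#'
#' Global max- and average-pooled channel descriptors are passed through a
#' shared two-layer bottleneck (hidden width `channels / reduction`) whose
#' outputs are summed and squashed by a sigmoid into a per-channel gate.
#'
#' @param channels Number of input channels G.
#' @param reduction Bottleneck reduction ratio; `channels %/% reduction`
#'   must be at least 1.
#' @return Parameter list for [channel_attention()].
#' @export
channel_attention_params <- function(channels, reduction = 8L) {
  hidden <- channels %/% reduction
  if (hidden < 1L)
    stop("channel attention reduction ratio ", reduction,
         " leaves no hidden unit for ", channels, " channels")
  list(mlp = new_penv(
    W1 = matrix(init_weights(c(channels, hidden), kernel_size = 1L,
                             prev_kernels = channels), channels, hidden),
    b1 = numeric(hidden),
    W2 = matrix(init_weights(c(hidden, channels), kernel_size = 1L,
                             prev_kernels = hidden), hidden, channels),
    b2 = numeric(channels)))
}

ca_mlp <- function(m, d) {
  h_pre <- d %*% m$W1 + rep(m$b1, each = nrow(d))
  h <- relu_fw(h_pre)
  o <- h$out %*% m$W2 + rep(m$b2, each = nrow(d))
  list(o = o, h = h, d = d)
}

ca_mlp_bw <- function(m, cache, go) {
  dW2 <- crossprod(cache$h$out, go)
  db2 <- colSums(go)
  gh <- relu_bw(cache$h, go %*% t(m$W2))
  dW1 <- crossprod(cache$d, gh)
  db1 <- colSums(gh)
  list(dd = gh %*% t(m$W1), dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

ca_fw <- function(p, x, training) {
  gp <- gpool_fw(x)
  ma <- ca_mlp(p$mlp, gp$avg)
  mm <- ca_mlp(p$mlp, gp$max)
  sg <- sigmoid_fw(ma$o + mm$o)
  gt <- gate_channel_fw(x, sg$out)
  list(out = gt$out, gate = sg$out, gp = gp, ma = ma, mm = mm,
       sg = sg, gt = gt)
}

ca_bw <- function(p, cache, gout) {
  gg <- gate_channel_bw(cache$gt, gout)
  gs <- sigmoid_bw(cache$sg, gg$dg)
  ba <- ca_mlp_bw(p$mlp, cache$ma, gs)
  bm <- ca_mlp_bw(p$mlp, cache$mm, gs)
  dx <- gg$dx + gpool_bw(cache$gp, ba$dd, bm$dd)
  list(dx = dx, grads = list(mlp = list(
    W1 = ba$dW1 + bm$dW1, b1 = ba$db1 + bm$db1,
    W2 = ba$dW2 + bm$dW2, b2 = ba$db2 + bm$db2)))
}

# --- SCAB: fused spatial-channel attention ----------------------------------

#' SCAB parameters
#'
#' The spatial-channel attention block applies spatial and channel
#' attention to the same input, concatenates the two gated maps (2G
#' channels) and projects back to G channels with a 1x1 convolution so the
#' block is shape-preserving.
#'
#' @param channels Number of input channels G.
#' @param spatial_kernel Kernel size of the spatial gate convolution.
#' @param reduction Channel-attention bottleneck reduction ratio.
#' @return Parameter list for [scab()].
#' @export
scab_params <- function(channels, spatial_kernel = 7L, reduction = 8L) {
  list(spatial = spatial_attention_params(spatial_kernel),
       channel = channel_attention_params(channels, reduction),
       proj = conv_params(1L, 2L * channels, channels))
}

scab_fw <- function(p, x, training) {
  sa <- sa_fw(p$spatial, x, training)
  ca <- ca_fw(p$channel, x, training)
  cc <- concat_ch(sa$out, ca$out)
  pj <- conv2d_fw(cc, p$proj$W, p$proj$b, 1L)
  list(out = pj$out, sa = sa, ca = ca, pj = pj, c1 = dim(x)[4L])
}

scab_bw <- function(p, cache, gout) {
  gp <- conv2d_bw(cache$pj, gout, p$proj$W)
  sp <- split_ch(gp$dx, cache$c1)
  gs <- sa_bw(p$spatial, cache$sa, sp$g1)
  gc <- ca_bw(p$channel, cache$ca, sp$g2)
  list(dx = gs$dx + gc$dx,
       grads = list(spatial = gs$grads, channel = gc$grads,
                    proj = list(W = gp$dW, b = gp$db)))
}

# --- RSCAB: residual SCAB ---------------------------------------------------

#' RSCAB parameters
#'
#' Residual SCAB first raises the input to `out_channels` with a 1x1
#' convolution and applies SCAB to the result; the attended map is then
#' concatenated with the raw input (a residual connection that carries the
#' shallow features forward) and fused back to `out_channels` by a second
#' 1x1 convolution.
#'
#' @param in_channels,out_channels Input/output channel counts.
#' @inheritParams scab_params
#' @return Parameter list for [rscab()].
#' @export
rscab_params <- function(in_channels, out_channels, spatial_kernel = 7L,
                         reduction = 8L) {
  list(up = conv_params(1L, in_channels, out_channels),
       scab = scab_params(out_channels, spatial_kernel, reduction),
       fuse = conv_params(1L, out_channels + in_channels, out_channels))
}

rscab_fw <- function(p, x, training) {
  up <- conv2d_fw(x, p$up$W, p$up$b, 1L)
  at <- scab_fw(p$scab, up$out, training)
  cc <- concat_ch(at$out, x)
  fz <- conv2d_fw(cc, p$fuse$W, p$fuse$b, 1L)
  list(out = fz$out, up = up, at = at, fz = fz, c1 = dim(up$out)[4L])
}

rscab_bw <- function(p, cache, gout) {
  gf <- conv2d_bw(cache$fz, gout, p$fuse$W)
  sp <- split_ch(gf$dx, cache$c1)
  ga <- scab_bw(p$scab, cache$at, sp$g1)
  gu <- conv2d_bw(cache$up, ga$dx, p$up$W)
  list(dx = gu$dx + sp$g2,
       grads = list(up = list(W = gu$dW, b = gu$db), scab = ga$grads,
                    fuse = list(W = gf$dW, b = gf$db)))
}

# --- exported single-map wrappers -------------------------------------------

# Convert a channels-first (G, P, Q) feature map to the internal
# (P, Q, 1, G) layout and back.
fmap_to_internal <- function(v) {
  if (length(dim(v)) != 3L)
    stop("a feature map must be a 3-D array with dimensions (G, P, Q)")
  x <- aperm(v, c(2L, 3L, 1L))
  dim(x) <- c(dim(v)[2L], dim(v)[3L], 1L, dim(v)[1L])
  x
}

fmap_from_internal <- function(x) {
  d <- dim(x)
  aperm(array(x, c(d[1L], d[2L], d[4L])), c(3L, 1L, 2L))
}

#' Residual block forward pass
#'
#' Computes `u = c(v, w_h) + w v`: the residual branch `c` is two
#' convolution + batch-normalization + ReLU layers and `w` is the 1x1
#' projection (identity when absent).  Output spatial size equals input
#' size.
#'
#' @param v Feature map, a (G, P, Q) array (channels first).
#' @param params From [residual_block_params()].
#' @param training Use batch statistics (TRUE) or running statistics
#'   (FALSE, default) in the normalization layers.
#' @return The output feature map, same (P, Q) and `out_channels` channels.
#' @export
residual_block <- function(v, params, training = FALSE) {
  c_in <- if (!is.null(params$proj)) params$proj$c_in else params$cbr1$conv$c_in
  if (dim(v)[1L] != c_in)
    stop("feature map has ", dim(v)[1L], " channels but the block expects ",
         c_in)
  fmap_from_internal(rb_fw(params, fmap_to_internal(v), training)$out)
}

#' Spatial attention forward pass
#'
#' Gates the input by a (1, P, Q) map in `[0, 1]` computed from the
#' channel-wise mean and max of the input: `e_s = b * S`.
#'
#' @param b Feature map, a (G, P, Q) array.
#' @param params From [spatial_attention_params()].
#' @return Gated feature map with the gate attached as attribute `"gate"`
#'   (a P x Q matrix).
#' @export
spatial_attention <- function(b, params) {
  r <- sa_fw(params, fmap_to_internal(b), FALSE)
  out <- fmap_from_internal(r$out)
  attr(out, "gate") <- matrix(r$gate, dim(b)[2L], dim(b)[3L])
  out
}

#' Channel attention forward pass
#'
#' Gates each channel by a scalar in `[0, 1]` derived from global max- and
#' average-pooled descriptors passed through a shared bottleneck:
#' `e_c = b * C`.
#'
#' @param b Feature map, a (G, P, Q) array.
#' @param params From [channel_attention_params()].
#' @return Gated feature map with the length-G gate attached as attribute
#'   `"gate"`.
#' @export
channel_attention <- function(b, params) {
  r <- ca_fw(params, fmap_to_internal(b), FALSE)
  out <- fmap_from_internal(r$out)
  attr(out, "gate") <- as.vector(r$gate)
  out
}

#' Fused spatial-channel attention (SCAB)
#'
#' Applies [spatial_attention()] and [channel_attention()] to the same
#' input, concatenates the two results along channels and projects back to
#' G channels: `d = proj(Cat(e_s, e_c))`.
#'
#' @param b Feature map, a (G, P, Q) array.
#' @param params From [scab_params()].
#' @return Feature map with the same shape as the input.
#' @export
scab <- function(b, params) {
  fmap_from_internal(scab_fw(params, fmap_to_internal(b), FALSE)$out)
}

#' Residual SCAB (RSCAB)
#'
#' `d_att = SCAB(conv1x1(d))`, then `out = conv1x1(Cat(d_att, d))`; the
#' concatenation carries the shallow input forward as a residual
#' connection.
#'
#' @param d Feature map, a (G, P, Q) array.
#' @param params From [rscab_params()].
#' @return Feature map with `out_channels` channels and unchanged (P, Q).
#' @export
rscab <- function(d, params) {
  fmap_from_internal(rscab_fw(params, fmap_to_internal(d), FALSE)$out)
}
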