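# Low-level tensor operations for the segmentation network.
#
# Activations are stored as 4-D arrays with dimension order (H, W, B, C):
# spatial rows, spatial columns, batch, channels.  Channels last keeps the
# im2col gather a single vectorized index expression and lets channel-wise
# broadcasting use R's recycling rules.  Every op returns a forward value
# plus the cache its backward pass needs; backward passes return the
# gradient w.r.t. the input and w.r.t. every parameter.

.op_cache <- new.env(parent = emptyenv())

# Padding convention: total zero padding is k-1 ("same" output size,
# stride 1).  pad_before rows/cols go on the top/left; for even kernels
# this puts the extra pad row on top (left-biased).
conv_pad_before <- function(k) as.integer(k %/% 2L)

# 2-D convolution, stride 1, "same" padding.  W is the (k*k*Cin) x Cout
# weight matrix (rows ordered kernel-row fastest, then kernel-col, then
# input channel); b is the length-Cout bias.  The im2col unroll is the
# compiled hot path; the product with the weight matrix goes to BLAS.
conv2d_fw <- function(x, W, b, k, pb = conv_pad_before(k)) {
  d <- dim(x)
  H <- d[1L]; Wd <- d[2L]; B <- d[3L]; C <- d[4L]
  stopifnot(nrow(W) == k * k * C)
  Co <- ncol(W)
  M <- cpp_im2col(x, H, Wd, B, C, k, pb)
  out <- M %*% W
  if (!is.null(b)) out <- out + rep(b, each = nrow(M))
  dim(out) <- c(H, Wd, B, Co)
  list(out = out, M = M, x_dim = d, k = k, pb = pb)
}

conv2d_bw <- function(cache, gout, W) {
  d <- cache$x_dim
  k <- cache$k
  C <- d[4L]
  Co <- ncol(W)
  G <- gout
  dim(G) <- c(d[1L] * d[2L] * d[3L], Co)
  dW <- crossprod(cache$M, G)
  db <- colSums(G)
  # Gradient w.r.t. the input is a convolution of the output gradient with
  # the spatially flipped, channel-transposed kernel and mirrored padding.
  Wa <- W
  dim(Wa) <- c(k, k, C, Co)
  Wf <- Wa[rev(seq_len(k)), rev(seq_len(k)), , , drop = FALSE]
  Wf <- aperm(Wf, c(1L, 2L, 4L, 3L))
  dim(Wf) <- c(k * k * Co, C)
  dx <- conv2d_fw(gout, Wf, NULL, k, pb = k - 1L - cache$pb)$out
  list(dx = dx, dW = dW, db = db)
}

# Batch normalization over (H, W, B) per channel.
bn_fw <- function(x, gamma, beta, run_mean, run_var, training,
                  momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  n <- d[1L] * d[2L] * d[3L]
  C <- d[4L]
  if (training) {
    m <- .colMeans(x, n, C)
    v <- .colMeans(x * x, n, C) - m * m
    v[v < 0] <- 0
    run_mean <- (1 - momentum) * run_mean + momentum * m
    # unbiased variance for the running estimate, as is conventional
    run_var <- (1 - momentum) * run_var + momentum * v * n / max(n - 1, 1)
  } else {
    m <- run_mean
    v <- run_var
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- (x - rep(m, each = n)) * rep(ivar, each = n)
  out <- xhat * rep(gamma, each = n) + rep(beta, each = n)
  list(out = out, xhat = xhat, ivar = ivar, n = n, C = C,
       training = training, run_mean = run_mean, run_var = run_var)
}

bn_bw <- function(cache, gout, gamma) {
  n <- cache$n
  C <- cache$C
  xhat <- cache$xhat
  dgamma <- .colSums(gout * xhat, n, C)
  dbeta <- .colSums(gout, n, C)
  if (cache$training) {
    s1 <- rep(dbeta / n, each = n)
    s2 <- rep(dgamma / n, each = n)
    dx <- rep(gamma * cache$ivar, each = n) * (gout - s1 - xhat * s2)
  } else {
    dx <- rep(gamma * cache$ivar, each = n) * gout
  }
  dim(dx) <- dim(gout)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_fw <- function(x) {
  out <- x
  out[out < 0] <- 0
  list(out = out, mask = x > 0)
}

relu_bw <- function(cache, gout) gout * cache$mask

sigmoid_fw <- function(x) {
  s <- 1 / (1 + exp(-x))
  list(out = s, s = s)
}

sigmoid_bw <- function(cache, gout) gout * cache$s * (1 - cache$s)

# 2x2 max pooling, stride 2.  Ties are broken toward the first quadrant in
# scan order so the backward pass routes each gradient to exactly one pixel.
maxpool2_fw <- function(x) {
  d <- dim(x)
  H <- d[1L]; W <- d[2L]
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  ri <- seq.int(1L, H, by = 2L)
  ci <- seq.int(1L, W, by = 2L)
  q <- list(
    x[ri, ci, , , drop = FALSE],
    x[ri + 1L, ci, , , drop = FALSE],
    x[ri, ci + 1L, , , drop = FALSE],
    x[ri + 1L, ci + 1L, , , drop = FALSE])
  out <- pmax(q[[1]], q[[2]], q[[3]], q[[4]])
  dim(out) <- c(H %/% 2L, W %/% 2L, d[3L], d[4L])
  masks <- vector("list", 4L)
  taken <- array(FALSE, dim(out))
  for (i in 1:4) {
    sel <- (q[[i]] == out) & !taken
    dim(sel) <- dim(out)
    masks[[i]] <- sel
    taken <- taken | sel
  }
  list(out = out, masks = masks, x_dim = d)
}

maxpool2_bw <- function(cache, gout) {
  d <- cache$x_dim
  dx <- array(0, d)
  ri <- seq.int(1L, d[1L], by = 2L)
  ci <- seq.int(1L, d[2L], by = 2L)
  dx[ri, ci, , ] <- gout * cache$masks[[1]]
  dx[ri + 1L, ci, , ] <- gout * cache$masks[[2]]
  dx[ri, ci + 1L, , ] <- gout * cache$masks[[3]]
  dx[ri + 1L, ci + 1L, , ] <- gout * cache$masks[[4]]
  dx
}

# Factor-2 bilinear interpolation matrix (half-pixel centers, edges
# clamped), applied separably along rows and columns.
bilinear_mat <- function(n) {
  key <- paste0("up", n)
  U <- .op_cache[[key]]
  if (!is.null(U)) return(U)
  U <- matrix(0, 2L * n, n)
  for (i in seq_len(2L * n)) {
    s <- (i - 0.5) / 2 - 0.5        # 0-based source coordinate
    f <- floor(s)
    w <- s - f
    lo <- min(max(f, 0), n - 1)
    hi <- min(max(f + 1, 0), n - 1)
    U[i, lo + 1L] <- U[i, lo + 1L] + (1 - w)
    U[i, hi + 1L] <- U[i, hi + 1L] + w
  }
  .op_cache[[key]] <- U
  U
}

# Apply row matrix A (m x H) and column matrix Bm (p x W) to each (B, C)
# slice: y[,,b,c] = A %*% x[,,b,c] %*% t(Bm).
sep_apply <- function(x, A, Bm) {
  d <- dim(x)
  y <- A %*% matrix(x, d[1L])          # (m, W*B*C)
  dim(y) <- c(nrow(A), d[2L], d[3L], d[4L])
  y <- aperm(y, c(2L, 1L, 3L, 4L))
  z <- Bm %*% matrix(y, d[2L])         # (p, m*B*C)
  dim(z) <- c(nrow(Bm), nrow(A), d[3L], d[4L])
  aperm(z, c(2L, 1L, 3L, 4L))
}

upsample2_fw <- function(x) {
  d <- dim(x)
  Ur <- bilinear_mat(d[1L])
  Uc <- bilinear_mat(d[2L])
  list(out = sep_apply(x, Ur, Uc), x_dim = d)
}

upsample2_bw <- function(cache, gout) {
  d <- cache$x_dim
  sep_apply(gout, t(bilinear_mat(d[1L])), t(bilinear_mat(d[2L])))
}

# Global pooling over (H, W) per (sample, channel): returns (B, C) matrices.
gpool_fw <- function(x) {
  d <- dim(x)
  n <- d[1L] * d[2L]
  m <- matrix(x, n, d[3L] * d[4L])
  avg <- matrix(.colMeans(x, n, d[3L] * d[4L]), d[3L], d[4L])
  wmax <- max.col(t(m), ties.method = "first")
  mx <- matrix(m[cbind(wmax, seq_len(ncol(m)))], d[3L], d[4L])
  list(avg = avg, max = mx, argmax = wmax, x_dim = d)
}

gpool_bw <- function(cache, g_avg, g_max) {
  d <- cache$x_dim
  n <- d[1L] * d[2L]
  dx <- rep(as.vector(g_avg) / n, each = n)
  dim(dx) <- d
  dm <- matrix(0, n, d[3L] * d[4L])
  dm[cbind(cache$argmax, seq_len(ncol(dm)))] <- as.vector(g_max)
  dim(dm) <- d
  dx + dm
}

# Per-pixel pooling across channels: returns (H, W, B, 2) with the
# channel-wise mean in slice 1 and the channel-wise max in slice 2.
chanpool_fw <- function(x) {
  d <- dim(x)
  n <- d[1L] * d[2L] * d[3L]
  C <- d[4L]
  avg <- .rowMeans(x, n, C)
  xm <- matrix(x, n, C)
  wmax <- max.col(xm, ties.method = "first")
  mx <- xm[cbind(seq_len(n), wmax)]
  out <- c(avg, mx)
  dim(out) <- c(d[1L], d[2L], d[3L], 2L)
  list(out = out, argmax = wmax, x_dim = d)
}

chanpool_bw <- function(cache, gout) {
  d <- cache$x_dim
  n <- d[1L] * d[2L] * d[3L]
  C <- d[4L]
  g_avg <- gout[, , , 1L]
  g_max <- gout[, , , 2L]
  dx <- matrix(rep(as.vector(g_avg) / C, C), n, C)
  dx[cbind(seq_len(n), cache$argmax)] <-
    dx[cbind(seq_len(n), cache$argmax)] + as.vector(g_max)
  dim(dx) <- d
  dx
}

# Gate a (H, W, B, C) tensor by a spatial gate (H, W, B, 1): the gate is
# recycled across channels.
gate_spatial_fw <- function(x, g) {
  gv <- as.vector(g)
  list(out = x * gv, x = x, g = gv)
}

gate_spatial_bw <- function(cache, gout) {
  d <- dim(cache$x)
  n <- d[1L] * d[2L] * d[3L]
  dg <- .rowSums(gout * cache$x, n, d[4L])
  dim(dg) <- c(d[1L], d[2L], d[3L], 1L)
  list(dx = gout * cache$g, dg = dg)
}

# Gate by a per-(sample, channel) gate g of shape (B, C).
gate_channel_fw <- function(x, g) {
  d <- dim(x)
  n <- d[1L] * d[2L]
  gv <- rep(as.vector(g), each = n)
  list(out = x * gv, x = x, gv = gv, g_dim = dim(g))
}

gate_channel_bw <- function(cache, gout) {
  d <- dim(cache$x)
  n <- d[1L] * d[2L]
  dg <- .colSums(matrix(gout * cache$x, n, d[3L] * d[4L]), n, d[3L] * d[4L])
  dim(dg) <- cache$g_dim
  list(dx = gout * cache$gv, dg = dg)
}

concat_ch <- function(x1, x2) {
  d1 <- dim(x1)
  d2 <- dim(x2)
  stopifnot(all(d1[1:3] == d2[1:3]))
  out <- c(x1, x2)
  dim(out) <- c(d1[1:3], d1[4L] + d2[4L])
  out
}

split_ch <- function(g, c1) {
  d <- dim(g)
  list(g1 = g[, , , seq_len(c1), drop = FALSE],
       g2 = g[, , , -seq_len(c1), drop = FALSE])
}
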