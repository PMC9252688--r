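# Independent reference implementations used as oracles: everything here
# is written with explicit loops / direct formula transcription, sharing
# no code with the package internals it checks.

# Direct convolution sum: x (H,W,B,C), Wa (k,k,Cin,Cout), bias length
# Cout, stride 1, zero padding pb before / k-1-pb after.
oracle_conv <- function(x, Wa, bias, pb) {
  d <- dim(x)
  k <- dim(Wa)[1]
  Co <- dim(Wa)[4]
  out <- array(0, c(d[1], d[2], d[3], Co))
  for (co in seq_len(Co)) for (s in seq_len(d[3]))
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      acc <- bias[co]
      for (a in seq_len(k)) for (b in seq_len(k)) for (c in seq_len(d[4])) {
        ii <- i + a - 1 - pb
        jj <- j + b - 1 - pb
        if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2])
          acc <- acc + x[ii, jj, s, c] * Wa[a, b, c, co]
      }
      out[i, j, s, co] <- acc
    }
  out
}

# Batch normalization in evaluation mode (running mean 0, variance 1).
oracle_bn_eval <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  out <- x
  for (c in seq_len(d[4]))
    out[, , , c] <- gamma[c] * x[, , , c] / sqrt(1 + eps) + beta[c]
  out
}

oracle_relu <- function(x) pmax(x, 0)

oracle_sigmoid <- function(x) 1 / (1 + exp(-x))

# Residual block in evaluation mode from its parameter object.
oracle_residual_block <- function(x, p) {
  k <- p$cbr1$conv$k
  wa1 <- array(p$cbr1$conv$W, c(k, k, p$cbr1$conv$c_in, p$cbr1$conv$c_out))
  h <- oracle_relu(oracle_bn_eval(
    oracle_conv(x, wa1, p$cbr1$conv$b, k %/% 2),
    p$cbr1$bn$gamma, p$cbr1$bn$beta))
  wa2 <- array(p$cbr2$conv$W, c(k, k, p$cbr2$conv$c_in, p$cbr2$conv$c_out))
  h <- oracle_relu(oracle_bn_eval(
    oracle_conv(h, wa2, p$cbr2$conv$b, k %/% 2),
    p$cbr2$bn$gamma, p$cbr2$bn$beta))
  if (!is.null(p$proj)) {
    wap <- array(p$proj$W, c(1, 1, p$proj$c_in, p$proj$c_out))
    h + oracle_conv(x, wap, p$proj$b, 0)
  } else h + x
}

# Spatial attention gate and output, x (H,W,B,C), p from
# spatial_attention_params().
oracle_spatial_attention <- function(x, p) {
  d <- dim(x)
  pooled <- array(0, c(d[1], d[2], d[3], 2))
  for (s in seq_len(d[3])) for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    v <- x[i, j, s, ]
    pooled[i, j, s, 1] <- mean(v)
    pooled[i, j, s, 2] <- max(v)
  }
  k <- p$conv$k
  wa <- array(p$conv$W, c(k, k, 2, 1))
  gate <- oracle_sigmoid(oracle_conv(pooled, wa, p$conv$b, k %/% 2))
  out <- x
  for (c in seq_len(d[4])) out[, , , c] <- x[, , , c] * gate[, , , 1]
  list(out = out, gate = gate)
}

# Channel attention: shared bottleneck over global max/avg descriptors.
oracle_channel_attention <- function(x, p) {
  d <- dim(x)
  out <- x
  gates <- matrix(0, d[3], d[4])
  mlp <- function(v) {
    h <- pmax(as.vector(v %*% p$mlp$W1) + p$mlp$b1, 0)
    as.vector(h %*% p$mlp$W2) + p$mlp$b2
  }
  for (s in seq_len(d[3])) {
    avg <- vapply(seq_len(d[4]), function(c) mean(x[, , s, c]), numeric(1))
    mx <- vapply(seq_len(d[4]), function(c) max(x[, , s, c]), numeric(1))
    g <- oracle_sigmoid(mlp(avg) + mlp(mx))
    gates[s, ] <- g
    for (c in seq_len(d[4])) out[, , s, c] <- x[, , s, c] * g[c]
  }
  list(out = out, gate = gates)
}

oracle_scab <- function(x, p) {
  es <- oracle_spatial_attention(x, p$spatial)$out
  ec <- oracle_channel_attention(x, p$channel)$out
  d <- dim(x)
  cc <- array(0, c(d[1], d[2], d[3], 2 * d[4]))
  cc[, , , seq_len(d[4])] <- es
  cc[, , , d[4] + seq_len(d[4])] <- ec
  wa <- array(p$proj$W, c(1, 1, 2 * d[4], d[4]))
  oracle_conv(cc, wa, p$proj$b, 0)
}

oracle_rscab <- function(x, p) {
  d <- dim(x)
  co <- p$up$c_out
  wu <- array(p$up$W, c(1, 1, p$up$c_in, co))
  up <- oracle_conv(x, wu, p$up$b, 0)
  at <- oracle_scab(up, p$scab)
  cc <- array(0, c(d[1], d[2], d[3], co + d[4]))
  cc[, , , seq_len(co)] <- at
  cc[, , , co + seq_len(d[4])] <- x
  wf <- array(p$fuse$W, c(1, 1, co + d[4], co))
  oracle_conv(cc, wf, p$fuse$b, 0)
}

# Double-loop bilateral filter with border renormalization.
oracle_bilateral <- function(img, ss, sr, r) {
  H <- nrow(img)
  W <- ncol(img)
  out <- img
  for (i in seq_len(H)) for (j in seq_len(W)) {
    num <- 0
    den <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- i + di
      jj <- j + dj
      if (ii < 1 || ii > H || jj < 1 || jj > W) next
      w <- exp(-(di^2 + dj^2) / (2 * ss^2)) *
        exp(-(img[ii, jj] - img[i, j])^2 / (2 * sr^2))
      num <- num + w * img[ii, jj]
      den <- den + w
    }
    out[i, j] <- num / den
  }
  out
}

# Boundary pixels by direct neighbor checks (out-of-image = background).
oracle_boundary <- function(mask) {
  H <- nrow(mask)
  W <- ncol(mask)
  pts <- NULL
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (mask[i, j] != 1) next
    up <- if (i > 1) mask[i - 1, j] else 0
    dn <- if (i < H) mask[i + 1, j] else 0
    lf <- if (j > 1) mask[i, j - 1] else 0
    rt <- if (j < W) mask[i, j + 1] else 0
    if (min(up, dn, lf, rt) == 0) pts <- rbind(pts, c(i, j))
  }
  pts
}

# Exhaustive pairwise boundary distances.
oracle_hd_mad <- function(pred, truth) {
  bp <- oracle_boundary(pred)
  bt <- oracle_boundary(truth)
  dpt <- matrix(0, nrow(bp), nrow(bt))
  for (a in seq_len(nrow(bp))) for (b in seq_len(nrow(bt)))
    dpt[a, b] <- sqrt(sum((bp[a, ] - bt[b, ])^2))
  d_p <- apply(dpt, 1, min)
  d_t <- apply(dpt, 2, min)
  list(hd = max(max(d_p), max(d_t)), mad = (mean(d_p) + mean(d_t)) / 2)
}

# Random blob-ish binary mask guaranteed nonempty with nonempty boundary.
random_mask <- function(H, W, p = 0.3) {
  repeat {
    m <- matrix(as.numeric(stats::runif(H * W) < p), H, W)
    if (sum(m) >= 1) return(m)
  }
}

# Central finite differences of f w.r.t. x.
fd_grad <- function(f, x, h = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}
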