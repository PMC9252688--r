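# Feature maps in these tests follow the channels-first (G, P, Q)
# convention of the exported block functions; internal-layout oracles
# receive the (P, Q, 1, G) conversion via busseg:::fmap_to_internal.

rand_fmap <- function(G, P, Q) array(rnorm(G * P * Q), c(G, P, Q))

test_that("the internal convolution equals the direct convolution sum", {
  withr::with_seed(11, {
    for (spec in list(list(k = 3, cin = 2, cout = 3, H = 4, W = 5),
                      list(k = 1, cin = 3, cout = 2, H = 4, W = 4),
                      list(k = 6, cin = 1, cout = 2, H = 7, W = 6),
                      list(k = 2, cin = 2, cout = 1, H = 5, W = 5))) {
      x <- array(rnorm(spec$H * spec$W * 2 * spec$cin),
                 c(spec$H, spec$W, 2, spec$cin))
      W <- matrix(rnorm(spec$k^2 * spec$cin * spec$cout),
                  spec$k^2 * spec$cin, spec$cout)
      b <- rnorm(spec$cout)
      pb <- spec$k %/% 2
      got <- busseg:::conv2d_fw(x, W, b, spec$k, pb)$out
      want <- oracle_conv(x, array(W, c(spec$k, spec$k, spec$cin,
                                        spec$cout)), b, pb)
      expect_lt(max(abs(got - want)), 1e-6)
    }
  })
})

test_that("a zeroed residual branch with matching channels is the identity", {
  p <- residual_block_params(3, 3, kernel_size = 3)
  p$cbr2$conv$W[] <- 0
  p$cbr2$conv$b[] <- 0
  v <- rand_fmap(3, 4, 4)
  expect_equal(residual_block(v, p), v, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("the residual block matches the loop-based oracle", {
  withr::with_seed(12, {
    for (chans in list(c(1, 1), c(2, 3))) {
      p <- residual_block_params(chans[1], chans[2], kernel_size = 3)
      v <- rand_fmap(chans[1], 4, 4)
      got <- residual_block(v, p)
      want <- busseg:::fmap_from_internal(
        oracle_residual_block(busseg:::fmap_to_internal(v), p))
      expect_lt(max(abs(got - want)), 1e-6)
      expect_identical(dim(got), c(as.integer(chans[2]), 4L, 4L))
    }
  })
})

test_that("with the residual branch zeroed the input Jacobian is the identity", {
  p <- residual_block_params(2, 2, kernel_size = 3)
  p$cbr2$conv$W[] <- 0
  p$cbr2$conv$b[] <- 0
  withr::with_seed(13, {
    v <- rand_fmap(2, 3, 3)
  })
  f <- function(x) residual_block(array(x, dim(v)), p)
  h <- 1e-5
  for (probe in sample(length(v), 4)) {
    e <- numeric(length(v))
    e[probe] <- h
    col <- (f(as.vector(v) + e) - f(as.vector(v) - e)) / (2 * h)
    want <- numeric(length(v))
    want[probe] <- 1
    expect_lt(max(abs(as.vector(col) - want)), 1e-5)
  }
})

test_that("attention gates live in [0, 1] and all-ones gates pass through", {
  withr::with_seed(14, {
    for (rep in 1:5) {
      b <- rand_fmap(4, 5, 6) * 10
      sp <- spatial_attention_params(kernel_size = 3)
      es <- spatial_attention(b, sp)
      g <- attr(es, "gate")
      expect_true(all(g >= 0 & g <= 1))
      ch <- channel_attention_params(4, reduction = 2)
      ec <- channel_attention(b, ch)
      expect_true(all(attr(ec, "gate") >= 0 & attr(ec, "gate") <= 1))
    }
  })
  # saturate the gate convolutions -> sigmoid underflows to exactly 1
  b <- rand_fmap(4, 5, 6)
  sp <- spatial_attention_params(kernel_size = 3)
  sp$conv$W[] <- 0
  sp$conv$b[] <- 1000
  expect_equal(spatial_attention(b, sp), b, ignore_attr = TRUE)
  ch <- channel_attention_params(4, reduction = 2)
  ch$mlp$W1[] <- 0
  ch$mlp$b1[] <- 0
  ch$mlp$W2[] <- 0
  ch$mlp$b2[] <- 500
  expect_equal(channel_attention(b, ch), b, ignore_attr = TRUE)
})

test_that("spatial attention prefers a high-magnitude region", {
  b <- array(0, c(2, 8, 8))
  b[, 2:4, 2:4] <- 5          # positive-bias construction
  p <- spatial_attention_params(kernel_size = 3)
  p$conv$W[] <- abs(p$conv$W)     # positive weights so pooling raises the gate
  g <- attr(spatial_attention(b, p), "gate")
  expect_gte(mean(g[2:4, 2:4]), mean(g[6:8, 6:8]))
})

test_that("identical channels receive identical gates under a channel-symmetric bottleneck", {
  # the shared bottleneck mixes channels, so exact gate equality requires
  # channel-symmetric weights; with those, identical channels must tie
  one <- matrix(rnorm(25), 5, 5)
  b <- array(0, c(3, 5, 5))
  for (g in 1:3) b[g, , ] <- one
  p <- channel_attention_params(3, reduction = 3)
  p$mlp$W1[] <- 0.2
  p$mlp$b1[] <- 0.05
  p$mlp$W2[] <- -0.3
  p$mlp$b2[] <- 0.1
  gate <- attr(channel_attention(b, p), "gate")
  expect_lt(diff(range(gate)), 1e-12)
})

test_that("channel attention matches a hand-set closed form", {
  p <- channel_attention_params(2, reduction = 2)
  p$mlp$W1 <- matrix(c(0.3, -0.2), 2, 1)
  p$mlp$b1 <- 0.1
  p$mlp$W2 <- matrix(c(0.5, -0.4), 1, 2)
  p$mlp$b2 <- c(0.05, -0.05)
  withr::with_seed(15, {
    b <- rand_fmap(2, 3, 3)
  })
  mlp <- function(v) {
    h <- max(sum(v * c(0.3, -0.2)) + 0.1, 0)
    h * c(0.5, -0.4) + c(0.05, -0.05)
  }
  avg <- c(mean(b[1, , ]), mean(b[2, , ]))
  mx <- c(max(b[1, , ]), max(b[2, , ]))
  gate <- 1 / (1 + exp(-(mlp(avg) + mlp(mx))))
  want <- b
  want[1, , ] <- b[1, , ] * gate[1]
  want[2, , ] <- b[2, , ] * gate[2]
  expect_lt(max(abs(channel_attention(b, p) - want)), 1e-6)
})

test_that("scab equals the composed attention + concat + projection oracle", {
  withr::with_seed(16, {
    p <- scab_params(2, spatial_kernel = 3, reduction = 2)
    b <- rand_fmap(2, 3, 3)
  })
  got <- scab(b, p)
  expect_identical(dim(got), dim(b))
  want <- busseg:::fmap_from_internal(
    oracle_scab(busseg:::fmap_to_internal(b), p))
  expect_lt(max(abs(got - want)), 1e-6)
})

test_that("scab configured as an averaging projection with open gates is the identity", {
  G <- 3
  p <- scab_params(G, spatial_kernel = 3, reduction = 3)
  p$spatial$conv$W[] <- 0
  p$spatial$conv$b[] <- 1000
  p$channel$mlp$W1[] <- 0
  p$channel$mlp$b1[] <- 0
  p$channel$mlp$W2[] <- 0
  p$channel$mlp$b2[] <- 1000
  p$proj$W[] <- 0
  for (g in 1:G) p$proj$W[c(g, G + g), g] <- 0.5   # average the two copies
  p$proj$b[] <- 0
  b <- rand_fmap(G, 4, 4)
  expect_equal(scab(b, p), b, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("rscab matches the two-stage oracle and its shape contract", {
  withr::with_seed(17, {
    p <- rscab_params(2, 4, spatial_kernel = 3, reduction = 2)
    d <- rand_fmap(2, 4, 4)
  })
  got <- rscab(d, p)
  expect_identical(dim(got), c(4L, 4L, 4L))
  want <- busseg:::fmap_from_internal(
    oracle_rscab(busseg:::fmap_to_internal(d), p))
  expect_lt(max(abs(got - want)), 1e-6)
})

test_that("rscab with open gates and identity-preserving 1x1 weights reduces to a residual concat block", {
  G <- 2
  p <- rscab_params(G, G, spatial_kernel = 3, reduction = 2)
  # open gates
  p$scab$spatial$conv$W[] <- 0
  p$scab$spatial$conv$b[] <- 1000
  p$scab$channel$mlp$W1[] <- 0
  p$scab$channel$mlp$b1[] <- 0
  p$scab$channel$mlp$W2[] <- 0
  p$scab$channel$mlp$b2[] <- 1000
  # scab projection averages its two identical copies -> identity
  p$scab$proj$W[] <- 0
  for (g in 1:G) p$scab$proj$W[c(g, G + g), g] <- 0.5
  p$scab$proj$b[] <- 0
  # up = identity, fuse = average of d_att and d
  p$up$W <- diag(G)
  p$up$b[] <- 0
  p$fuse$W[] <- 0
  for (g in 1:G) p$fuse$W[c(g, G + g), g] <- 0.5
  p$fuse$b[] <- 0
  d <- rand_fmap(G, 5, 5)
  expect_equal(rscab(d, p), d, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the assembled model maps (P, Q) inputs to in-range (P, Q) probabilities", {
  m <- build_model(arch_config(depth = 3, base_channels = 8), seed = 5)
  img <- matrix(runif(64 * 64), 64, 64)
  pr <- predict(m, img)
  expect_identical(dim(pr), c(64L, 64L))
  expect_true(all(pr >= 0 & pr <= 1))
  # repeated forward passes are bit-identical
  expect_identical(pr, predict(m, img))
  # shape preservation across attention variants
  for (att in c("rscab", "none")) {
    mv <- build_model(arch_config(depth = 2, base_channels = 4,
                                  attention = att, reduction = 2), seed = 6)
    expect_identical(dim(predict(mv, matrix(runif(32 * 32), 32, 32))),
                     c(32L, 32L))
  }
})

test_that("indivisible input sizes raise a configuration error", {
  m <- build_model(arch_config(depth = 3, base_channels = 4,
                               reduction = 2), seed = 7)
  expect_error(predict(m, matrix(0.5, 30, 32)), "divisible")
})

test_that("the parameter count matches a hand-summed closed form", {
  m <- build_model(arch_config(depth = 2, base_channels = 4,
                               kernel_size = 3, attention = "none"),
                   seed = 8)
  conv_n <- function(k, ci, co) k * k * ci * co + co
  bn_n <- function(c) 2 * c
  rb_n <- function(ci, co, k = 3) {
    n <- conv_n(k, ci, co) + bn_n(co) + conv_n(k, co, co) + bn_n(co)
    if (ci != co) n <- n + conv_n(1, ci, co)
    n
  }
  want <- rb_n(1, 4) + rb_n(4, 8) +                 # encoder levels
    (conv_n(3, 8, 4) + bn_n(4)) + rb_n(8, 4) +      # decoder level
    conv_n(1, 4, 1)                                 # head
  expect_equal(n_parameters(m), want)
})

test_that("model gradients agree with finite differences through the composite loss", {
  arch <- arch_config(depth = 2, base_channels = 2, reduction = 2,
                      spatial_kernel = 3)
  m <- build_model(arch, seed = 9)
  withr::with_seed(18, {
    x <- array(runif(8 * 8 * 2), c(8, 8, 2, 1))
    t <- array(rbinom(8 * 8 * 2, 1, 0.3), c(8, 8, 2, 1))
  })
  cfg <- loss_config()
  sd0 <- busseg:::state_dict(m$params)
  fw <- busseg:::unet_fw(m, x, training = TRUE)
  lg <- busseg:::loss_value_grad(fw$out, t, "composite", cfg)
  gtree <- busseg:::unet_bw(m, fw, array(lg$grad, dim(fw$out)))
  gflat <- busseg:::grad_flatten(gtree)
  refs <- busseg:::param_refs(m$params)
  h <- 1e-5
  withr::with_seed(19, {
    probe_refs <- sample(length(refs), 8)
  })
  for (ri in probe_refs) {
    r <- refs[[ri]]
    ii <- 1L
    perturbed_loss <- function(delta) {
      busseg:::load_state_dict(m$params, sd0)
      v <- r$env[[r$field]]
      v[ii] <- v[ii] + delta
      r$env[[r$field]] <- v
      fw2 <- busseg:::unet_fw(m, x, training = TRUE)
      busseg:::loss_value_grad(fw2$out, t, "composite", cfg)$value
    }
    fd <- (perturbed_loss(h) - perturbed_loss(-h)) / (2 * h)
    busseg:::load_state_dict(m$params, sd0)
    ana <- gflat[[r$path]][ii]
    expect_lt(abs(fd - ana) / max(1e-6, abs(fd), abs(ana)), 1e-3)
  }
})
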