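test_that("init_weights draws zero-mean Gaussians with std sqrt(2/delta)", {
  settings <- list(c(3, 8), c(3, 1), c(6, 4))
  for (s in settings) {
    delta <- s[1]^2 * s[2]
    w <- init_weights(1e5, kernel_size = s[1], prev_kernels = s[2],
                      seed = 99)
    target <- sqrt(2 / delta)
    expect_lt(abs(mean(w)), 3 * target / sqrt(1e5))
    expect_lt(abs(stats::sd(w) - target) / target, 0.02)
  }
  expect_error(init_weights(10, kernel_size = 1, prev_kernels = 0), "delta")
  # std scales as 1/(k sqrt(z))
  expect_equal(sqrt(2 / (3^2 * 8)) / sqrt(2 / (3^2 * 2)), 1 / 2)
})

test_that("adam reproduces a hand-computed scalar trajectory", {
  cfg <- adam_config()   # phi1 0.95, phi2 0.999, eps 1.5e-4, sigma 1.5e-8
  st <- adam_init(1, cfg)
  # hand arithmetic, step 1 (y = 0.5):
  #   o = 0.05 * 0.5 = 0.025          z = 0.001 * 0.25 = 2.5e-4
  #   ohat = 0.025 / 0.05 = 0.5       zhat = 2.5e-4 / 0.001 = 0.25
  #   theta = 1 - 1.5e-4 * 0.5 / (0.5 + 1.5e-8)
  th <- 1
  o <- 0
  z <- 0
  for (t in 1:3) {
    st <- adam_step(st, 0.5)
    o <- 0.95 * o + 0.05 * 0.5
    z <- 0.999 * z + 0.001 * 0.25
    oh <- o / (1 - 0.95^t)
    zh <- z / (1 - 0.999^t)
    th <- th - 1.5e-4 * oh / (sqrt(zh) + 1.5e-8)
    expect_equal(st$theta, th, tolerance = 1e-12)
    expect_equal(st$o, o, tolerance = 1e-12)
    expect_equal(st$z, z, tolerance = 1e-12)
  }
})

test_that("zero gradient leaves parameters untouched", {
  st <- adam_init(c(a = 1, b = -2), adam_config())
  st <- adam_step(st, c(0, 0))
  expect_equal(st$theta, c(a = 1, b = -2))
})

test_that("the first bias-corrected step has magnitude ~eps at any gradient scale", {
  cfg <- adam_config()
  for (y in c(0.01, 1, 100)) {
    st <- adam_step(adam_init(0, cfg), y)
    # |step| = eps * |y| / (|y| + sigma): off eps by at most sigma/|y|
    expect_equal(abs(st$theta), cfg$eps, tolerance = 1e-5)
    expect_equal(sign(st$theta), -sign(y))
  }
})

test_that("moment accumulators stay within convex-combination bounds", {
  cfg <- adam_config()
  st <- adam_init(0, cfg)
  withr::with_seed(6, {
    ys <- rnorm(50)
  })
  for (y in ys) {
    st <- adam_step(st, y)
    expect_lte(abs(st$o), max(abs(ys)) + 1e-12)
    expect_lte(st$z, max(ys^2) + 1e-12)
    expect_gte(st$z, 0)
  }
})

test_that("adam_step handles nested parameter lists and rejects shape mismatch", {
  th <- list(w = matrix(1, 2, 2), b = c(0, 0))
  st <- adam_init(th, adam_config())
  st <- adam_step(st, list(w = matrix(0.5, 2, 2), b = c(1, -1)))
  expect_equal(dim(st$theta$w), c(2, 2))
  expect_true(all(st$theta$w < 1))
  expect_error(adam_step(st, list(w = matrix(0.5, 2, 2), b = 1)), "shape")
})

test_that("the literal bias-correction variant is selectable", {
  cfg <- adam_config(paper_literal = TRUE)
  expect_equal(cfg$phi2, 1.0)
  st <- adam_step(adam_init(1, cfg), 0.5)
  # z stays 0 under phi2 = 1, so the step is eps * (o / phi1) / sigma
  expect_equal(st$z, 0)
  expect_equal(st$theta,
               1 - 1.5e-4 * (0.05 * 0.5 / 0.95) / 1.5e-8,
               tolerance = 1e-9)
  expect_error(adam_config(phi2 = 1), "paper_literal")
})

test_that("fit validates inputs and epochs = 0 changes nothing", {
  d <- generate_dataset(phantom_config(height = 16, width = 16,
                                       lesion_area_fraction = 0.2), 4,
                        seed = 1)
  arch <- arch_config(depth = 2, base_channels = 4, reduction = 2)
  m <- build_model(arch, seed = 1)
  expect_error(fit(m, list(), d), "nonempty")
  expect_error(fit(m, d, d, epochs = -1), "epochs")
  before <- busseg:::state_dict(m$params)
  res <- fit(m, d, d, epochs = 0)
  expect_identical(busseg:::state_dict(m$params), before)
  expect_equal(nrow(res$history), 0)
})

test_that("training reduces the loss on an easy segmentation task", {
  cfg <- phantom_config(height = 32, width = 32, contrast = 0.5,
                        speckle_sigma = 0, lesion_area_fraction = 0.25)
  train <- generate_dataset(cfg, 50, seed = 5)
  val <- generate_dataset(cfg, 8, seed = 6)
  m <- build_model(arch_config(depth = 2, base_channels = 4,
                               reduction = 2), seed = 2)
  res <- fit(m, train, val, adam_cfg = train_config(), epochs = 5,
             seed = 3)
  h <- res$history
  expect_equal(nrow(h), 5)
  expect_lt(h$train_loss[5], h$train_loss[1])
  expect_gt(max(h$val_dice), h$val_dice[1] - 0.02)
})

test_that("training trajectories are reproducible from the seed", {
  cfg <- phantom_config(height = 16, width = 16, lesion_area_fraction = 0.2)
  train <- generate_dataset(cfg, 12, seed = 8)
  val <- generate_dataset(cfg, 4, seed = 9)
  arch <- arch_config(depth = 2, base_channels = 4, reduction = 2)
  h <- lapply(1:2, function(i) {
    m <- build_model(arch, seed = 4)
    fit(m, train, val, adam_cfg = train_config(), epochs = 2,
        seed = 10)$history
  })
  expect_identical(h[[1]], h[[2]])
})
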