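# Training machinery: scaled-Gaussian weight initialization, the Adam
# optimizer, and the mini-batch training loop.

#' Scaled-Gaussian weight initialization
#'
#' Draws independent zero-mean Gaussian weights with standard deviation
#' `sqrt(2 / delta)` where `delta = kernel_size^2 * prev_kernels` is the
#' fan-in of the receiving layer -- the scaling that keeps activation
#' variance stable under ReLU nonlinearities.
#'
#' @param shape Integer vector of array dimensions (or a single count).
#' @param kernel_size Convolution kernel size of the layer, in pixels
#'   (use 1 for dense layers).
#' @param prev_kernels Number of kernels (channels) in the previous
#'   layer, i.e. the input channel count.
#' @param seed Optional integer seed; when `NULL`, draws from the
#'   current RNG state.
#' @return An array of the requested shape.
#' @export
init_weights <- function(shape, kernel_size, prev_kernels, seed = NULL) {
  delta <- kernel_size^2 * prev_kernels
  if (delta < 1) stop("fan-in delta = ", delta, " must be >= 1")
  sd <- sqrt(2 / delta)
  n <- prod(shape)
  draw <- function() stats::rnorm(n, mean = 0, sd = sd)
  w <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  if (length(shape) > 1L) dim(w) <- shape
  w
}

#' Adam optimizer configuration
#'
#' Defaults follow the training settings used for the segmentation
#' network: `phi1 = 0.95`, learning rate `eps = 1.5e-4`, denominator
#' stabilizer `sigma = 1.5e-8`.  The second-moment decay defaults to the
#' standard 0.999.  With `paper_literal = TRUE` the bias corrections are
#' computed as `o/phi1` and `z/phi2` (and `phi2` defaults to 1.00), a
#' variant kept selectable for comparison; it is not recommended, since
#' `phi2 = 1` freezes the second moment at zero.
#'
#' @param phi1,phi2 First/second-moment decay coefficients in `[0, 1)`
#'   (phi2 may be 1 only in literal mode).
#' @param eps Learning rate.
#' @param sigma Small positive constant preventing division by zero.
#' @param paper_literal Use the literal `o/phi1`, `z/phi2` corrections.
#' @return An object of class `"adam_config"`.
#' @export
adam_config <- function(phi1 = 0.95, phi2 = if (paper_literal) 1.0 else 0.999,
                        eps = 1.5e-4, sigma = 1.5e-8,
                        paper_literal = FALSE) {
  if (phi1 < 0 || phi1 >= 1) stop("phi1 must be in [0, 1)")
  if (phi2 < 0 || phi2 > 1) stop("phi2 must be in [0, 1]")
  if (!paper_literal && phi2 == 1)
    stop("phi2 = 1 freezes the second moment; use paper_literal = TRUE ",
         "if you really want the literal update")
  if (eps <= 0) stop("learning rate eps must be > 0")
  if (sigma <= 0) stop("sigma must be > 0")
  structure(list(phi1 = phi1, phi2 = phi2, eps = eps, sigma = sigma,
                 paper_literal = paper_literal),
            class = "adam_config")
}

# Core elementwise update shared by the exported adam_step and the
# training loop.  o, z, y are arrays of identical shape; t is the
# (already incremented) step count.  Returns o, z and the parameter
# increment.
adam_update_arrays <- function(o, z, y, t, cfg) {
  o <- cfg$phi1 * o + (1 - cfg$phi1) * y
  z <- cfg$phi2 * z + (1 - cfg$phi2) * y * y
  if (cfg$paper_literal) {
    ohat <- o / cfg$phi1
    zhat <- z / cfg$phi2
  } else {
    ohat <- o / (1 - cfg$phi1^t)
    zhat <- z / (1 - cfg$phi2^t)
  }
  list(o = o, z = z, step = -cfg$eps * ohat / (sqrt(zhat) + cfg$sigma))
}

#' Initialize Adam optimizer state
#'
#' @param theta Initial parameters: a numeric vector/array or a nested
#'   list of such.
#' @param cfg An [adam_config()].
#' @return An object of class `"adam_state"` holding the parameters,
#'   zeroed first/second moment accumulators and the step counter `t = 0`.
#' @export
adam_init <- function(theta, cfg = adam_config()) {
  zeros <- function(x) {
    if (is.list(x)) return(lapply(x, zeros))
    z <- x
    z[] <- 0
    z
  }
  structure(list(theta = theta, o = zeros(theta), z = zeros(theta),
                 t = 0L, cfg = cfg),
            class = "adam_state")
}

#' One Adam update step
#'
#' Applies the adaptive-moment update: exponential first/second moment
#' accumulation, bias correction, and the parameter step
#' `theta <- theta - eps * ohat / (sqrt(zhat) + sigma)`.
#'
#' @param state An [adam_init()] state.
#' @param y Gradient of the loss w.r.t. `theta`, same structure as
#'   `theta`.
#' @return The updated state.
#' @export
adam_step <- function(state, y) {
  stopifnot(inherits(state, "adam_state"))
  t <- state$t + 1L
  cfg <- state$cfg
  walk <- function(th, o, z, g) {
    if (is.list(th)) {
      out <- Map(walk, th, o, z, g)
      return(list(theta = lapply(out, `[[`, "theta"),
                  o = lapply(out, `[[`, "o"),
                  z = lapply(out, `[[`, "z")))
    }
    if (length(g) != length(th))
      stop("gradient shape does not match parameter shape")
    u <- adam_update_arrays(o, z, g, t, cfg)
    list(theta = th + u$step, o = u$o, z = u$z)
  }
  r <- walk(state$theta, state$o, state$z, y)
  state$theta <- r$theta
  state$o <- r$o
  state$z <- r$z
  state$t <- t
  state
}

# --- training loop ----------------------------------------------------------

#' Train a segmentation model
#'
#' Mini-batch optimization of the network with Adam.  The run is fully
#' deterministic given `seed` (batch shuffling is the only randomness;
#' weights are initialized when the model is built).  After every epoch
#' the mean Dice coefficient over the validation pairs (probability maps
#' binarized at `threshold`) is recorded, and the parameters with the
#' best validation Dice are restored into the model when training ends.
#'
#' @param model A `"busseg_model"` from [build_model()]; updated in
#'   place.
#' @param train,val Lists of image/mask pairs (`list(image =, mask =)`),
#'   e.g. from [generate_dataset()].
#' @param loss Which loss to optimize: the weighted composite (default),
#'   or pure BCE / pure Dice for ablation.
#' @param loss_cfg A [loss_config()].
#' @param adam_cfg An [adam_config()]; note the learning rate for short
#'   desk-scale runs typically needs to be larger than the long-run
#'   default (see [train_config()]).
#' @param epochs Number of passes over the training set (`0` leaves the
#'   model untouched and returns an empty history).
#' @param batch_size Images per gradient step.
#' @param seed Integer seed for batch shuffling.
#' @param threshold Binarization threshold for validation Dice.
#' @param verbose Print per-epoch progress.
#' @return A list with `model` (best-validation weights), `history`
#'   (data.frame of epoch, train_loss, val_dice) and `best_epoch`.
#' @export
fit <- function(model, train, val,
                loss = c("composite", "bce", "dice"),
                loss_cfg = loss_config(), adam_cfg = adam_config(),
                epochs = 10L, batch_size = 8L, seed = 1L,
                threshold = 0.5, verbose = FALSE) {
  stopifnot(inherits(model, "busseg_model"))
  loss <- match.arg(loss)
  if (length(train) < 1L || length(val) < 1L)
    stop("training and validation sets must be nonempty")
  if (epochs < 0L) stop("epochs must be >= 0")
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_dice = numeric())
  if (epochs == 0L)
    return(invisible(list(model = model, history = history,
                          best_epoch = NA_integer_)))
  refs <- param_refs(model$params)
  mo <- lapply(refs, function(r) { a <- r$env[[r$field]]; a[] <- 0; a })
  mz <- mo
  tstep <- 0L
  n <- length(train)
  best_dice <- -Inf
  best_sd <- NULL
  best_epoch <- NA_integer_
  val_imgs <- lapply(val, `[[`, "image")
  withr::with_seed(seed, {
    for (epoch in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      n_batch <- 0L
      i <- 1L
      while (i <= n) {
        j <- min(i + batch_size - 1L, n)
        sel <- ord[i:j]
        x <- batch_tensor(lapply(train[sel], `[[`, "image"))
        tt <- batch_tensor(lapply(train[sel], `[[`, "mask"))
        fwres <- unet_fw(model, x, training = TRUE)
        lg <- loss_value_grad(fwres$out, tt, loss, loss_cfg)
        gtree <- unet_bw(model, fwres,
                         array(lg$grad, dim(fwres$out)))
        gflat <- grad_flatten(gtree)
        tstep <- tstep + 1L
        for (k in seq_along(refs)) {
          r <- refs[[k]]
          g <- gflat[[r$path]]
          u <- adam_update_arrays(mo[[k]], mz[[k]], as.numeric(g),
                                  tstep, adam_cfg)
          mo[[k]] <- u$o
          mz[[k]] <- u$z
          r$env[[r$field]] <- r$env[[r$field]] + u$step
        }
        ep_loss <- ep_loss + lg$value
        n_batch <- n_batch + 1L
        i <- j + 1L
      }
      pr <- predict(model, val_imgs, type = "mask", threshold = threshold,
                    batch_size = batch_size)
      vd <- mean(vapply(seq_along(val), function(ii)
        dice_coefficient(pr[[ii]], val[[ii]]$mask, warn = FALSE),
        numeric(1)))
      history[epoch, ] <- list(epoch, ep_loss / n_batch, vd)
      if (vd > best_dice) {
        best_dice <- vd
        best_sd <- state_dict(model$params)
        best_epoch <- epoch
      }
      if (verbose)
        message(sprintf("epoch %d  train %s = %.5f  val Dice = %.4f",
                        epoch, loss, ep_loss / n_batch, vd))
    }
  })
  if (!is.null(best_sd)) load_state_dict(model$params, best_sd)
  invisible(list(model = model, history = history, best_epoch = best_epoch))
}
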