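# U-Net assembly: encoder of residual blocks with 2x max-pool
# downsampling, skip connections gated by SCAB, decoder with bilinear
# upsampling + convolution, and a 1x1 convolution + sigmoid head that
# yields a per-pixel lesion probability map the same size as the input.

#' Architecture configuration
#'
#' @param depth Number of encoder levels (the deepest level is the
#'   bottleneck); input height/width must be divisible by
#'   `2^(depth - 1)`.
#' @param base_channels Channels at the first level; widths double per
#'   level.
#' @param kernel_size Residual-branch convolution kernel in pixels.
#'   Odd sizes use symmetric "same" padding; even sizes (e.g. 6 or 2) are
#'   supported with left-biased padding.
#' @param attention `"scab"` gates every skip connection with a
#'   spatial-channel attention block, `"rscab"` replaces the level
#'   feature blocks with residual SCAB modules (skips left plain), and
#'   `"none"` is a plain residual U-Net.
#' @param spatial_kernel Kernel of the spatial-attention gate convolution.
#' @param reduction Channel-attention bottleneck reduction ratio.
#' @return An object of class `"arch_config"`.
#' @export
arch_config <- function(depth = 4L, base_channels = 16L, kernel_size = 3L,
                        attention = c("scab", "rscab", "none"),
                        spatial_kernel = 7L, reduction = 8L) {
  attention <- match.arg(attention)
  if (depth < 2L) stop("depth must be at least 2")
  if (base_channels < 1L) stop("base_channels must be at least 1")
  if (kernel_size < 1L) stop("kernel_size must be at least 1")
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 kernel_size = as.integer(kernel_size),
                 attention = attention,
                 spatial_kernel = as.integer(spatial_kernel),
                 reduction = as.integer(reduction)),
            class = "arch_config")
}

level_channels <- function(arch, l) arch$base_channels * 2L^(l - 1L)

# Level feature block: residual by default, RSCAB when configured.
feat_params <- function(arch, c_in, c_out) {
  if (arch$attention == "rscab")
    rscab_params(c_in, c_out, arch$spatial_kernel, arch$reduction)
  else
    residual_block_params(c_in, c_out, arch$kernel_size)
}

feat_fw <- function(arch, p, x, training) {
  if (arch$attention == "rscab") rscab_fw(p, x, training)
  else rb_fw(p, x, training)
}

feat_bw <- function(arch, p, cache, gout) {
  if (arch$attention == "rscab") rscab_bw(p, cache, gout)
  else rb_bw(p, cache, gout)
}

#' Build a segmentation model
#'
#' Constructs the residual attention U-Net with freshly initialized
#' weights (scaled-Gaussian initialization, see [init_weights()]).
#'
#' @param arch An [arch_config()].
#' @param seed Integer seed for weight initialization; when `NULL` the
#'   current RNG state is used.
#' @return An object of class `"busseg_model"`.
#' @export
build_model <- function(arch = arch_config(), seed = NULL) {
  stopifnot(inherits(arch, "arch_config"))
  maker <- function() {
    depth <- arch$depth
    params <- list(enc = vector("list", depth),
                   dec = vector("list", depth - 1L))
    c_prev <- 1L
    for (l in seq_len(depth)) {
      ch <- level_channels(arch, l)
      params$enc[[l]] <- feat_params(arch, c_prev, ch)
      c_prev <- ch
    }
    if (arch$attention == "scab") {
      params$att <- vector("list", depth - 1L)
      for (l in seq_len(depth - 1L))
        params$att[[l]] <- scab_params(level_channels(arch, l),
                                       arch$spatial_kernel, arch$reduction)
    }
    for (l in seq_len(depth - 1L)) {
      ch <- level_channels(arch, l)
      params$dec[[l]] <- list(
        upconv = cbr_params(arch$kernel_size, 2L * ch, ch),
        block = feat_params(arch, 2L * ch, ch))
    }
    params$head <- conv_params(1L, level_channels(arch, 1L), 1L)
    params
  }
  params <- if (is.null(seed)) maker() else withr::with_seed(seed, maker())
  model <- new.env(parent = emptyenv())
  model$arch <- arch
  model$params <- params
  class(model) <- "busseg_model"
  model
}

check_input_size <- function(arch, H, W) {
  f <- 2L^(arch$depth - 1L)
  if (H %% f != 0L || W %% f != 0L)
    stop("input size ", H, "x", W, " is not divisible by 2^(depth-1) = ", f)
}

unet_fw <- function(model, x, training = FALSE) {
  arch <- model$arch
  p <- model$params
  d <- dim(x)
  check_input_size(arch, d[1L], d[2L])
  depth <- arch$depth
  caches <- list(enc = vector("list", depth),
                 pool = vector("list", depth - 1L),
                 att = vector("list", depth - 1L),
                 up = vector("list", depth - 1L),
                 upconv = vector("list", depth - 1L),
                 dec = vector("list", depth - 1L))
  skips <- vector("list", depth - 1L)
  h <- x
  for (l in seq_len(depth)) {
    fb <- feat_fw(arch, p$enc[[l]], h, training)
    caches$enc[[l]] <- fb
    if (l < depth) {
      skips[[l]] <- fb$out
      pl <- maxpool2_fw(fb$out)
      caches$pool[[l]] <- pl
      h <- pl$out
    } else {
      h <- fb$out
    }
  }
  for (l in rev(seq_len(depth - 1L))) {
    up <- upsample2_fw(h)
    caches$up[[l]] <- up
    uc <- cbr_fw(p$dec[[l]]$upconv, up$out, training)
    caches$upconv[[l]] <- uc
    s <- skips[[l]]
    if (arch$attention == "scab") {
      at <- scab_fw(p$att[[l]], s, training)
      caches$att[[l]] <- at
      s <- at$out
    }
    cc <- concat_ch(s, uc$out)
    db <- feat_fw(arch, p$dec[[l]]$block, cc, training)
    caches$dec[[l]] <- db
    h <- db$out
  }
  hd <- conv2d_fw(h, p$head$W, p$head$b, 1L)
  sg <- sigmoid_fw(hd$out)
  caches$head <- hd
  caches$sig <- sg
  list(out = sg$out, caches = caches)
}

# Backward pass: `gout` is the gradient of the loss w.r.t. the sigmoid
# output probabilities.  Returns a gradient tree parallel to model$params.
unet_bw <- function(model, fwres, gout) {
  arch <- model$arch
  p <- model$params
  cs <- fwres$caches
  depth <- arch$depth
  grads <- list(enc = vector("list", depth),
                dec = vector("list", depth - 1L))
  if (arch$attention == "scab")
    grads$att <- vector("list", depth - 1L)
  g <- sigmoid_bw(cs$sig, gout)
  gh <- conv2d_bw(cs$head, g, p$head$W)
  grads$head <- list(W = gh$dW, b = gh$db)
  g <- gh$dx
  gskip <- vector("list", depth - 1L)
  for (l in seq_len(depth - 1L)) {
    gd <- feat_bw(arch, p$dec[[l]]$block, cs$dec[[l]], g)
    ch <- level_channels(arch, l)
    sp <- split_ch(gd$dx, ch)
    gs <- sp$g1
    if (arch$attention == "scab") {
      ga <- scab_bw(p$att[[l]], cs$att[[l]], gs)
      grads$att[[l]] <- ga$grads
      gs <- ga$dx
    }
    gskip[[l]] <- gs
    gu <- cbr_bw(p$dec[[l]]$upconv, cs$upconv[[l]], sp$g2)
    grads$dec[[l]] <- list(upconv = gu$grads, block = gd$grads)
    g <- upsample2_bw(cs$up[[l]], gu$dx)
  }
  for (l in rev(seq_len(depth))) {
    if (l < depth)
      g <- maxpool2_bw(cs$pool[[l]], g) + gskip[[l]]
    ge <- feat_bw(arch, p$enc[[l]], cs$enc[[l]], g)
    grads$enc[[l]] <- ge$grads
    g <- ge$dx
  }
  grads
}

# --- parameter bookkeeping --------------------------------------------------

trainable_fields <- c("W", "b", "gamma", "beta", "W1", "b1", "W2", "b2")

# Ordered list of references (environment + field + path) to every
# trainable array in a parameter tree.
param_refs <- function(tree, path = character()) {
  if (is.environment(tree)) {
    fields <- intersect(trainable_fields, ls(tree))
    return(lapply(fields, function(f)
      list(env = tree, field = f, path = paste(c(path, f), collapse = "/"))))
  }
  if (is.list(tree)) {
    nms <- names(tree)
    if (is.null(nms)) nms <- as.character(seq_along(tree))
    out <- list()
    for (i in seq_along(tree))
      out <- c(out, param_refs(tree[[i]], c(path, nms[i])))
    return(out)
  }
  list()
}

# Flatten a gradient tree (nested plain lists) into a path-named list.
grad_flatten <- function(tree, path = character()) {
  if (is.list(tree)) {
    nms <- names(tree)
    if (is.null(nms)) nms <- as.character(seq_along(tree))
    out <- list()
    for (i in seq_along(tree))
      out <- c(out, grad_flatten(tree[[i]], c(path, nms[i])))
    return(out)
  }
  stats::setNames(list(tree), paste(path, collapse = "/"))
}

# Deep copy of all parameter environments (weights, biases, batch-norm
# statistics) into plain nested lists, and back.
state_dict <- function(tree) {
  if (is.environment(tree)) return(as.list(tree, all.names = TRUE))
  if (is.list(tree)) return(lapply(tree, state_dict))
  tree
}

load_state_dict <- function(tree, sd) {
  if (is.environment(tree)) {
    for (f in names(sd)) assign(f, sd[[f]], envir = tree)
    return(invisible(tree))
  }
  if (is.list(tree))
    for (i in seq_along(tree)) load_state_dict(tree[[i]], sd[[i]])
  invisible(tree)
}

#' Number of trainable parameters
#'
#' @param model A `"busseg_model"`.
#' @return Total count of trainable weights, biases and normalization
#'   parameters (batch-norm running statistics excluded).
#' @export
n_parameters <- function(model) {
  refs <- param_refs(model$params)
  sum(vapply(refs, function(r) length(r$env[[r$field]]), numeric(1)))
}

#' @export
print.busseg_model <- function(x, ...) {
  a <- x$arch
  cat("<busseg_model> residual attention U-Net\n")
  cat("  depth:", a$depth, " base channels:", a$base_channels,
      " kernel:", a$kernel_size, "x", a$kernel_size, "\n")
  cat("  attention:", a$attention, "\n")
  cat("  trainable parameters:", n_parameters(x), "\n")
  invisible(x)
}

batch_tensor <- function(images) {
  d <- dim(images[[1]])
  x <- array(0, c(d[1L], d[2L], length(images), 1L))
  for (i in seq_along(images)) x[, , i, 1L] <- images[[i]]
  x
}

#' Predict lesion probability maps
#'
#' Runs the network in evaluation mode (batch-norm running statistics).
#'
#' @param object A `"busseg_model"`.
#' @param images A single matrix in `[0, 1]` or a list of such matrices,
#'   all the same size.
#' @param type `"prob"` for probability maps, `"mask"` for masks
#'   binarized at `threshold`.
#' @param threshold Binarization threshold for `type = "mask"`.
#' @param batch_size Images per forward pass.
#' @param ... Unused.
#' @return A matrix (single input) or list of matrices.
#' @export
predict.busseg_model <- function(object, images, type = c("prob", "mask"),
                                 threshold = 0.5, batch_size = 8L, ...) {
  type <- match.arg(type)
  single <- is.matrix(images)
  if (single) images <- list(images)
  out <- vector("list", length(images))
  i <- 1L
  while (i <= length(images)) {
    j <- min(i + batch_size - 1L, length(images))
    x <- batch_tensor(images[i:j])
    pr <- unet_fw(object, x, training = FALSE)$out
    for (k in i:j) {
      m <- matrix(pr[, , k - i + 1L, 1L], dim(x)[1L], dim(x)[2L])
      if (type == "mask") m <- (m > threshold) * 1
      out[[k]] <- m
    }
    i <- j + 1L
  }
  if (single) out[[1]] else out
}
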