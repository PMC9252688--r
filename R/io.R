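# Image, checkpoint and configuration I/O.  Grayscale images travel as
# matrices in [0, 1]; 8-bit output is written as PNG and 16-bit output
# (probability maps) as TIFF, both lossless.

img_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") return("png")
  if (ext %in% c("tif", "tiff")) return("tiff")
  stop("unsupported image format '", ext, "' for ", path,
       " (PNG and TIFF are supported)")
}

#' Read a grayscale image
#'
#' Reads a PNG or TIFF image and returns a matrix scaled to `[0, 1]` by
#' the file's bit depth.  RGB images are collapsed by luminance
#' (0.299 R + 0.587 G + 0.114 B); an alpha channel is dropped.
#'
#' @param path Path to a PNG or TIFF file.
#' @return A numeric matrix in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- switch(img_format(path),
                png = png::readPNG(path),
                tiff = tiff::readTIFF(path))
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] >= 3L)
      img <- 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
    else
      img <- img[, , 1L]
  }
  img
}

#' Write a grayscale image
#'
#' 8-bit output is PNG; 16-bit output is TIFF (the installed PNG writer
#' is 8-bit).  Round-tripping a `[0, 1]` matrix at 16 bits is accurate
#' to `1 / (2^16 - 1)`.
#'
#' @param image Matrix in `[0, 1]`.
#' @param path Output path; extension must match the bit depth (`.png`
#'   for 8, `.tif`/`.tiff` for 16).
#' @param bits 8 or 16.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bits = 8L) {
  image <- pmin(pmax(image, 0), 1)
  if (bits == 8L) {
    if (img_format(path) != "png") stop("8-bit images are written as PNG")
    png::writePNG(image, path)
  } else if (bits == 16L) {
    if (img_format(path) != "tiff") stop("16-bit images are written as TIFF")
    tiff::writeTIFF(image, path, bits.per.sample = 16L)
  } else stop("bits must be 8 or 16")
  invisible(path)
}

#' Read a binary mask
#'
#' Reads an image and binarizes it: values above 0.5 (after bit-depth
#' scaling) become 1.  A 0/255 8-bit mask PNG therefore maps to 0/1.
#'
#' @param path Path to a PNG or TIFF file.
#' @return A 0/1 matrix.
#' @export
read_mask <- function(path) (read_image(path) > 0.5) * 1

#' Write a binary mask as 0/255 PNG
#'
#' @param mask 0/1 matrix.
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  write_image(as_binary_mask(mask), path, bits = 8L)
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds a copy of the architecture configuration
#' together with all weights and batch-norm statistics, so
#' [load_model()] can rebuild the network without further input.
#'
#' @param model A `"busseg_model"`.
#' @param path Checkpoint file path (RDS format).
#' @return `path` invisibly (save); the restored model (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "busseg_model"))
  saveRDS(list(arch = model$arch, state = state_dict(model$params)), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$arch, seed = 0L)
  load_state_dict(model$params, ck$state)
  model
}

# --- run configuration ------------------------------------------------------

#' Default run configuration
#'
#' The nested configuration consumed by the command-line entry points:
#' sections `phantom`, `preprocess`, `arch`, `loss`, `train` and `seed`.
#' `train$eps` is the learning rate; the default 5e-3 targets short
#' desk-scale runs (tens of epochs on hundreds of images).
#'
#' @return A nested list of defaults.
#' @export
default_config <- function() {
  list(
    phantom = list(height = 64L, width = 64L, lesion_count = 1L,
                   lesion_area_fraction = 0.3, contrast = 0.15,
                   speckle_sigma = 0.3, bias_field_amplitude = 0.2),
    preprocess = list(denoise = TRUE, equalize = TRUE, sigma_spatial = 3,
                      sigma_range = 0.1, radius = 9L, levels = 256L),
    arch = list(depth = 3L, base_channels = 8L, kernel_size = 3L,
                attention = "scab", spatial_kernel = 7L, reduction = 8L),
    loss = list(tau = 1.5e-3, gamma = 1.0, clamp_eps = 1e-7,
                which = "composite"),
    train = list(epochs = 10L, batch_size = 8L, eps = 5e-3, phi1 = 0.95,
                 phi2 = 0.999, sigma = 1.5e-8, val_fraction = 0.2,
                 threshold = 0.5),
    seed = 1L)
}

merge_config <- function(base, override, path = character()) {
  for (k in names(override)) {
    if (!k %in% names(base))
      stop("unknown configuration key: ",
           paste(c(path, k), collapse = "$"))
    if (is.list(base[[k]]) && is.list(override[[k]]))
      base[[k]] <- merge_config(base[[k]], override[[k]], c(path, k))
    else
      base[[k]] <- override[[k]]
  }
  base
}

#' Read a YAML run configuration
#'
#' Values in the file override the [default_config()]; unknown keys are
#' rejected.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return The resolved configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg
}

write_resolved_config <- function(cfg, dir) {
  yaml::write_yaml(cfg, file.path(dir, "config_resolved.yaml"))
}

config_phantom <- function(cfg, seed) {
  do.call(phantom_config, c(cfg$phantom, list(seed = seed)))
}

config_arch <- function(cfg) do.call(arch_config, cfg$arch)

config_loss <- function(cfg) {
  loss_config(tau = cfg$loss$tau, gamma = cfg$loss$gamma,
              clamp_eps = cfg$loss$clamp_eps)
}

config_adam <- function(cfg) {
  adam_config(phi1 = cfg$train$phi1, phi2 = cfg$train$phi2,
              eps = cfg$train$eps, sigma = cfg$train$sigma)
}

#' Training configuration helper
#'
#' Convenience wrapper returning the Adam configuration for desk-scale
#' training: the long-run default learning rate 1.5e-4 is appropriate
#' for thousands of updates, while short phantom runs (a few hundred
#' updates) use a proportionally larger rate, 5e-3 by default.
#'
#' @param eps Learning rate.
#' @param ... Further arguments to [adam_config()].
#' @return An [adam_config()].
#' @export
train_config <- function(eps = 5e-3, ...) adam_config(eps = eps, ...)
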