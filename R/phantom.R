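# Synthetic ultrasound phantom generator.  Emulates the three inherent
# characteristics of breast ultrasound images -- high (speckle) noise,
# low lesion/background contrast, and smooth intensity nonuniformity --
# with exactly known lesion masks, so every downstream stage of the
# pipeline can be exercised and verified without clinical data.

#' Phantom configuration
#'
#' @param height,width Image size in pixels (at least 16 each).
#' @param lesion_count Number of lesions to place (0 gives a pure
#'   background image with an empty mask).
#' @param lesion_area_fraction Target fraction of the image area covered
#'   by each lesion, in (0, 1).
#' @param contrast Mean-intensity gap between background and lesion on
#'   the [0, 1] scale, in (0, 1].  Lesions are hypoechoic (darker than
#'   background), the typical appearance of breast masses.  The default
#'   0.15 is a deliberately low-contrast regime.
#' @param speckle_sigma Scale of the multiplicative speckle,
#'   `image * (1 + speckle_sigma * N(0,1))`; 0 disables noise.  The
#'   default 0.3 is strong granular noise.
#' @param bias_field_amplitude Amplitude of the smooth multiplicative
#'   nonuniformity field (a random low-order polynomial normalized to
#'   mean 1); 0 disables it.
#' @param seed Integer seed; the generated pair is a pure function of
#'   the configuration including this seed.
#' @return An object of class `"phantom_config"`.
#' @export
phantom_config <- function(height = 64L, width = 64L, lesion_count = 1L,
                           lesion_area_fraction = 0.3, contrast = 0.15,
                           speckle_sigma = 0.3, bias_field_amplitude = 0.2,
                           seed = 1L) {
  bad <- function(field, why) stop("invalid ", field, ": ", why)
  if (!is.numeric(height) || height < 16) bad("height", "must be >= 16")
  if (!is.numeric(width) || width < 16) bad("width", "must be >= 16")
  if (lesion_count < 0) bad("lesion_count", "must be >= 0")
  if (lesion_area_fraction <= 0 || lesion_area_fraction >= 1)
    bad("lesion_area_fraction", "must be in (0, 1)")
  if (contrast <= 0 || contrast > 1) bad("contrast", "must be in (0, 1]")
  if (speckle_sigma < 0) bad("speckle_sigma", "must be >= 0")
  if (bias_field_amplitude < 0) bad("bias_field_amplitude", "must be >= 0")
  structure(list(height = as.integer(height), width = as.integer(width),
                 lesion_count = as.integer(lesion_count),
                 lesion_area_fraction = lesion_area_fraction,
                 contrast = contrast, speckle_sigma = speckle_sigma,
                 bias_field_amplitude = bias_field_amplitude,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Background reference level; lesions sit at bg_level - contrast.
.bg_level <- 0.55

# One lesion mask: an ellipse with a radial Fourier perturbation of
# harmonics 3-5, guaranteed not to touch the image border.
lesion_mask <- function(H, W, area_frac, avoid = NULL) {
  margin <- 2
  r0 <- sqrt(area_frac * H * W / pi)
  aspect <- stats::runif(1, 0.65, 1)
  a <- r0 / sqrt(aspect)
  b <- r0 * sqrt(aspect)
  rot <- stats::runif(1, 0, pi)
  harm <- 3:5
  amp <- stats::runif(3, 0, 0.08)
  phase <- stats::runif(3, 0, 2 * pi)
  ext <- a * (1 + sum(amp))          # maximal radial extent
  max_ext <- min(H, W) / 2 - margin - 1
  if (ext > max_ext) {               # shrink oversized lesions to fit
    sc <- max_ext / ext
    a <- a * sc
    b <- b * sc
    ext <- max_ext
  }
  lo_r <- 1 + margin + ext
  hi_r <- H - margin - ext
  lo_c <- 1 + margin + ext
  hi_c <- W - margin - ext
  pick_center <- function() c(stats::runif(1, lo_r, hi_r),
                              stats::runif(1, lo_c, hi_c))
  ctr <- pick_center()
  if (!is.null(avoid)) {
    for (try in 1:20) {
      ok <- all(sqrt((avoid[, 1] - ctr[1])^2 + (avoid[, 2] - ctr[2])^2) >
                  ext + avoid[, 3])
      if (ok) break
      ctr <- pick_center()
    }
  }
  rr <- matrix(seq_len(H), H, W) - ctr[1]
  cc <- matrix(seq_len(W), H, W, byrow = TRUE) - ctr[2]
  u <- (rr * cos(rot) + cc * sin(rot)) / a
  v <- (-rr * sin(rot) + cc * cos(rot)) / b
  rho <- sqrt(u * u + v * v)
  ang <- atan2(v, u)
  lim <- 1 + amp[1] * cos(harm[1] * ang + phase[1]) +
    amp[2] * cos(harm[2] * ang + phase[2]) +
    amp[3] * cos(harm[3] * ang + phase[3])
  list(mask = (rho <= lim) * 1, center = ctr, ext = ext)
}

# Smooth multiplicative bias field: random quadratic polynomial over the
# image, scaled to peak deviation `amplitude` and normalized to mean 1.
bias_field <- function(H, W, amplitude) {
  if (amplitude == 0) return(matrix(1, H, W))
  X <- matrix(seq(-1, 1, length.out = W), H, W, byrow = TRUE)
  Y <- matrix(seq(-1, 1, length.out = H), H, W)
  co <- stats::runif(5, -1, 1)
  f <- co[1] * X + co[2] * Y + co[3] * X * Y + co[4] * X * X + co[5] * Y * Y
  f <- f - mean(f)
  mx <- max(abs(f))
  if (mx > 0) f <- f / mx
  1 + amplitude * f
}

#' Generate one synthetic phantom
#'
#' Builds an image/mask pair: smooth-edged irregular lesions (perturbed
#' ellipses) darker than the background by `contrast`, multiplied by a
#' smooth bias field and multiplicative Gaussian speckle, clipped to
#' `[0, 1]`.  The mask marks the exact lesion support.  Identical
#' configurations (including the seed) give bit-identical output; the
#' global RNG state is left untouched.
#'
#' @param config A [phantom_config()].
#' @return A list (class `"segmentation_pair"`) with `image` and `mask`
#'   matrices of size height x width.
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  H <- config$height
  W <- config$width
  withr::with_seed(config$seed, {
    mask <- matrix(0, H, W)
    placed <- NULL
    if (config$lesion_count > 0) {
      for (i in seq_len(config$lesion_count)) {
        lm <- lesion_mask(H, W, config$lesion_area_fraction, placed)
        mask <- pmax(mask, lm$mask)
        placed <- rbind(placed, c(lm$center, lm$ext))
      }
    }
    clean <- matrix(.bg_level, H, W)
    clean <- clean - config$contrast * mask
    bf <- bias_field(H, W, config$bias_field_amplitude)
    noise <- matrix(stats::rnorm(H * W), H, W)
    img <- bf * clean * (1 + config$speckle_sigma * noise)
    img <- pmin(pmax(img, 0), 1)
    structure(list(image = img, mask = mask), class = "segmentation_pair")
  })
}

#' Generate a phantom dataset
#'
#' Draws `n` independent phantoms; each item uses a seed derived from
#' the top-level `seed`, so the whole dataset is reproducible and item
#' `i` equals `generate_phantom()` called with its derived seed.
#'
#' @param config A [phantom_config()]; its own `seed` field is replaced
#'   by the derived per-item seeds.
#' @param n Number of pairs (>= 1).
#' @param seed Top-level integer seed.
#' @return A list of `n` segmentation pairs.
#' @export
generate_dataset <- function(config, n, seed = config$seed) {
  stopifnot(inherits(config, "phantom_config"))
  if (n < 1) stop("n must be >= 1")
  item_seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max - 1L, n))
  lapply(item_seeds, function(s) {
    cfg <- config
    cfg$seed <- s
    generate_phantom(cfg)
  })
}

#' @export
print.segmentation_pair <- function(x, ...) {
  cat("<segmentation_pair>", nrow(x$image), "x", ncol(x$image),
      " lesion pixels:", sum(x$mask), "\n")
  invisible(x)
}
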