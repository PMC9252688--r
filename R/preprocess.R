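# Preprocessing chain for ultrasound images: region-of-interest
# cropping, edge-preserving bilateral-filter denoising, and gray
# histogram equalization, applied in that order.

#' Region-of-interest box
#'
#' Rectangular box given by two diagonal corner indices, 0-based and
#' half-open on the max side: rows `row_min .. row_max - 1` and columns
#' `col_min .. col_max - 1` are inside.  The cropped shape is therefore
#' `(row_max - row_min) x (col_max - col_min)`.
#'
#' @param row_min,col_min,row_max,col_max Pixel indices, 0-based,
#'   half-open on the max side.
#' @return An object of class `"roi_box"`.
#' @export
roi_box <- function(row_min, col_min, row_max, col_max) {
  b <- list(row_min = as.integer(row_min), col_min = as.integer(col_min),
            row_max = as.integer(row_max), col_max = as.integer(col_max))
  if (b$row_min < 0L || b$col_min < 0L)
    stop("box indices must be >= 0")
  if (b$row_min >= b$row_max || b$col_min >= b$col_max)
    stop("zero-area box: min indices must be strictly below max indices")
  structure(b, class = "roi_box")
}

check_box_bounds <- function(box, H, W) {
  stopifnot(inherits(box, "roi_box"))
  if (box$row_max > H || box$col_max > W)
    stop("box (", box$row_min, ",", box$col_min, ",", box$row_max, ",",
         box$col_max, ") exceeds the ", H, "x", W, " image")
}

#' Crop an image/mask pair to a region of interest
#'
#' @param pair A segmentation pair (`list(image =, mask =)`; the mask may
#'   be `NULL`), or a plain image matrix.
#' @param box An [roi_box()] within the image bounds.
#' @return The cropped pair (or matrix), shape
#'   `(row_max - row_min) x (col_max - col_min)`.
#' @export
crop_roi <- function(pair, box) {
  plain <- is.matrix(pair)
  if (plain) pair <- list(image = pair, mask = NULL)
  check_box_bounds(box, nrow(pair$image), ncol(pair$image))
  ri <- (box$row_min + 1L):box$row_max
  ci <- (box$col_min + 1L):box$col_max
  img <- pair$image[ri, ci, drop = FALSE]
  if (plain) return(img)
  out <- list(image = img,
              mask = if (!is.null(pair$mask))
                pair$mask[ri, ci, drop = FALSE])
  class(out) <- class(pair)
  out
}

#' Lesion fraction inside a box
#'
#' Fraction of the box area occupied by mask foreground; used to check a
#' region-of-interest selection against the convention that the tumor
#' occupies about 30% of the box.
#'
#' @param mask Binary 0/1 matrix.
#' @param box An [roi_box()] within the mask bounds.
#' @return A number in `[0, 1]`.
#' @export
roi_tumor_fraction <- function(mask, box) {
  mask <- as_binary_mask(mask)
  check_box_bounds(box, nrow(mask), ncol(mask))
  sub <- mask[(box$row_min + 1L):box$row_max,
              (box$col_min + 1L):box$col_max, drop = FALSE]
  sum(sub) / length(sub)
}

#' Automatic ROI box around a lesion
#'
#' Inflates the tight bounding box of the mask foreground, keeping its
#' center, until the lesion occupies about `target_fraction` of the box
#' (clipped at the image border).  A convenience for synthetic data; on
#' clinical images the box is operator-chosen.
#'
#' @param mask Binary 0/1 matrix with nonempty foreground.
#' @param target_fraction Desired lesion/box area ratio.
#' @return An [roi_box()].
#' @export
auto_roi_box <- function(mask, target_fraction = 0.3) {
  mask <- as_binary_mask(mask)
  idx <- which(mask == 1, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty; cannot derive a box")
  area <- nrow(idx)
  r0 <- min(idx[, 1]) - 1L
  r1 <- max(idx[, 1])
  c0 <- min(idx[, 2]) - 1L
  c1 <- max(idx[, 2])
  # inflate both sides equally to reach area / target_fraction
  want <- area / target_fraction
  h <- r1 - r0
  w <- c1 - c0
  s <- sqrt(want / (h * w))
  dh <- round((s - 1) * h / 2)
  dw <- round((s - 1) * w / 2)
  roi_box(max(0L, r0 - dh), max(0L, c0 - dw),
          min(nrow(mask), r1 + dh), min(ncol(mask), c1 + dw))
}

#' Bilateral-filter denoising
#'
#' Each output pixel is the normalized average of its
#' `(2 radius + 1)^2` neighborhood, weighted by both spatial proximity
#' (Gaussian, `sigma_spatial`) and intensity similarity (Gaussian,
#' `sigma_range`), which smooths speckle while preserving lesion edges.
#' Near the image border the weights are renormalized over the pixels
#' that exist.
#'
#' @param image Grayscale matrix in `[0, 1]`.
#' @param sigma_spatial Spatial Gaussian scale in pixels.
#' @param sigma_range Intensity Gaussian scale (for `[0, 1]` images).
#' @param radius Neighborhood radius in pixels; defaults to
#'   `3 * sigma_spatial`.
#' @return The filtered matrix; its range stays within the input range.
#' @export
bilateral_denoise <- function(image, sigma_spatial = 3,
                              sigma_range = 0.1,
                              radius = ceiling(3 * sigma_spatial)) {
  if (sigma_spatial <= 0 || sigma_range <= 0)
    stop("sigma_spatial and sigma_range must be > 0")
  if (radius < 1) stop("radius must be >= 1")
  H <- nrow(image)
  W <- ncol(image)
  num <- matrix(0, H, W)
  den <- matrix(0, H, W)
  for (di in -radius:radius) {
    ti <- max(1L, 1L - di):min(H, H - di)   # target rows with valid neighbor
    si <- ti + di
    for (dj in -radius:radius) {
      tj <- max(1L, 1L - dj):min(W, W - dj)
      sj <- tj + dj
      ws <- exp(-(di * di + dj * dj) / (2 * sigma_spatial^2))
      nb <- image[si, sj, drop = FALSE]
      ct <- image[ti, tj, drop = FALSE]
      w <- ws * exp(-(nb - ct)^2 / (2 * sigma_range^2))
      num[ti, tj] <- num[ti, tj] + w * nb
      den[ti, tj] <- den[ti, tj] + w
    }
  }
  num / den
}

#' Gray histogram equalization
#'
#' Quantizes the image to `levels` gray levels, forms the empirical
#' cumulative distribution `e_j = sum_{i<=j} c_i / c` over the region,
#' and maps every pixel of level j to `e_j`.  The map is non-strictly
#' monotone, so pixel rank order is preserved; output values lie in
#' `(0, 1]`.
#'
#' @param image Grayscale matrix in `[0, 1]`.
#' @param levels Number of gray levels J (>= 2; default 256).
#' @return The equalized matrix.
#' @export
hist_equalize <- function(image, levels = 256L) {
  if (levels < 2L) stop("levels must be >= 2")
  if (any(image < 0 | image > 1)) stop("image values must lie in [0, 1]")
  q <- pmin(floor(image * levels) + 1L, levels)   # gray level 1..J
  counts <- tabulate(q, nbins = levels)
  cdf <- cumsum(counts) / length(image)
  out <- cdf[q]
  dim(out) <- dim(image)
  out
}

#' Full preprocessing chain
#'
#' Crop to the region of interest, denoise with the bilateral filter,
#' then equalize the gray histogram of the cropped region -- in that
#' order.  Each stage can be disabled.
#'
#' @param pair A segmentation pair or plain image matrix.
#' @param box Optional [roi_box()]; `NULL` skips cropping.
#' @param denoise,equalize Enable the respective stage.
#' @param sigma_spatial,sigma_range,radius Bilateral filter parameters,
#'   see [bilateral_denoise()].
#' @param levels Histogram equalization levels.
#' @return The processed pair (or matrix).
#' @export
preprocess_pair <- function(pair, box = NULL, denoise = TRUE,
                            equalize = TRUE, sigma_spatial = 3,
                            sigma_range = 0.1,
                            radius = ceiling(3 * sigma_spatial),
                            levels = 256L) {
  plain <- is.matrix(pair)
  if (plain) pair <- list(image = pair, mask = NULL)
  if (!is.null(box)) pair <- crop_roi(pair, box)
  if (denoise)
    pair$image <- bilateral_denoise(pair$image, sigma_spatial,
                                    sigma_range, radius)
  if (equalize) pair$image <- hist_equalize(pair$image, levels)
  if (plain) pair$image else pair
}
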