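# Evaluation metrics for binary segmentations: region overlap (Dice,
# IoU) and boundary distances (Hausdorff distance, mean absolute
# boundary deviation).  Masks are 0/1 matrices; probability maps can be
# binarized first with a threshold.

as_binary_mask <- function(m, threshold = NULL) {
  if (!is.matrix(m)) stop("a mask must be a matrix")
  if (!is.null(threshold)) return((m > threshold) * 1)
  if (any(m != 0 & m != 1)) stop("mask contains values other than 0 and 1")
  m * 1
}

check_same_shape <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    stop("masks have different shapes (", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"), ")")
}

#' Dice coefficient
#'
#' Region overlap `2 |R ∩ G| / (|R| + |G|)` between a segmented region R
#' and ground truth G.  1 is perfect agreement, 0 disjoint regions.  When
#' both masks are empty the value is defined as 1 (with a warning).
#'
#' @param pred,truth Binary 0/1 matrices of equal shape.
#' @param warn Warn on the both-empty convention.
#' @return A number in `[0, 1]`.
#' @export
dice_coefficient <- function(pred, truth, warn = TRUE) {
  pred <- as_binary_mask(pred)
  truth <- as_binary_mask(truth)
  check_same_shape(pred, truth)
  np <- sum(pred)
  nt <- sum(truth)
  if (np + nt == 0) {
    if (warn) warning("both masks empty; Dice defined as 1")
    return(1)
  }
  2 * sum(pred * truth) / (np + nt)
}

#' Intersection over union (Jaccard index)
#'
#' `|R ∩ G| / |R ∪ G|`; related to Dice by `dice = 2 iou / (1 + iou)`.
#'
#' @inheritParams dice_coefficient
#' @return A number in `[0, 1]`.
#' @export
iou <- function(pred, truth, warn = TRUE) {
  pred <- as_binary_mask(pred)
  truth <- as_binary_mask(truth)
  check_same_shape(pred, truth)
  inter <- sum(pred * truth)
  union <- sum(pred) + sum(truth) - inter
  if (union == 0) {
    if (warn) warning("both masks empty; IoU defined as 1")
    return(1)
  }
  inter / union
}

#' Boundary pixels of a binary mask
#'
#' A region pixel belongs to the boundary when at least one of its
#' 4-neighbors is background; pixels on the image edge count their
#' missing neighbors as background.
#'
#' @param mask Binary 0/1 matrix.
#' @return Integer matrix of boundary pixel coordinates (row, col), one
#'   pixel per row.
#' @export
mask_boundary <- function(mask) {
  mask <- as_binary_mask(mask)
  H <- nrow(mask)
  W <- ncol(mask)
  pad <- matrix(0, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- mask
  inner <- pad[2:(H + 1L), 2:(W + 1L)]
  nb_min <- pmin(pad[1:H, 2:(W + 1L)], pad[3:(H + 2L), 2:(W + 1L)],
                 pad[2:(H + 1L), 1:W], pad[2:(H + 1L), 3:(W + 2L)])
  which(inner == 1 & nb_min == 0, arr.ind = TRUE)
}

# Directed minimum distances: for each point of `a`, the Euclidean
# distance to the nearest point of `b`.  Coordinates are n x 2 matrices.
min_dists <- function(a, b) {
  d2 <- outer(a[, 1L], b[, 1L], "-")^2 + outer(a[, 2L], b[, 2L], "-")^2
  sqrt(apply(d2, 1L, min))
}

boundary_pair <- function(pred, truth, what) {
  pred <- as_binary_mask(pred)
  truth <- as_binary_mask(truth)
  check_same_shape(pred, truth)
  bp <- mask_boundary(pred)
  bt <- mask_boundary(truth)
  if (nrow(bp) == 0L)
    stop(what, " undefined: the predicted mask has an empty boundary")
  if (nrow(bt) == 0L)
    stop(what, " undefined: the ground-truth mask has an empty boundary")
  list(bp = bp, bt = bt)
}

#' Hausdorff distance between mask boundaries
#'
#' Worst-case boundary disagreement
#' `max(max_x min_y ||x - y||, max_y min_x ||x - y||)` over the boundary
#' pixels of the two masks, in Euclidean pixel units.
#'
#' @inheritParams dice_coefficient
#' @return A non-negative number (pixels).
#' @export
hausdorff_distance <- function(pred, truth) {
  b <- boundary_pair(pred, truth, "Hausdorff distance")
  max(max(min_dists(b$bp, b$bt)), max(min_dists(b$bt, b$bp)))
}

#' Mean absolute boundary deviation
#'
#' Symmetric average boundary disagreement
#' `(mean_x d(x, dG) + mean_y d(y, dR)) / 2` where the means run over the
#' boundary pixels of the predicted and true masks respectively.
#'
#' @inheritParams dice_coefficient
#' @return A non-negative number (pixels).
#' @export
mad_distance <- function(pred, truth) {
  b <- boundary_pair(pred, truth, "mean absolute deviation")
  (mean(min_dists(b$bp, b$bt)) + mean(min_dists(b$bt, b$bp))) / 2
}

#' Evaluate a set of segmentations
#'
#' Computes Dice, IoU, Hausdorff distance and mean absolute boundary
#' deviation for each prediction/truth pair and their unweighted means.
#' Pairs on which the boundary metrics are undefined (an empty mask on
#' either side) get `NA` for hd/mad and are skipped in those means.
#'
#' @param pred,truth Lists of binary masks (or probability maps if
#'   `threshold` is given), pairwise the same shape.
#' @param ids Optional identifiers for the per-image rows.
#' @param threshold Optional binarization threshold applied to `pred`.
#' @return A list of class `"metrics_report"`: `per_image` (data.frame
#'   id/dice/iou/hd/mad), `mean` (named numeric), `n_images`,
#'   `n_boundary_skipped`.
#' @export
evaluate_set <- function(pred, truth, ids = NULL, threshold = NULL) {
  if (length(pred) != length(truth))
    stop("prediction and truth lists differ in length")
  if (length(pred) == 0L) stop("empty evaluation set")
  if (is.null(ids)) ids <- seq_along(pred)
  rows <- lapply(seq_along(pred), function(i) {
    p <- as_binary_mask(pred[[i]], threshold)
    t <- truth[[i]]
    hd <- tryCatch(hausdorff_distance(p, t), error = function(e) NA_real_)
    md <- tryCatch(mad_distance(p, t), error = function(e) NA_real_)
    data.frame(id = ids[i],
               dice = dice_coefficient(p, t, warn = FALSE),
               iou = iou(p, t, warn = FALSE), hd = hd, mad = md)
  })
  per <- do.call(rbind, rows)
  if (all(is.na(per$hd)) && all(is.na(per$dice)))
    stop("metrics undefined for every pair")
  structure(list(
    per_image = per,
    mean = c(dice = mean(per$dice), iou = mean(per$iou),
             hd = mean(per$hd, na.rm = TRUE),
             mad = mean(per$mad, na.rm = TRUE)),
    n_images = nrow(per),
    n_boundary_skipped = sum(is.na(per$hd))),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> over", x$n_images, "image(s)\n")
  m <- x$mean
  cat(sprintf("  Dice %.4f  IoU %.4f  HD %.3f px  MAD %.3f px\n",
              m["dice"], m["iou"], m["hd"], m["mad"]))
  if (x$n_boundary_skipped > 0)
    cat("  boundary metrics skipped on", x$n_boundary_skipped, "pair(s)\n")
  invisible(x)
}
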