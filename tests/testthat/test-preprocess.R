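test_that("roi boxes use the 0-based half-open convention", {
  img <- matrix(runif(100), 10, 10)
  expect_identical(crop_roi(img, roi_box(0, 0, 10, 10)), img)
  out <- crop_roi(img, roi_box(2, 3, 7, 9))
  expect_identical(dim(out), c(5L, 6L))
  expect_identical(out, img[3:7, 4:9])
  expect_error(roi_box(2, 3, 2, 9), "zero-area")
  expect_error(crop_roi(img, roi_box(0, 0, 11, 10)), "exceeds")
})

test_that("crop_roi carries image and mask together", {
  pair <- generate_phantom(phantom_config(seed = 2))
  box <- roi_box(4, 8, 40, 60)
  cr <- crop_roi(pair, box)
  expect_identical(dim(cr$image), c(36L, 52L))
  expect_identical(cr$mask, pair$mask[5:40, 9:60])
})

test_that("roi_tumor_fraction counts foreground over box area", {
  m <- matrix(0, 10, 10)
  m[1:5, 1:6] <- 1   # 30 pixels in the 100-pixel full box
  expect_equal(roi_tumor_fraction(m, roi_box(0, 0, 10, 10)), 0.30)
  expect_equal(roi_tumor_fraction(matrix(0, 10, 10), roi_box(0, 0, 10, 10)), 0)
})

test_that("auto box inflation brings the lesion near the 30% convention", {
  fr <- vapply(1:30, function(s) {
    p <- generate_phantom(phantom_config(lesion_area_fraction = 0.1, seed = s))
    roi_tumor_fraction(p$mask, auto_roi_box(p$mask, 0.3))
  }, numeric(1))
  expect_gt(mean(fr), 0.2)
  expect_lt(mean(fr), 0.4)
})

test_that("bilateral filter leaves constant images unchanged", {
  img <- matrix(0.42, 12, 12)
  expect_lt(max(abs(bilateral_denoise(img, 2, 0.1, 3) - img)), 1e-9)
})

test_that("bilateral filter equals the double-loop reference", {
  withr::with_seed(31, {
    img <- matrix(runif(81), 9, 9)
  })
  for (prm in list(c(1.5, 0.1, 2), c(3, 0.25, 4))) {
    got <- bilateral_denoise(img, prm[1], prm[2], prm[3])
    want <- oracle_bilateral(img, prm[1], prm[2], prm[3])
    expect_lt(max(abs(got - want)), 1e-6)
  }
  expect_error(bilateral_denoise(img, -1, 0.1), "sigma")
})

test_that("bilateral filter preserves a step edge better than Gaussian blur", {
  withr::with_seed(8, {
    img <- cbind(matrix(0, 20, 10), matrix(1, 20, 10)) +
      matrix(rnorm(400, sd = 0.05), 20)
    img <- pmin(pmax(img, 0), 1)
  })
  bil <- bilateral_denoise(img, 2, 0.1, 4)
  # sigma_range -> Inf degenerates to a plain spatial Gaussian blur
  gau <- bilateral_denoise(img, 2, 1e6, 4)
  edge <- function(x) mean(x[, 11:12]) - mean(x[, 9:10])
  expect_gte(edge(bil), edge(gau))
})

test_that("histogram equalization reproduces the 4-level worked example", {
  img <- matrix(c(0, 1, 2, 3) / 3, 2, 2)
  out <- hist_equalize(img, levels = 4)
  expect_equal(sort(as.vector(out)), c(0.25, 0.5, 0.75, 1.0))
  expect_error(hist_equalize(img, levels = 1), "levels")
})

test_that("histogram equalization maps constant images to 1", {
  expect_true(all(hist_equalize(matrix(0.37, 5, 5)) == 1))
})

test_that("histogram equalization preserves pixel rank order", {
  withr::with_seed(14, {
    for (rep in 1:10) {
      img <- matrix(runif(400), 20, 20)
      out <- hist_equalize(img, levels = 32)
      o <- order(img)
      expect_true(all(diff(out[o]) >= 0))
    }
  })
})

test_that("full-image crop leaves downstream metrics unchanged", {
  p <- generate_phantom(phantom_config(seed = 21))
  full <- roi_box(0, 0, nrow(p$image), ncol(p$image))
  cr <- crop_roi(p, full)
  pred <- generate_phantom(phantom_config(seed = 22))$mask
  expect_identical(dice_coefficient(pred, cr$mask),
                   dice_coefficient(pred, p$mask))
  expect_identical(hausdorff_distance(pred, cr$mask),
                   hausdorff_distance(pred, p$mask))
})

test_that("the preprocessing chain composes crop, denoise, equalize", {
  p <- generate_phantom(phantom_config(seed = 4))
  box <- auto_roi_box(p$mask, 0.3)
  out <- preprocess_pair(p, box = box, sigma_spatial = 1.5, radius = 3)
  manual <- hist_equalize(bilateral_denoise(crop_roi(p, box)$image,
                                            1.5, 0.1, 3), 256L)
  expect_identical(out$image, manual)
  expect_identical(dim(out$image), dim(out$mask))
})
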