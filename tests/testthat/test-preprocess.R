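test_that("Otsu threshold separates a two-class image and matches brute force", {
  half <- gray_image(matrix(rep(c(0, 255), each = 50), 10, 10))
  level <- otsu_threshold(half)
  expect_gt(level, 0)
  expect_lte(level, 255)
  expect_equal(sum(binarize(half, level)), 50)

  # bimodal populations: exhaustive search oracle over all 255 split levels
  set.seed(31)
  px <- c(pmin(pmax(round(rnorm(2000, 60, 10)), 0), 255),
          pmin(pmax(round(rnorm(2000, 180, 10)), 0), 255))
  img <- gray_image(matrix(px, 50, 80))
  expect_equal(otsu_threshold(img), brute_otsu(img))

  # the chosen level achieves at least the between-class variance of
  # EBImage's independent implementation (the variance curve has a flat
  # plateau between well-separated modes, so the argmax itself may differ)
  bcv <- function(L) {
    lo <- px[px < L]; hi <- px[px >= L]
    length(lo) * length(hi) / length(px)^2 * (mean(lo) - mean(hi))^2
  }
  eb <- EBImage::otsu(EBImage::Image(unclass(img) / 255),
                      range = c(0, 1), levels = 256) * 255
  expect_gte(bcv(otsu_threshold(img)) + 1e-9, bcv(ceiling(eb)))
  # and both separate the two populations
  expect_true(otsu_threshold(img) > 60 && otsu_threshold(img) < 180)
  expect_true(eb > 60 && eb < 180)
})

test_that("constant images have a degenerate histogram", {
  expect_error(otsu_threshold(gray_image(matrix(7, 5, 5))), "degenerate")
})

test_that("binarize thresholds with foreground >= level", {
  img <- gray_image(matrix(c(0, 255), 4, 4))
  expect_true(all(binarize(img, 0)))
  expect_false(any(binarize(img, 256 - 1) & unclass(img) < 255))
  chk <- gray_image(255 * (outer(1:6, 1:6, `+`) %% 2))
  expect_identical(binarize(chk, 128), unclass(chk) == 255)
})

test_that("object centroid is the rounded mean of foreground pixels", {
  m <- matrix(FALSE, 30, 60)
  m[11, 21] <- TRUE
  expect_equal(object_centroid(m), c(row = 11L, col = 21L))

  m <- matrix(FALSE, 10, 10)
  m[1, 1] <- TRUE; m[3, 5] <- TRUE
  expect_equal(object_centroid(m), c(row = 2L, col = 3L))

  # filled rectangle: mean has a .5 tie, resolved by rounding half up
  m <- matrix(FALSE, 40, 80)
  m[11:20, 31:50] <- TRUE
  expect_equal(object_centroid(m), c(row = 16L, col = 41L))

  expect_error(object_centroid(matrix(FALSE, 3, 3)), "empty mask")
})

test_that("ROI crop centers the window and clamps at borders", {
  img <- rand_image(480, 640, seed = 8)
  roi <- crop_roi(img, c(241, 321))
  expect_equal(dim(roi), c(160L, 480L))
  expect_identical(unclass(roi), unclass(img)[161:320, 81:560])

  # near-corner center: window shifted fully inside
  roi <- crop_roi(img, c(1, 1))
  expect_identical(unclass(roi), unclass(img)[1:160, 1:480])

  # exactly ROI-sized input is an identity crop wherever the center is
  small <- rand_image(160, 480, seed = 9)
  expect_identical(unclass(crop_roi(small, c(80, 240))), unclass(small))

  expect_error(crop_roi(rand_image(100, 100, seed = 1), c(50, 50)), "smaller")
})

test_that("resize follows round(dim * ratio) with bilinear interpolation", {
  roi <- rand_image(160, 480, seed = 12)
  out <- resize_image(roi, 0.4)
  expect_equal(dim(out), c(64L, 192L))

  expect_identical(unclass(resize_image(roi, 1)), unclass(roi))

  const <- gray_image(matrix(93, 40, 50))
  for (ratio in c(0.3, 0.7, 1.6)) {
    expect_true(all(unclass(resize_image(const, ratio)) == 93))
  }
  expect_error(resize_image(roi, 0), "positive")
})

test_that("high-pass mask follows the radial profile a(1-exp(-D^2/2D0^2))+b", {
  p <- enhancement_params(S = 9, a = 12.53, b = -4, D0 = 4.5)
  mask <- build_highpass_mask(p)
  expect_equal(dim(mask), c(9, 9))
  expect_equal(mask[5, 5], -4) # center: D = 0, exp(0) = 1
  # corner: D^2 = 32, independent scalar evaluation
  expect_equal(mask[1, 1], 12.53 * (1 - exp(-32 / (2 * 4.5^2))) - 4)
  # far-distance limit of the profile approaches a + b
  far <- 12.53 * (1 - exp(-1e6)) - 4
  expect_equal(far, 12.53 - 4)

  # symmetric under horizontal, vertical and diagonal reflection
  expect_equal(mask, mask[9:1, ])
  expect_equal(mask, mask[, 9:1])
  expect_equal(mask, t(mask))

  expect_error(enhancement_params(S = 8), "odd")
  expect_error(enhancement_params(S = 9, D0 = 0), "positive")
})

test_that("enhance equals naive reflect-padded convolution, rescaled", {
  ramp <- gray_image(matrix(seq(0, 240, by = 10), 5, 5))
  mask <- matrix(c(0, -1, 0, -1, 5, -1, 0, -1, 0), 3, 3)
  ref <- naive_conv2_reflect(as.matrix(unclass(ramp)), mask)
  ref_scaled <- floor((ref - min(ref)) / (max(ref) - min(ref)) * 255 + 0.5)
  expect_equal(unclass(enhance(ramp, mask)), matrix(as.integer(ref_scaled), 5, 5),
               ignore_attr = TRUE)

  # a larger random case against the same oracle
  img <- rand_image(12, 15, seed = 77)
  mask2 <- matrix(seq(-2, 2, length.out = 25), 5, 5)
  ref2 <- naive_conv2_reflect(as.matrix(unclass(img)), mask2)
  ref2_scaled <- floor((ref2 - min(ref2)) / (max(ref2) - min(ref2)) * 255 + 0.5)
  expect_equal(unclass(enhance(img, mask2)), matrix(as.integer(ref2_scaled), 12, 15),
               ignore_attr = TRUE)
})

test_that("enhance preserves ordering under a delta mask and handles constants", {
  img <- rand_image(10, 10, seed = 3)
  delta <- matrix(0, 3, 3); delta[2, 2] <- 1
  out <- enhance(img, delta)
  expect_equal(order(unclass(out)), order(unclass(img)))

  const <- gray_image(matrix(50, 8, 8))
  out <- enhance(const, matrix(1 / 9, 3, 3))
  expect_true(all(unclass(out) == 128))

  expect_error(enhance(gray_image(matrix(1, 2, 2)), matrix(1, 5, 5)), "larger")
  # output always lands in [0, 255]
  for (s in 1:5) {
    out <- enhance(rand_image(9, 9, seed = s),
                   build_highpass_mask(enhancement_params(S = 5)))
    expect_true(min(out) >= 0 && max(out) <= 255)
  }
})

test_that("the full preprocessing chain maps a 640x480 capture to 192x64", {
  img <- generate_finger_image(finger_model(3), sample_seed = 1)
  expect_equal(dim(img), c(480L, 640L))
  enh <- preprocess_image(img)
  expect_equal(dim(enh), c(64L, 192L))
})
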