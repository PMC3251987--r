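test_that("the thresholding step is 1 exactly when the difference is >= 0", {
  expect_identical(step_bit(0), 1L)
  expect_identical(step_bit(-1), 0L)
  expect_identical(step_bit(13), 1L)
  expect_identical(step_bit(c(-0.5, 0, 2)), c(0L, 1L, 1L))
})

test_that("line codes on a constant image are all ones", {
  const <- gray_image(matrix(42, 20, 30))
  for (map in list(llbp_h(const, 5), llbp_v(const, 5), llbp(const, 5),
                   lbp(const, 8, 1))) {
    expect_true(all(map$bits))
  }
})

test_that("a strictly increasing horizontal ramp gives code 0011 for N = 5", {
  # column j has intensity 10 * j: strictly increasing left to right
  ramp <- gray_image(matrix(rep(seq(10, 100, by = 10), each = 10), 10, 10))
  map <- llbp_h(ramp, 5)
  expect_equal(map$bits_per_pixel, 4L)
  for (r in seq_len(map$valid_height)) {
    for (cc in seq_len(map$valid_width)) {
      expect_equal(as.integer(map$bits[r, cc, ]), c(0L, 0L, 1L, 1L))
    }
  }
})

test_that("code-map geometry reproduces the published template sizes", {
  g <- code_geometry(64, 192, "llbp", N = 21)
  expect_equal(unlist(g), c(valid_height = 44, valid_width = 172,
                            bits_per_pixel = 40, total_bits = 302720))
  g <- code_geometry(64, 192, "llbp_v", N = 17)
  expect_equal(g$total_bits, 135168)
  expect_equal(c(g$valid_height, g$valid_width, g$bits_per_pixel), c(48, 176, 16))
  g <- code_geometry(64, 192, "lbp", P = 8, R = 1)
  expect_equal(g$total_bits, 94240)
  expect_equal(c(g$valid_height, g$valid_width), c(62, 190))

  # the computed maps agree with the arithmetic
  img <- rand_image(64, 192, seed = 40)
  expect_equal(total_bits(llbp(img, 21)), 302720)
  expect_equal(total_bits(llbp_v(img, 17)), 135168)
  expect_equal(total_bits(lbp(img, 8, 1)), 94240)

  expect_error(code_geometry(10, 10, "llbp", N = 21), "does not fit")
})

test_that("concatenation appends vertical bits after horizontal bits", {
  # the published worked example, as raw bit strings
  h_bits <- "010111001111"
  v_bits <- "101001011101"
  h <- as.integer(strsplit(h_bits, "")[[1]]) == 1
  v <- as.integer(strsplit(v_bits, "")[[1]]) == 1
  mk <- function(bits) {
    veinline:::new_code_map(array(bits, c(1, 1, length(bits))), "llbp_h(N=13)",
                            rep(6L, 4L), veinline:::line_weights(13))
  }
  cat_map <- llbp_concat(mk(h), mk(v))
  got <- paste(as.integer(cat_map$bits[1, 1, ]), collapse = "")
  expect_identical(got, paste0(h_bits, v_bits))
  expect_equal(cat_map$bits_per_pixel, 24L)

  # per-pixel length always adds up
  img <- rand_image(30, 30, seed = 41)
  hm <- llbp_h(img, 7); vm <- llbp_v(img, 7)
  cm <- llbp_concat(hm, vm)
  expect_equal(cm$bits_per_pixel, hm$bits_per_pixel + vm$bits_per_pixel)
  expect_equal(total_bits(cm), total_bits(hm) + total_bits(vm))

  expect_error(llbp_concat(llbp_h(img, 7), llbp_v(img, 9)), "geometry mismatch")
})

test_that("magnitude combines component values euclideanly", {
  expect_equal(llbp_magnitude(3, 4), 5)
  expect_equal(llbp_magnitude(0, 0), 0)
  expect_equal(llbp_magnitude(7, 0), 7)
  expect_equal(llbp_magnitude(matrix(3, 2, 2), matrix(4, 2, 2)),
               matrix(5, 2, 2))
  expect_error(llbp_magnitude(-1, 2))
})

test_that("vectorized descriptors equal the naive per-pixel oracles", {
  for (seed in 1:6) {
    img <- rand_image(32, 32, seed = 400 + seed)
    expect_identical(llbp_h(img, 9)$bits, naive_llbp_h(img, 9))
    expect_identical(llbp_v(img, 9)$bits, naive_llbp_v(img, 9))
    expect_identical(lbp(img, 8, 1)$bits, naive_lbp(img, 8, 1))
    expect_identical(lbp(img, 8, 2)$bits, naive_lbp(img, 8, 2))
  }
})

test_that("codes are invariant to constant intensity offsets", {
  img <- rand_image(28, 28, seed = 50)
  shifted <- gray_image(pmin(unclass(img) + 30, 255))
  keep <- unclass(img) <= 225 # avoid clipping artifacts in the comparison
  if (all(keep)) {
    expect_identical(llbp(img, 7)$bits, llbp(shifted, 7)$bits)
  }
  img2 <- gray_image(matrix(sample(0:200, 28 * 28, replace = TRUE), 28, 28))
  shifted2 <- gray_image(unclass(img2) + 55)
  expect_identical(llbp(img2, 7)$bits, llbp(shifted2, 7)$bits)
  expect_identical(lbp(img2, 8, 1)$bits, lbp(shifted2, 8, 1)$bits)
})

test_that("vertical codes are the transpose dual of horizontal codes", {
  img <- rand_image(24, 36, seed = 51)
  timg <- gray_image(t(unclass(img)))
  vm <- llbp_v(img, 7)
  hm_t <- llbp_h(timg, 7)
  expect_identical(vm$bits, aperm(hm_t$bits, c(2, 1, 3)))
})

test_that("code values and grayscale rendering follow the bit weights", {
  # single-pixel map with known weighted value
  m <- veinline:::new_code_map(array(c(TRUE, FALSE, TRUE, TRUE), c(1, 1, 4)),
                               "llbp_h(N=5)", rep(2L, 4),
                               veinline:::line_weights(5))
  # weights for N=5: (2, 1 | 1, 2); bits 1,0,1,1 -> 2 + 0 + 1 + 2
  expect_equal(code_values(m)[1, 1], 5)

  # three-value map renders to {0, 128, 255} under min-max
  vals <- c(0, 50, 100)
  bits <- array(FALSE, c(1, 3, 7))
  for (i in 1:3) bits[1, i, ] <- as.integer(intToBits(vals[i]))[7:1] == 1
  m3 <- veinline:::new_code_map(bits, "llbp", rep(0L, 4), 2^(6:0))
  expect_equal(as.integer(code_to_grayscale(m3)), c(0L, 128L, 255L))

  # constant map renders mid-gray
  mc <- veinline:::new_code_map(array(TRUE, c(2, 2, 3)), "llbp", rep(0L, 4),
                                2^(2:0))
  expect_true(all(unclass(code_to_grayscale(mc)) == 128))

  # extremes map to 0 and 255
  b2 <- array(FALSE, c(1, 2, 4)); b2[1, 2, ] <- TRUE
  m2 <- veinline:::new_code_map(b2, "llbp", rep(0L, 4), 2^(3:0))
  expect_equal(as.integer(code_to_grayscale(m2)), c(0L, 255L))
})

test_that("packed template files round-trip code maps exactly", {
  img <- rand_image(40, 48, seed = 52)
  for (map in list(llbp(img, 9), llbp_h(img, 7), llbp_v(img, 11),
                   lbp(img, 8, 1))) {
    path <- withr::local_tempfile(fileext = ".vlcm")
    write_code_map(map, path)
    back <- read_code_map(path)
    expect_identical(back$bits, map$bits)
    expect_equal(back$bits_per_pixel, map$bits_per_pixel)
    expect_equal(back$margin, map$margin)
    expect_identical(back$descriptor, map$descriptor)
    expect_equal(back$weights, map$weights)
  }
})
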