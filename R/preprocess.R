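#' Otsu threshold of an 8-bit image
#'
#' Exhaustively maximizes the between-class variance over the 256-bin
#' intensity histogram. The returned level `L` splits pixels into a
#' background class `< L` and a foreground class `>= L`, matching
#' [binarize()].
#'
#' @param image A [gray_image()].
#' @return Integer threshold level in `1..255`.
#' @export
otsu_threshold <- function(image) {
  m <- as_pixel_matrix(image)
  counts <- tabulate(as.integer(m) + 1L, nbins = 256L)
  if (sum(counts > 0L) < 2L) {
    stop("degenerate histogram: image has fewer than 2 distinct intensities",
         call. = FALSE)
  }
  n <- sum(counts)
  p <- counts / n
  levels <- 0:255
  # class 0: intensities < L; class 1: intensities >= L, for L = 1..255
  w0 <- cumsum(p)[1:255]              # weight of class {0..L-1}
  mu0 <- cumsum(p * levels)[1:255]    # unnormalized class-0 mean
  mu_t <- sum(p * levels)
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, 255)
  sigma_b[valid] <- (mu_t * w0[valid] - mu0[valid])^2 / (w0[valid] * w1[valid])
  which.max(sigma_b) # level L in 1..255
}

#' Binarize an image at a threshold level
#'
#' @param image A [gray_image()].
#' @param level Threshold in `[0, 255]`; pixels with intensity `>= level`
#'   become foreground (`TRUE`) — the brighter finger region.
#' @return Logical matrix of the same dimensions.
#' @export
binarize <- function(image, level) {
  stopifnot(length(level) == 1L, level >= 0, level <= 255)
  as_pixel_matrix(image) >= level
}

#' Centroid of a binary object
#'
#' Mean position of the `TRUE` pixels, rounded half-up to an integer
#' pixel location.
#'
#' @param mask Logical matrix (foreground mask).
#' @return Integer vector `c(row, col)` (1-based).
#' @export
object_centroid <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    stop("empty mask: no foreground object to locate", call. = FALSE)
  }
  c(row = as.integer(round_half_up(mean(idx[, 1]))),
    col = as.integer(round_half_up(mean(idx[, 2]))))
}

#' Crop a fixed-size region of interest around a center
#'
#' Extracts a `roi_height` x `roi_width` window centered on `center`.
#' When the centered window would extend past the image border it is
#' shifted (clamped) to lie fully inside, so every ROI pixel is real data.
#'
#' @param image A [gray_image()] at least as large as the ROI.
#' @param center Integer `c(row, col)` (1-based), typically from
#'   [object_centroid()].
#' @param roi_height,roi_width ROI dimensions in pixels (default
#'   160 x 480, the standard finger window).
#' @return A `gray_image` of size `roi_height` x `roi_width`.
#' @export
crop_roi <- function(image, center, roi_height = 160L, roi_width = 480L) {
  m <- unclass(image)
  if (nrow(m) < roi_height || ncol(m) < roi_width) {
    stop(sprintf("image (%d x %d) smaller than ROI (%d x %d)",
                 nrow(m), ncol(m), roi_height, roi_width), call. = FALSE)
  }
  r0 <- center[[1]] - floor(roi_height / 2)
  c0 <- center[[2]] - floor(roi_width / 2)
  r0 <- min(max(r0, 1L), nrow(m) - roi_height + 1L)
  c0 <- min(max(c0, 1L), ncol(m) - roi_width + 1L)
  gray_image(m[r0:(r0 + roi_height - 1L), c0:(c0 + roi_width - 1L), drop = FALSE])
}

#' Resize an image by a scale ratio
#'
#' Bilinear interpolation; output dimensions are `round(dim * ratio)` and
#' intensities are re-quantized to 8 bits.
#'
#' @param image A [gray_image()].
#' @param ratio Positive scale factor (default 0.4, which maps the
#'   480 x 160 finger ROI to 192 x 64).
#' @return A `gray_image`.
#' @export
resize_image <- function(image, ratio = 0.4) {
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0) {
    stop("`ratio` must be a positive scalar", call. = FALSE)
  }
  m <- as_pixel_matrix(image)
  out_h <- as.integer(round_half_up(nrow(m) * ratio))
  out_w <- as.integer(round_half_up(ncol(m) * ratio))
  if (out_h < 1L || out_w < 1L) {
    stop("ratio too small: output would have zero size", call. = FALSE)
  }
  if (out_h == nrow(m) && out_w == ncol(m)) {
    return(gray_image(m))
  }
  res <- EBImage::resize(EBImage::Image(m / 255), w = out_h, h = out_w,
                         filter = "bilinear")
  gray_image(pmin(pmax(EBImage::imageData(res), 0), 1) * 255)
}

#' Enhancement parameters for the modified Gaussian high-pass filter
#'
#' @param S Mask side length in pixels; odd, `>= 3`.
#' @param a Amplitude adjustment (dimensionless).
#' @param b DC-level adjustment (dimensionless).
#' @param D0 Gaussian width scalar in pixels; defaults to `S / 2`, tying
#'   the filter's spatial scale to the mask extent.
#' @return A validated list of class `enhancement_params`.
#' @export
enhancement_params <- function(S = 15L, a = 12.53, b = -4, D0 = S / 2) {
  S <- as.integer(S)
  if (S < 3L || S %% 2L == 0L) {
    stop("`S` must be an odd integer >= 3", call. = FALSE)
  }
  if (!is.numeric(D0) || D0 <= 0) {
    stop("`D0` must be positive", call. = FALSE)
  }
  structure(list(S = S, a = a, b = b, D0 = D0), class = "enhancement_params")
}

#' Build the modified Gaussian high-pass filter mask
#'
#' The S x S mask has weights
#' `H(x, y) = a * (1 - exp(-D(x, y)^2 / (2 * D0^2))) + b`,
#' where `D(x, y)` is the Euclidean distance from the mask center. The
#' center weight is `b`; weights approach `a + b` far from the center, so
#' with `b < 0` the mask acts as a high-pass (center-suppressing) filter.
#'
#' @param params An [enhancement_params()] object.
#' @return Numeric S x S matrix of filter weights.
#' @export
build_highpass_mask <- function(params) {
  stopifnot(inherits(params, "enhancement_params"))
  S <- params$S
  ctr <- (S + 1L) / 2L
  d <- (seq_len(S) - ctr)
  D2 <- outer(d^2, d^2, `+`)
  params$a * (1 - exp(-D2 / (2 * params$D0^2))) + params$b
}

# reflect-pad a matrix by (pr, pc) on each side (no edge duplication,
# i.e. "symmetric about the edge pixel" excluded: mirror without repeat)
pad_reflect <- function(m, pr, pc) {
  nr <- nrow(m); nc <- ncol(m)
  if (pr >= nr || pc >= nc) {
    stop("padding exceeds image size", call. = FALSE)
  }
  ri <- c(rev(seq_len(pr) + 1L), seq_len(nr), nr - seq_len(pr))
  ci <- c(rev(seq_len(pc) + 1L), seq_len(nc), nc - seq_len(pc))
  m[ri, ci, drop = FALSE]
}

#' Enhance an image by convolution with a filter mask
#'
#' 2-D convolution with reflected-border padding followed by a linear
#' min-max rescale to `[0, 255]`. A constant convolution result maps to
#' mid-gray 128 by convention.
#'
#' @param image A [gray_image()] larger than the mask.
#' @param mask Square odd-sided weight matrix, e.g. from
#'   [build_highpass_mask()].
#' @return A `gray_image` of the same dimensions.
#' @export
enhance <- function(image, mask) {
  stopifnot(is.matrix(mask), nrow(mask) == ncol(mask), nrow(mask) %% 2L == 1L)
  m <- as_pixel_matrix(image)
  S <- nrow(mask)
  if (S > nrow(m) || S > ncol(m)) {
    stop("mask larger than image", call. = FALSE)
  }
  half <- (S - 1L) / 2L
  pm <- pad_reflect(m, half, half)
  out <- matrix(0, nrow(m), ncol(m))
  # true convolution: kernel is flipped relative to cross-correlation
  for (u in seq_len(S)) {
    for (v in seq_len(S)) {
      w <- mask[S - u + 1L, S - v + 1L]
      if (w != 0) {
        out <- out + w * pm[u:(u + nrow(m) - 1L), v:(v + ncol(m) - 1L)]
      }
    }
  }
  rescale_to_8bit(out)
}

rescale_to_8bit <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2]) {
    return(gray_image(matrix(128, nrow(x), ncol(x))))
  }
  gray_image((x - rng[1]) / (rng[2] - rng[1]) * 255)
}

#' Run the full preprocessing chain
#'
#' Otsu binarization, finger centroid, 480 x 160 ROI crop, downscale by
#' the resize ratio, then high-pass enhancement. A raw 640 x 480 capture
#' becomes a 192 x 64 enhanced image under the defaults.
#'
#' @param image A raw [gray_image()] capture.
#' @param config Pipeline configuration from [default_config()] /
#'   [load_config()].
#' @return The enhanced `gray_image`.
#' @export
preprocess_image <- function(image, config = default_config()) {
  config <- validate_config(config)
  level <- otsu_threshold(image)
  mask <- binarize(image, level)
  ctr <- object_centroid(mask)
  roi <- crop_roi(image, ctr,
                  roi_height = config[["roi.height"]],
                  roi_width = config[["roi.width"]])
  small <- resize_image(roi, config[["resize.ratio"]])
  ep <- enhancement_params(S = config[["enhance.S"]], a = config[["enhance.a"]],
                           b = config[["enhance.b"]],
                           D0 = config[["enhance.D0"]] %||% config[["enhance.S"]] / 2)
  enhance(small, build_highpass_mask(ep))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
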