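#' Thresholding step function
#'
#' The sign comparison underlying every binary code in the package:
#' `step_bit(x)` is 1 when `x >= 0` and 0 otherwise, applied to the
#' difference neighbor - center.
#'
#' @param x Numeric vector of signed differences.
#' @return Integer vector of 0/1 bits.
#' @export
step_bit <- function(x) as.integer(x >= 0)

new_code_map <- function(bits, descriptor, margin, weights) {
  stopifnot(is.array(bits), length(dim(bits)) == 3L, is.logical(bits))
  structure(
    list(
      bits = bits,
      bits_per_pixel = dim(bits)[3],
      valid_height = dim(bits)[1],
      valid_width = dim(bits)[2],
      margin = margin, # c(top, bottom, left, right)
      descriptor = descriptor,
      weights = weights
    ),
    class = "code_map"
  )
}

#' @export
print.code_map <- function(x, ...) {
  cat(sprintf(
    "<code_map> %s: %d x %d valid pixels x %d bits = %s bits\n",
    x$descriptor, x$valid_height, x$valid_width, x$bits_per_pixel,
    format(total_bits(x), big.mark = ",")
  ))
  invisible(x)
}

#' Total number of bits in a code map
#'
#' `valid_height * valid_width * bits_per_pixel`.
#'
#' @param map A `code_map`.
#' @return Integer bit count.
#' @export
total_bits <- function(map) {
  stopifnot(inherits(map, "code_map"))
  map$valid_height * map$valid_width * map$bits_per_pixel
}

#' Per-pixel decimal values of a code map
#'
#' Interprets each pixel's bit pattern with the descriptor's bit weights
#' (for the line descriptors these are the weights of the defining binary
#' expansion, with the most significant bit at the line's outer ends).
#' Used for the magnitude descriptor and grayscale visualization, not for
#' matching.
#'
#' @param map A `code_map`.
#' @return Numeric matrix `valid_height` x `valid_width`.
#' @export
code_values <- function(map) {
  stopifnot(inherits(map, "code_map"))
  d <- dim(map$bits)
  vals <- matrix(as.double(map$bits), d[1] * d[2], d[3]) %*% map$weights
  matrix(vals, d[1], d[2])
}

line_offsets <- function(N) {
  m <- (N - 1L) %/% 2L
  c(-(m:1), 1:m) # pixel order along the line, center excluded
}

# Weights of the defining binary expansion: on each side of the center
# the most significant bit is the pixel farthest from the center.
line_weights <- function(N) {
  m <- (N - 1L) %/% 2L
  c(2^((m - 1L):0), 2^(0:(m - 1L)))
}

check_line_params <- function(N) {
  N <- as.integer(N)
  if (N < 3L || N %% 2L == 0L) {
    stop("line length `N` must be an odd integer >= 3", call. = FALSE)
  }
  N
}

#' Horizontal local line binary pattern
#'
#' For each pixel, compares the `N - 1` other pixels on the horizontal
#' line of length `N` centered there against the center pixel
#' (neighbor `>=` center gives bit 1), storing bits in pixel order from
#' left to right. A margin of `(N - 1) / 2` pixels is trimmed on all four
#' sides so the horizontal and vertical maps stay co-registered.
#'
#' @param image A [gray_image()].
#' @param N Odd line length in pixels (default 21, the tuned value for
#'   the concatenated descriptor).
#' @return A `code_map` with `N - 1` bits per pixel.
#' @export
llbp_h <- function(image, N = 21L) {
  N <- check_line_params(N)
  m <- as_pixel_matrix(image)
  if (ncol(m) < N) stop("image narrower than the line length", call. = FALSE)
  if (nrow(m) < N) stop("image shorter than the line length", call. = FALSE)
  mg <- (N - 1L) %/% 2L
  rows <- (mg + 1L):(nrow(m) - mg)
  cols <- (mg + 1L):(ncol(m) - mg)
  ctr <- m[rows, cols, drop = FALSE]
  offs <- line_offsets(N)
  bits <- array(FALSE, c(length(rows), length(cols), N - 1L))
  for (k in seq_along(offs)) {
    bits[, , k] <- m[rows, cols + offs[k], drop = FALSE] >= ctr
  }
  new_code_map(bits, descriptor = sprintf("llbp_h(N=%d)", N),
               margin = rep(mg, 4L), weights = line_weights(N))
}

#' Vertical local line binary pattern
#'
#' As [llbp_h()] on the vertical line (bits in pixel order top to
#' bottom); equals the transpose of the horizontal operator applied to
#' the transposed image.
#'
#' @inheritParams llbp_h
#' @param N Odd line length in pixels (default 17, the tuned value for
#'   the vertical-only descriptor).
#' @return A `code_map` with `N - 1` bits per pixel.
#' @export
llbp_v <- function(image, N = 17L) {
  N <- check_line_params(N)
  m <- as_pixel_matrix(image)
  if (nrow(m) < N) stop("image shorter than the line length", call. = FALSE)
  if (ncol(m) < N) stop("image narrower than the line length", call. = FALSE)
  mg <- (N - 1L) %/% 2L
  rows <- (mg + 1L):(nrow(m) - mg)
  cols <- (mg + 1L):(ncol(m) - mg)
  ctr <- m[rows, cols, drop = FALSE]
  offs <- line_offsets(N)
  bits <- array(FALSE, c(length(rows), length(cols), N - 1L))
  for (k in seq_along(offs)) {
    bits[, , k] <- m[rows + offs[k], cols, drop = FALSE] >= ctr
  }
  new_code_map(bits, descriptor = sprintf("llbp_v(N=%d)", N),
               margin = rep(mg, 4L), weights = line_weights(N))
}

#' Concatenated local line binary pattern
#'
#' Joins the horizontal and vertical codes pixel-wise, horizontal bits
#' first, giving `2 * (N - 1)` bits per pixel.
#'
#' @param h_map,v_map `code_map`s from [llbp_h()] and [llbp_v()]
#'   computed on the same image with the same `N`.
#' @return A `code_map`.
#' @export
llbp_concat <- function(h_map, v_map) {
  stopifnot(inherits(h_map, "code_map"), inherits(v_map, "code_map"))
  if (h_map$valid_height != v_map$valid_height ||
      h_map$valid_width != v_map$valid_width ||
      h_map$bits_per_pixel != v_map$bits_per_pixel ||
      !all(h_map$margin == v_map$margin)) {
    stop("geometry mismatch: horizontal and vertical maps must come from ",
         "the same image and line length", call. = FALSE)
  }
  bpp <- h_map$bits_per_pixel + v_map$bits_per_pixel
  bits <- array(FALSE, c(h_map$valid_height, h_map$valid_width, bpp))
  bits[, , seq_len(h_map$bits_per_pixel)] <- h_map$bits
  bits[, , h_map$bits_per_pixel + seq_len(v_map$bits_per_pixel)] <- v_map$bits
  # decimal interpretation (visualization only): plain MSB-first value of
  # the concatenated bit string
  new_code_map(bits, descriptor = sub("_h", "", h_map$descriptor),
               margin = h_map$margin, weights = 2^((bpp - 1L):0))
}

#' Local line binary pattern applied end to end
#'
#' Convenience wrapper computing [llbp_h()] and [llbp_v()] with the same
#' `N` and concatenating them.
#'
#' @inheritParams llbp_h
#' @return A `code_map` with `2 * (N - 1)` bits per pixel.
#' @export
llbp <- function(image, N = 21L) {
  llbp_concat(llbp_h(image, N), llbp_v(image, N))
}

#' Magnitude of the line binary pattern components
#'
#' Euclidean combination `sqrt(h^2 + v^2)` of the decimal values of the
#' horizontal and vertical codes; used for visualization, not matching.
#'
#' @param h_value,v_value Non-negative numeric scalars, vectors or
#'   matrices (decimal code values, e.g. from [code_values()]).
#' @return Numeric of the common shape.
#' @export
llbp_magnitude <- function(h_value, v_value) {
  stopifnot(all(h_value >= 0), all(v_value >= 0))
  sqrt(h_value^2 + v_value^2)
}

#' Circular local binary pattern
#'
#' Classic LBP(P, R): each pixel is compared against `P` neighbors
#' sampled on a circle of radius `R`, the first neighbor at angle 0
#' (to the right) and subsequent ones counter-clockwise. Samples at
#' non-integer positions are bilinearly interpolated. A margin of
#' `ceiling(R)` pixels is trimmed on all sides.
#'
#' @param image A [gray_image()].
#' @param P Number of sampling points (default 8).
#' @param R Circle radius in pixels (default 1).
#' @return A `code_map` with `P` bits per pixel.
#' @export
lbp <- function(image, P = 8L, R = 1) {
  stopifnot(P >= 1L, R > 0)
  m <- as_pixel_matrix(image)
  mg <- as.integer(ceiling(R))
  if (nrow(m) <= 2L * mg || ncol(m) <= 2L * mg) {
    stop("image too small for the sampling radius", call. = FALSE)
  }
  rows <- (mg + 1L):(nrow(m) - mg)
  cols <- (mg + 1L):(ncol(m) - mg)
  ctr <- m[rows, cols, drop = FALSE]
  bits <- array(FALSE, c(length(rows), length(cols), P))
  for (p in seq_len(P) - 1L) {
    theta <- 2 * pi * p / P
    # counter-clockwise in image coordinates (row axis points down)
    dc <- R * cos(theta)
    dr <- -R * sin(theta)
    bits[, , p + 1L] <- sample_shifted(m, rows, cols, dr, dc) >= ctr
  }
  new_code_map(bits, descriptor = sprintf("lbp(P=%d,R=%g)", P, R),
               margin = rep(mg, 4L), weights = 2^(0:(P - 1L)))
}

# bilinearly sample m at (rows + dr, cols + dc); exact pixels when the
# offsets are (numerically) integral
sample_shifted <- function(m, rows, cols, dr, dc) {
  snap <- function(x) if (abs(x - round(x)) < 1e-8) round(x) else x
  dr <- snap(dr); dc <- snap(dc)
  if (dr == round(dr) && dc == round(dc)) {
    return(m[rows + as.integer(dr), cols + as.integer(dc), drop = FALSE])
  }
  r0 <- floor(dr); c0 <- floor(dc)
  fr <- dr - r0; fc <- dc - c0
  m00 <- m[rows + r0, cols + c0, drop = FALSE]
  m01 <- m[rows + r0, cols + c0 + 1L, drop = FALSE]
  m10 <- m[rows + r0 + 1L, cols + c0, drop = FALSE]
  m11 <- m[rows + r0 + 1L, cols + c0 + 1L, drop = FALSE]
  (1 - fr) * ((1 - fc) * m00 + fc * m01) + fr * ((1 - fc) * m10 + fc * m11)
}

#' Code-map geometry for a descriptor on a given image size
#'
#' Pure arithmetic of the valid region and template size: margins trimmed
#' by the descriptor, bits per pixel, and the total template length in
#' bits.
#'
#' @param height,width Enhanced-image dimensions in pixels.
#' @param descriptor One of `"llbp"`, `"llbp_h"`, `"llbp_v"`, `"lbp"`.
#' @param N Line length for the line descriptors.
#' @param P,R LBP sampling points and radius.
#' @return A tibble with columns `valid_height`, `valid_width`,
#'   `bits_per_pixel`, `total_bits`.
#' @examples
#' code_geometry(64, 192, "llbp", N = 21) # the 302,720-bit template
#' @export
code_geometry <- function(height, width,
                          descriptor = c("llbp", "llbp_h", "llbp_v", "lbp"),
                          N = 21L, P = 8L, R = 1) {
  descriptor <- match.arg(descriptor)
  if (descriptor == "lbp") {
    mg <- as.integer(ceiling(R))
    bpp <- as.integer(P)
  } else {
    N <- check_line_params(N)
    mg <- (N - 1L) %/% 2L
    bpp <- if (descriptor == "llbp") 2L * (N - 1L) else N - 1L
  }
  vh <- height - 2L * mg
  vw <- width - 2L * mg
  if (vh < 1L || vw < 1L) {
    stop("descriptor does not fit in the image", call. = FALSE)
  }
  tibble::tibble(valid_height = vh, valid_width = vw,
                 bits_per_pixel = bpp, total_bits = vh * vw * bpp)
}

#' Render a code map as a grayscale image
#'
#' Converts each pixel's code to its decimal value and linearly min-max
#' normalizes to `[0, 255]` (a constant map renders as mid-gray 128),
#' giving the conventional visualization of binary texture codes.
#'
#' @param map A `code_map`.
#' @return A `gray_image` of size `valid_height` x `valid_width`.
#' @export
code_to_grayscale <- function(map) {
  rescale_to_8bit(code_values(map))
}

#' Extract the descriptor configured for the pipeline
#'
#' Dispatches on `descriptor.kind` (`llbp`, `llbp_h`, `llbp_v` or `lbp`)
#' with the configured `N` or `(P, R)`.
#'
#' @param image An enhanced [gray_image()].
#' @param config Pipeline configuration.
#' @return A `code_map`.
#' @export
extract_code <- function(image, config = default_config()) {
  switch(config[["descriptor.kind"]],
    llbp = llbp(image, config[["descriptor.N"]]),
    llbp_h = llbp_h(image, config[["descriptor.N"]]),
    llbp_v = llbp_v(image, config[["descriptor.N"]]),
    lbp = lbp(image, config[["descriptor.P"]], config[["descriptor.R"]]),
    stop(sprintf("unknown descriptor kind '%s'", config[["descriptor.kind"]]),
         call. = FALSE)
  )
}

#' Serialize a code map to a packed binary template file
#'
#' Fixed layout: the ASCII magic `VLCM`, a version byte, then six
#' little-endian int32 fields (valid_height, valid_width, bits_per_pixel,
#' margin top/bottom as one pair of int32, margin left/right), a
#' length-prefixed descriptor tag, and the bits packed 8 per byte in
#' pixel-major order (row, then column, then bit).
#'
#' @param map A `code_map`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_code_map <- function(map, path) {
  stopifnot(inherits(map, "code_map"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("VLCM", con, eos = NULL)
  writeBin(1L, con, size = 1L)
  writeBin(as.integer(c(map$valid_height, map$valid_width,
                        map$bits_per_pixel, map$margin)), con,
           size = 4L, endian = "little")
  tag <- charToRaw(map$descriptor)
  writeBin(length(tag), con, size = 4L, endian = "little")
  writeBin(tag, con)
  # pixel-major bit order: all bits of pixel (1,1), then (1,2), ...
  bit_stream <- aperm(map$bits, c(3L, 2L, 1L))
  writeBin(packBits(as.logical(c(bit_stream,
                                 rep(FALSE, (-length(bit_stream)) %% 8))),
                    type = "raw"), con)
  invisible(path)
}

#' Read a packed code-map template written by [write_code_map()]
#'
#' @param path Template file path.
#' @return A `code_map`. The bit weights are restored from the descriptor
#'   tag.
#' @export
read_code_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(magic, "VLCM")) stop("not a code-map template file", call. = FALSE)
  ver <- readBin(con, "integer", size = 1L)
  if (ver != 1L) stop(sprintf("unsupported template version %d", ver), call. = FALSE)
  hdr <- readBin(con, "integer", n = 7L, size = 4L, endian = "little")
  taglen <- readBin(con, "integer", size = 4L, endian = "little")
  tag <- rawToChar(readBin(con, "raw", n = taglen))
  n_bits <- hdr[1] * hdr[2] * hdr[3]
  packed <- readBin(con, "raw", n = ceiling(n_bits / 8))
  bits_flat <- as.logical(rawToBits(packed))[seq_len(n_bits)]
  bits <- aperm(array(bits_flat, c(hdr[3], hdr[2], hdr[1])), c(3L, 2L, 1L))
  weights <- descriptor_weights(tag, hdr[3])
  new_code_map(bits, descriptor = tag, margin = hdr[4:7], weights = weights)
}

descriptor_weights <- function(tag, bpp) {
  if (grepl("^llbp_[hv]", tag)) {
    line_weights(bpp + 1L)
  } else if (grepl("^llbp", tag)) {
    2^((bpp - 1L):0)
  } else {
    2^(0:(bpp - 1L))
  }
}
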