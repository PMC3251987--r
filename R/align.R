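#' Phase-only correlation surface of two images
#'
#' Computes the real part of the inverse 2-D Fourier transform of the
#' normalized cross-phase spectrum `F * Conj(G) / |F * Conj(G)|`. For two
#' copies of the same non-constant image the surface is a unit delta at
#' zero shift; for a circularly shifted copy the (near-)unit peak moves to
#' the bin encoding the shift.
#'
#' @param f,g [gray_image()]s (or matrices) of identical dimensions.
#' @param window Optional pre-FFT window: `"none"` (default) or `"hann"`.
#' @return Numeric matrix of the same dimensions; entry `[1, 1]`
#'   corresponds to zero shift, wrap-around rules apply elsewhere.
#' @export
poc_surface <- function(f, g, window = c("none", "hann")) {
  window <- match.arg(window)
  fm <- as_pixel_matrix(f)
  gm <- as_pixel_matrix(g)
  if (!all(dim(fm) == dim(gm))) {
    stop(sprintf("dimension mismatch: %d x %d vs %d x %d",
                 nrow(fm), ncol(fm), nrow(gm), ncol(gm)), call. = FALSE)
  }
  if (window == "hann") {
    wr <- hann_window(nrow(fm))
    wc <- hann_window(ncol(fm))
    w2 <- outer(wr, wc)
    fm <- fm * w2
    gm <- gm * w2
  }
  Ff <- stats::fft(fm)
  Fg <- stats::fft(gm)
  R <- Ff * Conj(Fg)
  mag <- Mod(R)
  # terms with vanishing magnitude carry no phase information; treat them
  # as unit magnitude instead of amplifying numerical noise
  floor_mag <- .Machine$double.eps * max(mag, 1)
  mag[mag < floor_mag] <- 1
  Re(stats::fft(R / mag, inverse = TRUE)) / length(fm)
}

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
}

#' Estimate the integer translation between two images
#'
#' Locates the peak of the [poc_surface()] and unwraps it to signed
#' shifts. The estimate `(t_x, t_y)` is the displacement of `g` relative
#' to `f`: positive `t_x` means the content of `g` sits `t_x` pixels to
#' the right of (and `t_y` below, for `t_y`) the content of `f`.
#'
#' @inheritParams poc_surface
#' @return A list of class `translation_estimate` with fields `t_x`,
#'   `t_y` (signed integers) and `peak` (POC peak height, `<= 1` up to
#'   numerical noise).
#' @export
estimate_translation <- function(f, g, window = c("none", "hann")) {
  surf <- poc_surface(f, g, window = window)
  idx <- which.max(surf)
  pk <- surf[idx]
  r <- (idx - 1L) %% nrow(surf)
  cc <- (idx - 1L) %/% nrow(surf)
  # the F * Conj(G) peak sits at minus the shift of g relative to f
  t_y <- unwrap_shift(-r, nrow(surf))
  t_x <- unwrap_shift(-cc, ncol(surf))
  structure(list(t_x = t_x, t_y = t_y, peak = pk),
            class = "translation_estimate")
}

# map a shift known modulo n into (-n/2, n/2]
unwrap_shift <- function(s, n) {
  s <- ((s %% n) + n) %% n
  if (s > n / 2) s <- s - n
  as.integer(s)
}

#' @export
print.translation_estimate <- function(x, ...) {
  cat(sprintf("<translation_estimate> t_x = %d, t_y = %d, peak = %.4f\n",
              x$t_x, x$t_y, x$peak))
  invisible(x)
}

#' Alignment acceptance limits
#'
#' Pairs whose estimated translation reaches `max_tx` horizontally or
#' `max_ty` vertically are not aligned at all: such gross misalignment is
#' taken as evidence the two images show different fingers.
#'
#' @param max_tx,max_ty Strict upper bounds on `|t_x|` and `|t_y|` in
#'   pixels (defaults 20 and 10).
#' @return A list of class `alignment_limits`.
#' @export
alignment_limits <- function(max_tx = 20L, max_ty = 10L) {
  stopifnot(max_tx > 0, max_ty > 0)
  structure(list(max_tx = as.integer(max_tx), max_ty = as.integer(max_ty)),
            class = "alignment_limits")
}

#' Extract the common region of two images under a translation
#'
#' When `|t_x| < max_tx` and `|t_y| < max_ty`, returns the two
#' overlapping windows, each of size `(H - |t_y|) x (W - |t_x|)`;
#' otherwise returns a rejection marker (the pair is scored as different
#' fingers downstream).
#'
#' @param f,g [gray_image()]s of identical dimensions.
#' @param t A `translation_estimate` from [estimate_translation()].
#' @param limits An [alignment_limits()] object.
#' @return A list with elements `rejected` (logical), and when not
#'   rejected `f_c` and `g_c`, the aligned `gray_image` windows.
#' @export
common_region <- function(f, g, t, limits = alignment_limits()) {
  fm <- unclass(f)
  gm <- unclass(g)
  if (!all(dim(fm) == dim(gm))) {
    stop("dimension mismatch between images", call. = FALSE)
  }
  tx <- t$t_x
  ty <- t$t_y
  if (abs(tx) >= limits$max_tx || abs(ty) >= limits$max_ty) {
    return(list(rejected = TRUE, translation = t))
  }
  H <- nrow(fm); W <- ncol(fm)
  # g's content is f's shifted by (+tx, +ty): overlap of the two frames
  if (ty >= 0) { fr <- 1:(H - ty); gr <- (ty + 1):H } else { fr <- (1 - ty):H; gr <- 1:(H + ty) }
  if (tx >= 0) { fc <- 1:(W - tx); gc <- (tx + 1):W } else { fc <- (1 - tx):W; gc <- 1:(W + tx) }
  list(rejected = FALSE,
       f_c = gray_image(fm[fr, fc, drop = FALSE]),
       g_c = gray_image(gm[gr, gc, drop = FALSE]),
       translation = t)
}
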