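# Independent naive-oracle implementations used to cross-check the
# vectorized pipeline code. These deliberately use per-pixel loops and
# their own arithmetic.

rand_image <- function(h, w, seed) {
  set.seed(seed)
  gray_image(matrix(sample(0:255, h * w, replace = TRUE), h, w))
}

circshift <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  m[((seq_len(nr) - 1 - dy) %% nr) + 1, ((seq_len(nc) - 1 - dx) %% nc) + 1]
}

# brute-force Otsu: try all 255 split levels, maximize between-class variance
brute_otsu <- function(image) {
  px <- as.integer(unclass(image))
  best <- -Inf; best_l <- NA_integer_
  for (L in 1:255) {
    lo <- px[px < L]; hi <- px[px >= L]
    if (length(lo) == 0L || length(hi) == 0L) next
    w0 <- length(lo) / length(px); w1 <- 1 - w0
    v <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (v > best) { best <- v; best_l <- L }
  }
  best_l
}

# nested-loop 2-D convolution with reflect padding (no edge duplication)
naive_conv2_reflect <- function(m, mask) {
  S <- nrow(mask); half <- (S - 1) / 2
  reflect_idx <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 2 - i
      if (i > n) i <- 2 * n - i
    }
    i
  }
  out <- matrix(0, nrow(m), ncol(m))
  for (r in seq_len(nrow(m))) {
    for (cc in seq_len(ncol(m))) {
      acc <- 0
      for (u in -half:half) {
        for (v in -half:half) {
          # convolution: kernel indexed opposite to the image offset
          w <- mask[half + 1 - u, half + 1 - v]
          acc <- acc + w * m[reflect_idx(r + u, nrow(m)),
                             reflect_idx(cc + v, ncol(m))]
        }
      }
      out[r, cc] <- acc
    }
  }
  out
}

# per-pixel horizontal line code, bits left to right excluding the center
naive_llbp_h <- function(image, N) {
  m <- unclass(image); mg <- (N - 1) / 2
  vh <- nrow(m) - 2 * mg; vw <- ncol(m) - 2 * mg
  bits <- array(FALSE, c(vh, vw, N - 1))
  for (r in seq_len(vh)) {
    for (cc in seq_len(vw)) {
      r0 <- r + mg; c0 <- cc + mg
      k <- 0
      for (d in c(-(mg:1), 1:mg)) {
        k <- k + 1
        bits[r, cc, k] <- m[r0, c0 + d] >= m[r0, c0]
      }
    }
  }
  bits
}

naive_llbp_v <- function(image, N) {
  m <- unclass(image); mg <- (N - 1) / 2
  vh <- nrow(m) - 2 * mg; vw <- ncol(m) - 2 * mg
  bits <- array(FALSE, c(vh, vw, N - 1))
  for (r in seq_len(vh)) {
    for (cc in seq_len(vw)) {
      r0 <- r + mg; c0 <- cc + mg
      k <- 0
      for (d in c(-(mg:1), 1:mg)) {
        k <- k + 1
        bits[r, cc, k] <- m[r0 + d, c0] >= m[r0, c0]
      }
    }
  }
  bits
}

# per-pixel circular LBP with its own bilinear sampler
naive_lbp <- function(image, P, R) {
  m <- unclass(image); mg <- ceiling(R)
  vh <- nrow(m) - 2 * mg; vw <- ncol(m) - 2 * mg
  bilin <- function(rr, cc) {
    if (abs(rr - round(rr)) < 1e-8) rr <- round(rr)
    if (abs(cc - round(cc)) < 1e-8) cc <- round(cc)
    r0 <- floor(rr); c0 <- floor(cc)
    fr <- rr - r0; fc <- cc - c0
    if (fr == 0 && fc == 0) return(m[r0, c0])
    (1 - fr) * (1 - fc) * m[r0, c0] +
      (1 - fr) * fc * m[r0, c0 + 1] +
      fr * (1 - fc) * m[r0 + 1, c0] +
      fr * fc * m[r0 + 1, c0 + 1]
  }
  bits <- array(FALSE, c(vh, vw, P))
  for (r in seq_len(vh)) {
    for (cc in seq_len(vw)) {
      r0 <- r + mg; c0 <- cc + mg
      for (p in 0:(P - 1)) {
        th <- 2 * pi * p / P
        smp <- bilin(r0 - R * sin(th), c0 + R * cos(th))
        bits[r, cc, p + 1] <- smp >= m[r0, c0]
      }
    }
  }
  bits
}

# tiny synthetic dataset shared across evaluation tests
make_tiny_dataset <- function(dir, n_subjects = 2, fingers = 2, samples = 3,
                              seed = 101) {
  generate_dataset(n_subjects, fingers, samples, root_seed = seed,
                   out_dir = dir)
}
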