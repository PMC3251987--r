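#' Capture parameters of the synthetic generator
#'
#' Controls how individual samples of a finger vary between captures,
#' mimicking re-placement of a real finger on the device: integer
#' translation jitter, a global brightness offset, optical blur, and
#' sensor noise. Defaults keep the jitter well inside the alignment
#' limits after the 0.4 downscale (a capture-scale shift of `d` pixels
#' becomes roughly `0.4 * d` at the enhanced scale).
#'
#' @param jitter_tx,jitter_ty Maximum absolute per-sample translation in
#'   pixels at capture scale (defaults 10 and 5).
#' @param brightness_sd Standard deviation of the per-sample global
#'   intensity offset, in 8-bit intensity units (default 5).
#' @param noise_sd Standard deviation of additive per-pixel Gaussian
#'   noise, intensity units (default 6).
#' @param blur_sigma Gaussian blur applied to the rendered scene, in
#'   pixels (default 2), emulating optical blur and skin scattering.
#' @return A list of class `capture_params`.
#' @export
capture_params <- function(jitter_tx = 10L, jitter_ty = 5L,
                           brightness_sd = 5, noise_sd = 6, blur_sigma = 2) {
  stopifnot(jitter_tx >= 0, jitter_ty >= 0, brightness_sd >= 0,
            noise_sd >= 0, blur_sigma >= 0)
  structure(list(jitter_tx = as.integer(jitter_tx),
                 jitter_ty = as.integer(jitter_ty),
                 brightness_sd = brightness_sd, noise_sd = noise_sd,
                 blur_sigma = blur_sigma),
            class = "capture_params")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Generate the stable anatomy of one synthetic finger
#'
#' A finger is modelled as a bright horizontal band (rounded, elliptical
#' profile) on a dark background, carrying 3-6 dark curvilinear veins.
#' Each vein is a smooth spline running lengthwise with random waviness
#' and a random width of 3-8 pixels. The model is a pure function of
#' `finger_seed`: the same seed always yields the same anatomy.
#'
#' @param finger_seed Integer seed identifying the finger.
#' @param width,height Capture dimensions in pixels (default 640 x 480).
#' @return A list of class `finger_model` with the finger-band geometry
#'   and per-vein spline control points and widths.
#' @export
finger_model <- function(finger_seed, width = 640L, height = 480L) {
  with_seed(finger_seed, {
    band_center <- height / 2 + runif(1, -20, 20)
    band_halfheight <- runif(1, 115, 140)
    n_veins <- sample(3:6, 1)
    veins <- lapply(seq_len(n_veins), function(i) {
      n_ctrl <- sample(3:7, 1)
      x <- seq(-40, width + 40, length.out = n_ctrl)
      y0 <- band_center + runif(1, -0.75, 0.75) * band_halfheight * 0.7
      y <- y0 + cumsum(c(0, runif(n_ctrl - 1, -35, 35)))
      # keep the vein inside the finger band
      y <- pmin(pmax(y, band_center - 0.85 * band_halfheight),
                band_center + 0.85 * band_halfheight)
      list(x = x, y = y, width = runif(1, 3, 8),
           depth = runif(1, 45, 75))
    })
    structure(list(finger_seed = finger_seed, width = as.integer(width),
                   height = as.integer(height), band_center = band_center,
                   band_halfheight = band_halfheight, veins = veins),
              class = "finger_model")
  })
}

# disc of offsets with radius r (pixels), used to stamp vein cross-sections
disc_offsets <- function(r) {
  k <- ceiling(r)
  d <- expand.grid(dr = -k:k, dc = -k:k)
  d[d$dr^2 + d$dc^2 <= r^2, , drop = FALSE]
}

#' Render one synthetic capture of a finger
#'
#' Draws the finger band and veins of `model`, shifted by a per-sample
#' integer translation, then applies Gaussian blur, a global brightness
#' offset and per-pixel noise. The output is fully determined by
#' `(model, sample_seed, params)`.
#'
#' @param model A [finger_model()].
#' @param sample_seed Integer seed for the per-sample variation.
#' @param params A [capture_params()].
#' @return A 480 x 640 (height x width) [gray_image()].
#' @export
generate_finger_image <- function(model, sample_seed,
                                  params = capture_params()) {
  stopifnot(inherits(model, "finger_model"), inherits(params, "capture_params"))
  with_seed(sample_seed, {
    W <- model$width
    H <- model$height
    dx <- if (params$jitter_tx > 0) sample(-params$jitter_tx:params$jitter_tx, 1) else 0L
    dy <- if (params$jitter_ty > 0) sample(-params$jitter_ty:params$jitter_ty, 1) else 0L
    brightness <- if (params$brightness_sd > 0) rnorm(1, 0, params$brightness_sd) else 0

    rows <- seq_len(H)
    cols <- seq_len(W)
    # elliptical finger-band profile, shifted by (dy, dx)
    ry <- (rows - (model$band_center + dy)) / model$band_halfheight
    rx <- (cols - (W / 2 + dx)) / (W / 2 + 60) # soft rounding at the tips
    band <- 1 - outer(ry^2, rx^2, `+`)
    finger <- band > 0
    img <- matrix(28, H, W)
    img[finger] <- 165 + 18 * band[finger] # brighter toward the finger axis

    # stamp veins: dense spline samples, disc of the vein's radius
    for (v in model$veins) {
      sp <- stats::spline(v$x, v$y, n = max(64L, 2L * W %/% 3L))
      px <- round(sp$x + dx)
      py <- round(sp$y + dy)
      keep <- px >= 1 & px <= W & py >= 1 & py <= H
      disc <- disc_offsets(v$width / 2)
      stamped <- matrix(FALSE, H, W)
      for (j in which(keep)) {
        rr <- py[j] + disc$dr
        cc <- px[j] + disc$dc
        ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
        stamped[cbind(rr[ok], cc[ok])] <- TRUE
      }
      dark <- stamped & finger
      img[dark] <- img[dark] - v$depth
    }

    if (params$blur_sigma > 0) {
      img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img / 255),
                                               sigma = params$blur_sigma)) * 255
    }
    img <- img + brightness
    if (params$noise_sd > 0) {
      img <- img + matrix(rnorm(H * W, 0, params$noise_sd), H, W)
    }
    gray_image(pmin(pmax(img, 0), 255))
  })
}

finger_seed_for <- function(root_seed, finger_index) {
  ((root_seed %% 100000L) * 10000L + finger_index) %% 2147483647L
}

sample_seed_for <- function(finger_seed, sample_number) {
  (finger_seed + 131071L * sample_number) %% 2147483647L
}

#' Generate a complete synthetic dataset
#'
#' Emulates the standard database layout — subjects x fingers x samples —
#' writing one image per sample plus a `manifest.csv` index. The whole
#' dataset is a pure function of `root_seed` and the counts: finger
#' anatomy is stable across samples of a finger, while samples vary by
#' translation jitter, brightness, blur and noise per `params`.
#'
#' @param n_subjects Number of subjects.
#' @param fingers_per_subject Fingers per subject, 1-4 (labelled
#'   left-index, left-middle, right-index, right-middle).
#' @param samples_per_finger Captures per finger.
#' @param root_seed Integer master seed.
#' @param out_dir Output directory (created if needed).
#' @param params A [capture_params()].
#' @param format `"png"` (default) or `"pgm"`.
#' @param write_images Set `FALSE` for a dry run that returns the index
#'   without rendering files (useful for structure checks); the index
#'   then carries the paths that a full run would create.
#' @return The dataset index tibble (as from [load_dataset_index()]),
#'   with the manifest written to `file.path(out_dir, "manifest.csv")`
#'   when `write_images` is `TRUE`.
#' @export
generate_dataset <- function(n_subjects, fingers_per_subject,
                             samples_per_finger, root_seed = 7L,
                             out_dir = NULL, params = capture_params(),
                             format = c("png", "pgm"), write_images = TRUE) {
  format <- match.arg(format)
  stopifnot(n_subjects >= 1L, fingers_per_subject >= 1L,
            fingers_per_subject <= 4L, samples_per_finger >= 1L)
  if (write_images) {
    if (is.null(out_dir)) stop("`out_dir` is required to write images", call. = FALSE)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) {
      stop(sprintf("cannot create output directory '%s'", out_dir), call. = FALSE)
    }
  }
  labels <- finger_labels[seq_len(fingers_per_subject)]
  grid <- expand.grid(sample = seq_len(samples_per_finger),
                      finger = labels, subject = seq_len(n_subjects),
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$subject, grid$finger, grid$sample), ]
  subject_id <- sprintf("S%03d", grid$subject)
  fname <- sprintf("%s_%s_%02d.%s", subject_id, grid$finger, grid$sample, format)
  finger_index <- as.integer(interaction(grid$subject, grid$finger, drop = TRUE))
  idx <- tibble::tibble(subject = subject_id, finger = grid$finger,
                        sample = as.integer(grid$sample),
                        path = if (is.null(out_dir)) fname else file.path(out_dir, fname))
  if (write_images) {
    models <- list()
    for (i in seq_len(nrow(idx))) {
      fi <- finger_index[i]
      key <- as.character(fi)
      if (is.null(models[[key]])) {
        models[[key]] <- finger_model(finger_seed_for(root_seed, fi))
      }
      img <- generate_finger_image(models[[key]],
                                   sample_seed_for(models[[key]]$finger_seed,
                                                   idx$sample[i]),
                                   params)
      write_image(img, idx$path[i])
    }
    readr::write_csv(idx, file.path(out_dir, "manifest.csv"))
  }
  validate_dataset_index(idx, base_dir = ".", check_paths = write_images)
}
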