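#' Enumerate genuine and imposter pairs of a dataset
#'
#' All unordered pairs of images: pairs of the same physical finger are
#' genuine, every remaining cross-finger pair is an imposter. For the
#' standard 204-finger, 10-sample database layout this gives 9,180
#' genuine and 2,070,600 imposter pairs.
#'
#' @param index Dataset index tibble from [load_dataset_index()] or
#'   [generate_dataset()].
#' @return A tibble with columns `pair_type` (`"genuine"`/`"imposter"`),
#'   `a`, `b` (row indices into `index`), `finger_a`, `finger_b`.
#' @export
enumerate_pairs <- function(index) {
  stopifnot(is.data.frame(index), "finger_id" %in% names(index))
  n <- nrow(index)
  if (n < 2L) stop("need at least 2 images to form pairs", call. = FALSE)
  fid <- index$finger_id
  ut <- which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
  a <- ut[, 1]
  b <- ut[, 2]
  genuine <- fid[a] == fid[b]
  if (!any(genuine)) {
    stop("no genuine pairs: every finger has a single sample", call. = FALSE)
  }
  tibble::tibble(
    pair_type = ifelse(genuine, "genuine", "imposter"),
    a = a, b = b,
    finger_a = fid[a], finger_b = fid[b]
  )
}

#' Score all pairs of a dataset through the verification pipeline
#'
#' Loads and preprocesses every image once, then runs alignment, code
#' extraction on the common regions, and Hamming matching for each pair.
#' Rejected alignments score 1.
#'
#' @param index Dataset index tibble (paths must resolve).
#' @param config Pipeline configuration.
#' @param pairs Optional pair table from [enumerate_pairs()]; defaults to
#'   all pairs.
#' @param images Optional list of raw [gray_image()]s aligned with
#'   `index` rows, bypassing file loading (used by [grid_search()]).
#' @param progress Print a line every 2000 pairs.
#' @return The `pairs` tibble with columns `hd` and `rejected` added —
#'   the labeled score set used by [far_frr_curves()].
#' @export
score_pairs <- function(index, config = default_config(), pairs = NULL,
                        images = NULL, progress = FALSE) {
  config <- validate_config(config)
  if (is.null(pairs)) pairs <- enumerate_pairs(index)
  if (is.null(images)) {
    images <- lapply(index$path, load_image)
  }
  enhanced <- lapply(images, preprocess_image, config = config)
  ffts <- lapply(enhanced, function(e) stats::fft(as_pixel_matrix(e)))
  limits <- alignment_limits(config[["align.max_tx"]], config[["align.max_ty"]])
  n <- nrow(pairs)
  hd <- numeric(n)
  rejected <- logical(n)
  for (i in seq_len(n)) {
    sc <- score_enhanced_pair(enhanced[[pairs$a[i]]], enhanced[[pairs$b[i]]],
                              ffts[[pairs$a[i]]], ffts[[pairs$b[i]]],
                              config, limits)
    hd[i] <- sc$hd
    rejected[i] <- sc$rejected
    if (progress && i %% 2000L == 0L) {
      message(sprintf("scored %d / %d pairs", i, n))
    }
  }
  pairs$hd <- hd
  pairs$rejected <- rejected
  pairs
}

# pair scorer on enhanced images with cached FFTs (hot loop of score_pairs)
score_enhanced_pair <- function(fA, fB, FA, FB, config, limits) {
  R <- FA * Conj(FB)
  mag <- Mod(R)
  floor_mag <- .Machine$double.eps * max(mag, 1)
  mag[mag < floor_mag] <- 1
  surf <- Re(stats::fft(R / mag, inverse = TRUE)) / length(FA)
  idx <- which.max(surf)
  t <- structure(list(
    t_x = unwrap_shift(-((idx - 1L) %/% nrow(surf)), ncol(surf)),
    t_y = unwrap_shift(-((idx - 1L) %% nrow(surf)), nrow(surf)),
    peak = surf[idx]
  ), class = "translation_estimate")
  reg <- common_region(fA, fB, t, limits)
  if (reg$rejected) {
    return(list(hd = 1, rejected = TRUE, translation = t))
  }
  list(hd = pair_hamming(reg$f_c, reg$g_c, config), rejected = FALSE,
       translation = t)
}

# Hamming distance of the configured codes of two aligned images, summing
# differing bits offset by offset instead of materializing the code maps;
# exactly equals hamming_distance(extract_code(a), extract_code(b))
pair_hamming <- function(a, b, config) {
  kind <- config[["descriptor.kind"]]
  ma <- as_pixel_matrix(a)
  mb <- as_pixel_matrix(b)
  if (kind == "lbp") {
    P <- config[["descriptor.P"]]
    R <- config[["descriptor.R"]]
    mg <- as.integer(ceiling(R))
    if (nrow(ma) <= 2L * mg || ncol(ma) <= 2L * mg) {
      stop("common region too small for the descriptor", call. = FALSE)
    }
    rows <- (mg + 1L):(nrow(ma) - mg)
    cols <- (mg + 1L):(ncol(ma) - mg)
    ca <- ma[rows, cols, drop = FALSE]
    cb <- mb[rows, cols, drop = FALSE]
    diffs <- 0
    for (p in seq_len(P) - 1L) {
      theta <- 2 * pi * p / P
      dc <- R * cos(theta)
      dr <- -R * sin(theta)
      diffs <- diffs + sum((sample_shifted(ma, rows, cols, dr, dc) >= ca) !=
                           (sample_shifted(mb, rows, cols, dr, dc) >= cb))
    }
    return(diffs / (length(ca) * P))
  }
  N <- check_line_params(config[["descriptor.N"]])
  mg <- (N - 1L) %/% 2L
  if (nrow(ma) < N || ncol(ma) < N) {
    stop("common region too small for the descriptor", call. = FALSE)
  }
  rows <- (mg + 1L):(nrow(ma) - mg)
  cols <- (mg + 1L):(ncol(ma) - mg)
  ca <- ma[rows, cols, drop = FALSE]
  cb <- mb[rows, cols, drop = FALSE]
  offs <- line_offsets(N)
  diffs <- 0
  bpp <- 0L
  if (kind %in% c("llbp", "llbp_h")) {
    for (d in offs) {
      diffs <- diffs + sum((ma[rows, cols + d, drop = FALSE] >= ca) !=
                           (mb[rows, cols + d, drop = FALSE] >= cb))
    }
    bpp <- bpp + (N - 1L)
  }
  if (kind %in% c("llbp", "llbp_v")) {
    for (d in offs) {
      diffs <- diffs + sum((ma[rows + d, cols, drop = FALSE] >= ca) !=
                           (mb[rows + d, cols, drop = FALSE] >= cb))
    }
    bpp <- bpp + (N - 1L)
  }
  diffs / (length(ca) * bpp)
}

as_score_set <- function(scores) {
  if (is.data.frame(scores)) {
    stopifnot(all(c("pair_type", "hd") %in% names(scores)))
    out <- list(genuine = scores$hd[scores$pair_type == "genuine"],
                imposter = scores$hd[scores$pair_type == "imposter"])
  } else if (is.list(scores) && all(c("genuine", "imposter") %in% names(scores))) {
    out <- scores[c("genuine", "imposter")]
  } else {
    stop("`scores` must be a score tibble or a list(genuine=, imposter=)",
         call. = FALSE)
  }
  if (length(out$genuine) == 0L || length(out$imposter) == 0L) {
    stop("both genuine and imposter scores are required", call. = FALSE)
  }
  if (min(out$genuine, out$imposter) < 0 || max(out$genuine, out$imposter) > 1) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  out
}

#' False-acceptance / false-rejection curves
#'
#' Sweeps an acceptance threshold `t` over `[0, 1]`: a pair is accepted
#' when `hd <= t`. FAR(t) is the percentage of imposter pairs accepted,
#' FRR(t) the percentage of genuine pairs rejected.
#'
#' @param scores A score tibble from [score_pairs()] (columns `pair_type`
#'   and `hd`) or a `list(genuine =, imposter =)` of distances.
#' @param n_thresholds Grid size over `[0, 1]` (default 1001).
#' @return A `verification_report`: list with `curve` (tibble of
#'   `threshold`, `far`, `frr` in percent), score counts, and `eer` /
#'   `eer_threshold` filled in by [equal_error_rate()].
#' @export
far_frr_curves <- function(scores, n_thresholds = 1001L) {
  ss <- as_score_set(scores)
  stopifnot(n_thresholds >= 2L)
  thr <- seq(0, 1, length.out = n_thresholds)
  # vectorized via sorted-score counting
  far <- 100 * ecdf_at(ss$imposter, thr)
  frr <- 100 * (1 - ecdf_at(ss$genuine, thr))
  structure(list(
    curve = tibble::tibble(threshold = thr, far = far, frr = frr),
    n_genuine = length(ss$genuine),
    n_imposter = length(ss$imposter),
    eer = NA_real_,
    eer_threshold = NA_real_
  ), class = "verification_report")
}

# P(x <= t) for each t (right-continuous empirical CDF)
ecdf_at <- function(x, t) {
  findInterval(t, sort(x)) / length(x)
}

#' Equal error rate of a verification report
#'
#' The operating point where FAR equals FRR, linearly interpolated
#' between the adjacent thresholds bracketing the sign change of
#' FAR - FRR. If the curves never cross on the grid, the boundary value
#' closest to a crossing is returned with a warning.
#'
#' @param report A `verification_report` from [far_frr_curves()].
#' @return The report with `eer` (percent) and `eer_threshold` filled in.
#'   Use `glance()` or `$eer` to extract the number.
#' @export
equal_error_rate <- function(report) {
  stopifnot(inherits(report, "verification_report"))
  cv <- report$curve
  d <- cv$far - cv$frr # non-decreasing - non-increasing => non-decreasing
  i <- which(d >= 0)[1]
  if (is.na(i)) {
    warning("FAR and FRR never cross within the threshold grid; ",
            "reporting the boundary value")
    i <- nrow(cv)
    report$eer <- (cv$far[i] + cv$frr[i]) / 2
    report$eer_threshold <- cv$threshold[i]
    return(report)
  }
  if (i == 1L || d[i] == 0) {
    report$eer <- (cv$far[i] + cv$frr[i]) / 2
    report$eer_threshold <- cv$threshold[i]
    return(report)
  }
  # interpolate the crossing of the two line segments on [t_{i-1}, t_i]
  dfar <- cv$far[i] - cv$far[i - 1]
  dfrr <- cv$frr[i] - cv$frr[i - 1]
  alpha <- (cv$frr[i - 1] - cv$far[i - 1]) / (dfar - dfrr)
  report$eer <- cv$far[i - 1] + alpha * dfar
  report$eer_threshold <- cv$threshold[i - 1] +
    alpha * (cv$threshold[i] - cv$threshold[i - 1])
  report
}

#' Evaluate a score set end to end
#'
#' Convenience wrapper: [far_frr_curves()] followed by
#' [equal_error_rate()].
#'
#' @inheritParams far_frr_curves
#' @return A completed `verification_report`.
#' @export
evaluate_scores <- function(scores, n_thresholds = 1001L) {
  equal_error_rate(far_frr_curves(scores, n_thresholds))
}

#' @export
print.verification_report <- function(x, ...) {
  cat(sprintf(
    "<verification_report> %d genuine / %d imposter scores, %d thresholds\n",
    x$n_genuine, x$n_imposter, nrow(x$curve)))
  if (!is.na(x$eer)) {
    cat(sprintf("  EER = %.2f%% at threshold %.4f\n", x$eer, x$eer_threshold))
  }
  invisible(x)
}

#' @describeIn far_frr_curves `tidy()` returns the threshold/FAR/FRR
#'   curve as a tibble.
#' @param x A `verification_report`.
#' @param ... Unused.
#' @method tidy verification_report
#' @export
tidy.verification_report <- function(x, ...) {
  x$curve
}

#' @describeIn far_frr_curves `glance()` returns a one-row summary with
#'   `eer`, `eer_threshold`, `n_genuine`, `n_imposter`.
#' @method glance verification_report
#' @export
glance.verification_report <- function(x, ...) {
  tibble::tibble(eer = x$eer, eer_threshold = x$eer_threshold,
                 n_genuine = x$n_genuine, n_imposter = x$n_imposter)
}

#' @describeIn far_frr_curves `autoplot()` draws the FAR and FRR curves
#'   against the acceptance threshold, marking the EER.
#' @param object A `verification_report`.
#' @method autoplot verification_report
#' @export
autoplot.verification_report <- function(object, ...) {
  long <- tidyr_pivot(object$curve)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$rate,
                                          color = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "acceptance threshold (Hamming distance)",
                  y = "error rate (%)", color = NULL) +
    ggplot2::theme_minimal()
  if (!is.na(object$eer)) {
    p <- p + ggplot2::annotate("point", x = object$eer_threshold,
                               y = object$eer, shape = 4, size = 3) +
      ggplot2::annotate("text", x = object$eer_threshold, y = object$eer,
                        label = sprintf(" EER = %.2f%%", object$eer),
                        hjust = 0, vjust = -0.5)
  }
  p
}

# minimal wide-to-long for the two curve columns (avoids a tidyr dependency)
tidyr_pivot <- function(curve) {
  tibble::tibble(
    threshold = rep(curve$threshold, 2L),
    metric = rep(c("FAR", "FRR"), each = nrow(curve)),
    rate = c(curve$far, curve$frr)
  )
}

#' Grid search over descriptor line length and mask size
#'
#' Re-runs the full pipeline on every `(N, S)` cell of a parameter grid
#' and records the equal error rate, reproducing the standard tuning
#' protocol (choose the cell with the lowest EER on a tuning subset).
#' Cell failures are isolated: a cell that errors is flagged and the
#' remaining cells are still computed.
#'
#' @param index Dataset index of the tuning subset.
#' @param N_values Odd line lengths to try.
#' @param S_values Odd enhancement mask sizes to try.
#' @param config Base configuration (descriptor kind etc.).
#' @param images Optional preloaded raw images aligned with `index`.
#' @return A tibble with columns `N`, `S`, `eer` (percent, `NA` on
#'   failure) and `error` (message or `NA`), with the best cell in
#'   `attr(, "best")`.
#' @export
grid_search <- function(index, N_values, S_values, config = default_config(),
                        images = NULL) {
  config <- validate_config(config)
  if (is.null(images)) images <- lapply(index$path, load_image)
  pairs <- enumerate_pairs(index)
  cells <- expand.grid(N = as.integer(N_values), S = as.integer(S_values))
  res <- lapply(seq_len(nrow(cells)), function(i) {
    cfg <- unclass(config)
    cfg[["descriptor.N"]] <- cells$N[i]
    cfg[["enhance.S"]] <- cells$S[i]
    tryCatch({
      sc <- score_pairs(index, validate_config(cfg), pairs = pairs,
                        images = images)
      rep <- evaluate_scores(sc)
      tibble::tibble(N = cells$N[i], S = cells$S[i], eer = rep$eer,
                     error = NA_character_)
    }, error = function(e) {
      tibble::tibble(N = cells$N[i], S = cells$S[i], eer = NA_real_,
                     error = conditionMessage(e))
    })
  })
  tab <- dplyr::bind_rows(res)
  ok <- which(!is.na(tab$eer))
  best <- if (length(ok) > 0L) tab[ok[which.min(tab$eer[ok])], ] else NULL
  attr(tab, "best") <- best
  tab
}
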