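#' Normalized Hamming distance between two binary codes
#'
#' Fraction of differing bits: `|codeA XOR codeB| / CodeLength`. Scores
#' near 0 indicate the same finger, scores near 0.5 unrelated codes.
#'
#' @param codeA,codeB `code_map`s of identical geometry, or logical
#'   vectors/arrays of identical length.
#' @return Numeric in `[0, 1]`.
#' @export
hamming_distance <- function(codeA, codeB) {
  a <- code_bits(codeA)
  b <- code_bits(codeB)
  if (length(a) != length(b)) {
    stop(sprintf("code length mismatch: %d vs %d bits", length(a), length(b)),
         call. = FALSE)
  }
  if (length(a) == 0L) stop("empty codes", call. = FALSE)
  sum(a != b) / length(a)
}

code_bits <- function(x) {
  if (inherits(x, "code_map")) return(x$bits)
  if (is.character(x) && length(x) == 1L) {
    return(strsplit(x, "")[[1]] == "1")
  }
  if (is.logical(x)) return(x)
  if (is.numeric(x) && all(x %in% c(0, 1))) return(x == 1)
  stop("codes must be code_maps, logical bits or 0/1 strings", call. = FALSE)
}

new_match_score <- function(hd, rejected, translation) {
  structure(list(hd = hd, rejected = rejected, translation = translation),
            class = "match_score")
}

#' @export
print.match_score <- function(x, ...) {
  if (x$rejected) {
    cat(sprintf("<match_score> REJECTED at alignment (t_x = %d, t_y = %d); hd = 1\n",
                x$translation$t_x, x$translation$t_y))
  } else {
    cat(sprintf("<match_score> hd = %.4f (t_x = %d, t_y = %d, peak = %.3f)\n",
                x$hd, x$translation$t_x, x$translation$t_y, x$translation$peak))
  }
  invisible(x)
}

#' Verify a pair of finger images
#'
#' Runs the full pipeline on two captures: preprocessing (ROI crop,
#' resize, enhancement), phase-only correlation alignment, common-region
#' extraction, code extraction on both common regions, and the normalized
#' Hamming distance. Pairs whose translation exceeds the alignment
#' limits are rejected and scored with the maximal distance 1.
#'
#' @param imageA,imageB [gray_image()]s (raw captures, or already
#'   enhanced images if `preprocessed = TRUE`).
#' @param config Pipeline configuration, see [default_config()].
#' @param preprocessed Set `TRUE` when the inputs are already enhanced
#'   `192 x 64`-style images, skipping the preprocessing stage.
#' @return A `match_score` with fields `hd`, `rejected`, `translation`.
#' @export
verify_pair <- function(imageA, imageB, config = default_config(),
                        preprocessed = FALSE) {
  config <- validate_config(config)
  if (!preprocessed) {
    imageA <- preprocess_image(imageA, config)
    imageB <- preprocess_image(imageB, config)
  }
  t <- estimate_translation(imageA, imageB, window = config[["align.window"]])
  reg <- common_region(imageA, imageB, t,
                       alignment_limits(config[["align.max_tx"]],
                                        config[["align.max_ty"]]))
  if (reg$rejected) {
    return(new_match_score(hd = 1, rejected = TRUE, translation = t))
  }
  codeA <- extract_code(reg$f_c, config)
  codeB <- extract_code(reg$g_c, config)
  new_match_score(hd = hamming_distance(codeA, codeB),
                  rejected = FALSE, translation = t)
}
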