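#' Construct an 8-bit grayscale image
#'
#' The package-wide image container: an integer matrix with values in
#' `[0, 255]`, rows indexing image height (top to bottom) and columns
#' indexing width (left to right).
#'
#' @param pixels Numeric matrix; values are rounded and must fall in
#'   `[0, 255]` after rounding.
#' @return A `gray_image` object (integer matrix with class attribute).
#' @examples
#' img <- gray_image(matrix(0:255, 16, 16))
#' dim(img)
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image must have at least one row and one column", call. = FALSE)
  }
  px <- round_half_up(pixels)
  if (anyNA(px) || min(px) < 0 || max(px) > 255) {
    stop("pixel intensities must lie in [0, 255]", call. = FALSE)
  }
  storage.mode(px) <- "integer"
  structure(px, class = c("gray_image", "matrix", "array"))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf(
    "<gray_image> %d x %d (height x width), intensities %d..%d\n",
    nrow(x), ncol(x), min(x), max(x)
  ))
  invisible(x)
}

# round-half-up to integer; base round() ties to even
round_half_up <- function(x) floor(x + 0.5)

as_pixel_matrix <- function(image) {
  m <- unclass(image)
  storage.mode(m) <- "double"
  m
}

#' Read a grayscale image from disk
#'
#' Reads PNG (grayscale or color, converted to luminance) or binary PGM
#' (P5, maxval 255) rasters into a [gray_image()].
#'
#' @param path Path to a `.png` or `.pgm` file.
#' @return A `gray_image`.
#' @seealso [write_image()]
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    stop("`path` must be a single file path", call. = FALSE)
  }
  if (!file.exists(path)) {
    stop(sprintf("image file not found: '%s'", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- tryCatch(png::readPNG(path), error = function(e) {
      stop(sprintf("corrupt or unreadable PNG '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    })
    if (length(dim(arr)) == 3L) {
      # drop alpha if present, then Rec. 601 luminance
      d <- dim(arr)
      lum <- if (d[3] >= 3L) {
        0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
      } else {
        arr[, , 1]
      }
      arr <- matrix(lum, d[1], d[2])
    }
    gray_image(arr * 255)
  } else if (ext %in% c("pgm", "pnm")) {
    read_pgm(path)
  } else {
    stop(sprintf("unsupported image format '.%s' (use PNG or PGM)", ext),
         call. = FALSE)
  }
}

#' Write a grayscale image to disk
#'
#' @param image A [gray_image()] (or plain matrix in `[0, 255]`).
#' @param path Destination path; format chosen by extension (`.png` or
#'   `.pgm`). Both formats are lossless for 8-bit data.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  image <- gray_image(as_pixel_matrix(image))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(as_pixel_matrix(image) / 255, target = path)
  } else if (ext %in% c("pgm", "pnm")) {
    write_pgm(image, path)
  } else {
    stop(sprintf("unsupported image format '.%s' (use PNG or PGM)", ext),
         call. = FALSE)
  }
  invisible(path)
}

# Minimal binary PGM (P5, maxval <= 255) reader; no installed package
# handles PNM rasters and the format is trivial.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- character(0)
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop("truncated PGM header", call. = FALSE)
      if (ch == "#") { # comment to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
        next
      }
      if (grepl("^[ \t\r\n]$", ch)) {
        if (length(tok) > 0L) break else next
      }
      tok <- c(tok, ch)
    }
    paste(tok, collapse = "")
  }
  magic <- read_token()
  if (magic != "P5") {
    stop(sprintf("not a binary PGM (P5) file: '%s'", path), call. = FALSE)
  }
  width <- as.integer(read_token())
  height <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (anyNA(c(width, height, maxval)) || width < 1L || height < 1L) {
    stop(sprintf("corrupt PGM header in '%s'", path), call. = FALSE)
  }
  if (maxval > 255L) {
    stop("16-bit PGM not supported (maxval > 255)", call. = FALSE)
  }
  raw <- readBin(con, "integer", n = width * height, size = 1L, signed = FALSE)
  if (length(raw) != width * height) {
    stop(sprintf("truncated PGM pixel data in '%s'", path), call. = FALSE)
  }
  gray_image(matrix(raw, nrow = height, ncol = width, byrow = TRUE))
}

write_pgm <- function(image, path) {
  m <- unclass(image)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(m), nrow(m)), con, eos = NULL)
  writeBin(as.integer(t(m)), con, size = 1L)
  invisible(path)
}

finger_labels <- c("left-index", "left-middle", "right-index", "right-middle")

#' Load and validate a dataset manifest
#'
#' The manifest is a CSV with header `subject,finger,sample,path` listing
#' one captured image per row. Fingers are labelled
#' `left-index`, `left-middle`, `right-index`, `right-middle`; the
#' `(subject, finger, sample)` triple must be unique and every path must
#' resolve to an existing file (relative paths are resolved against the
#' manifest's directory).
#'
#' @param manifest Path to the manifest CSV.
#' @param check_paths Verify that every image file exists (default `TRUE`).
#' @return A tibble with columns `subject`, `finger`, `sample`, `path` and
#'   an additional `finger_id` column (`subject/finger` key identifying a
#'   physical finger).
#' @export
load_dataset_index <- function(manifest, check_paths = TRUE) {
  if (!file.exists(manifest)) {
    stop(sprintf("manifest not found: '%s'", manifest), call. = FALSE)
  }
  idx <- readr::read_csv(manifest, show_col_types = FALSE,
                         col_types = readr::cols(
                           subject = readr::col_character(),
                           finger = readr::col_character(),
                           sample = readr::col_integer(),
                           path = readr::col_character()
                         ))
  validate_dataset_index(idx, base_dir = dirname(manifest),
                         check_paths = check_paths)
}

validate_dataset_index <- function(idx, base_dir = ".", check_paths = TRUE) {
  required <- c("subject", "finger", "sample", "path")
  missing_cols <- setdiff(required, names(idx))
  if (length(missing_cols) > 0L) {
    stop(sprintf("manifest missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  idx <- tibble::as_tibble(idx)
  if (nrow(idx) == 0L) {
    idx$finger_id <- character(0)
    return(idx)
  }
  bad <- setdiff(unique(idx$finger), finger_labels)
  if (length(bad) > 0L) {
    stop(sprintf("unknown finger label(s): %s (expected one of %s)",
                 paste(bad, collapse = ", "),
                 paste(finger_labels, collapse = ", ")), call. = FALSE)
  }
  key <- paste(idx$subject, idx$finger, idx$sample, sep = "/")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop(sprintf("duplicate (subject, finger, sample) triple: %s", dup),
         call. = FALSE)
  }
  resolved <- ifelse(grepl("^(/|[A-Za-z]:)", idx$path),
                     idx$path, file.path(base_dir, idx$path))
  if (check_paths) {
    gone <- !file.exists(resolved)
    if (any(gone)) {
      stop(sprintf("%d manifest path(s) do not exist, e.g. '%s'",
                   sum(gone), resolved[which(gone)[1]]), call. = FALSE)
    }
  }
  idx$path <- resolved
  idx$finger_id <- paste(idx$subject, idx$finger, sep = "/")
  idx
}
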