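config_defaults <- function() {
  list(
    "enhance.S" = 15L,
    "enhance.a" = 12.53,
    "enhance.b" = -4,
    "enhance.D0" = NULL, # NULL -> S / 2
    "roi.width" = 480L,
    "roi.height" = 160L,
    "resize.ratio" = 0.4,
    "align.max_tx" = 20L,
    "align.max_ty" = 10L,
    "align.window" = "none",
    "descriptor.kind" = "llbp",
    "descriptor.N" = 21L,
    "descriptor.P" = 8L,
    "descriptor.R" = 1
  )
}

#' Default pipeline configuration
#'
#' Returns the full set of pipeline parameters at their tuned defaults:
#' enhancement mask size `S = 15`, amplitude/DC adjustments
#' `a = 12.53`, `b = -4`, Gaussian width `D0 = S / 2`, a 480 x 160 ROI
#' downscaled by 0.4, alignment limits of 20 (horizontal) and 10
#' (vertical) pixels, and the concatenated line descriptor with
#' `N = 21` (use `descriptor.kind = "llbp_v"`, `descriptor.N = 17` for
#' the lighter vertical-only variant).
#'
#' @param ... Named overrides using the dotted config keys, e.g.
#'   `default_config("descriptor.N" = 17, "descriptor.kind" = "llbp_v")`.
#' @return A validated named list of class `pipeline_config`.
#' @export
default_config <- function(...) {
  overrides <- list(...)
  cfg <- config_defaults()
  if (length(overrides) > 0L) {
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown) > 0L || is.null(names(overrides)) ||
        any(names(overrides) == "")) {
      stop(sprintf("unknown config key(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    cfg[names(overrides)] <- overrides
  }
  validate_config(cfg)
}

#' Load a pipeline configuration from YAML
#'
#' The file is flat YAML with the dotted keys documented in
#' [default_config()]; missing keys take their defaults, unknown keys are
#' errors (silent typos in parameter studies are costly).
#'
#' @param path YAML file path. An empty file yields the defaults.
#' @return A validated `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: '%s'", path), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (length(raw) > 0L) do.call(default_config, raw) else default_config()
}

#' Save a pipeline configuration to YAML
#'
#' @param config A `pipeline_config`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  config <- validate_config(config)
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

validate_config <- function(config) {
  if (inherits(config, "pipeline_config")) return(config)
  defaults <- config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  cfg <- defaults
  cfg[names(config)] <- config
  check <- function(ok, key, msg) {
    if (!ok) stop(sprintf("config key `%s`: %s", key, msg), call. = FALSE)
  }
  S <- cfg[["enhance.S"]]
  check(is.numeric(S) && S >= 3 && S %% 2 == 1, "enhance.S",
        "must be an odd integer >= 3")
  d0 <- cfg[["enhance.D0"]]
  check(is.null(d0) || (is.numeric(d0) && d0 > 0), "enhance.D0",
        "must be positive (or omitted for S / 2)")
  check(cfg[["roi.width"]] >= 1 && cfg[["roi.height"]] >= 1,
        "roi.width/roi.height", "must be positive")
  check(is.numeric(cfg[["resize.ratio"]]) && cfg[["resize.ratio"]] > 0,
        "resize.ratio", "must be positive")
  check(cfg[["align.max_tx"]] > 0, "align.max_tx", "must be positive")
  check(cfg[["align.max_ty"]] > 0, "align.max_ty", "must be positive")
  check(cfg[["align.window"]] %in% c("none", "hann"), "align.window",
        "must be 'none' or 'hann'")
  check(cfg[["descriptor.kind"]] %in% c("llbp", "llbp_h", "llbp_v", "lbp"),
        "descriptor.kind", "must be one of llbp, llbp_h, llbp_v, lbp")
  N <- cfg[["descriptor.N"]]
  check(is.numeric(N) && N >= 3 && N %% 2 == 1, "descriptor.N",
        "must be an odd integer >= 3")
  check(cfg[["descriptor.P"]] >= 1, "descriptor.P", "must be >= 1")
  check(cfg[["descriptor.R"]] > 0, "descriptor.R", "must be positive")
  int_keys <- c("enhance.S", "roi.width", "roi.height", "align.max_tx",
                "align.max_ty", "descriptor.N", "descriptor.P")
  cfg[int_keys] <- lapply(cfg[int_keys], as.integer)
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-16s %s\n", k, if (is.null(v)) "(auto)" else format(v)))
  }
  invisible(x)
}
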