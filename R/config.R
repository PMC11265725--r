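#' Pipeline run configuration
#'
#' Collects every tunable of the detection pipeline with its default.
#' Defaults that the method fixes: `a1 = 2`, `a2 = 1`, `gp = 0.5`,
#' `block_size = 8`, `closing_radius = 5`, `noise_sigma = 0.1` (synthetic
#' noise category). The rest are implementation choices documented in the
#' methods vignette. Unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults; see [run_config_defaults()].
#' @return A validated `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- run_config_defaults()
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == "")))
    stop("configuration overrides must be named", call. = FALSE)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  cfg[names(over)] <- over
  validate_config(cfg)
}

#' Default configuration values
#'
#' @return Named list of the pipeline defaults.
#' @export
run_config_defaults <- function() {
  list(
    block_size = 8L,
    gray_variant = "printed",
    contrast_threshold = 0.04,
    edge_threshold = 10,
    sift_max_scale = 8,
    a1 = 2,
    a2 = 1,
    gp = 0.5,
    max_iter = 20L,
    lambda_floor = 1e-6,
    threshold = 127.5,
    f_variant = "printed",
    member_rule = "mean",
    n_bins = 32L,
    distance_threshold = 0.1,
    max_rounds = 50L,
    closing_radius = 5L,
    min_region_pixels = 64L,
    noise_sigma = 0.1,
    seed = 1L
  )
}

validate_config <- function(cfg) {
  # eom_params performs the numeric validation of its own subset
  eom_params(a1 = cfg$a1, a2 = cfg$a2, gp = cfg$gp, max_iter = cfg$max_iter,
             lambda_floor = cfg$lambda_floor, seed = cfg$seed,
             threshold = cfg$threshold, f_variant = cfg$f_variant,
             member_rule = cfg$member_rule)
  if (!cfg$gray_variant %in% c("printed", "bt601"))
    stop("'gray_variant' must be \"printed\" or \"bt601\"", call. = FALSE)
  for (nm in c("block_size", "contrast_threshold", "edge_threshold",
               "n_bins", "distance_threshold", "max_rounds",
               "closing_radius", "min_region_pixels", "noise_sigma"))
    stopifnot_scalar_number(cfg[[nm]], nm)
  if (!is.numeric(cfg$sift_max_scale) || length(cfg$sift_max_scale) != 1L ||
      is.na(cfg$sift_max_scale) || cfg$sift_max_scale <= 0)
    stop("'sift_max_scale' must be a positive number (possibly Inf)",
         call. = FALSE)
  if (cfg$block_size < 2) stop("'block_size' must be at least 2", call. = FALSE)
  if (cfg$distance_threshold < 0)
    stop("'distance_threshold' must be non-negative", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Load a configuration file
#'
#' Reads a YAML (or plain `key: value`) configuration file and merges it
#' over the defaults; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("configuration file not found: '%s'", path), call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config:\n")
  for (nm in names(x)) cat(sprintf("  %s: %s\n", nm, format(x[[nm]])))
  invisible(x)
}
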