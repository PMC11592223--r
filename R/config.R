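#' Default pipeline configuration
#'
#' All user-facing constants of the two pipelines in one place. The
#' tangent-detection defaults mirror the sliding-window constants (window
#' = a tenth of the curve sequence, step 2 samples); the triangle
#' thresholds are the explicit severity calibration of
#' [grade_from_triangle()]; the edge-operator settings drive
#' [measure_atr()].
#'
#' @param ... named overrides of the defaults.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    n_samples = 200L,
    window_frac = 0.1,
    step = 2L,
    rel_prominence = 0.2,
    triangle_thresholds = c(2, 5, 10),
    edge_operator = "prewitt",
    log_sigma = 1.4,
    denoise = TRUE,
    equalize = FALSE,
    binarize_threshold = "otsu",
    ampd_seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stopf("unknown config field %s", unknown[[1L]])
  cfg[names(over)] <- over
  validate_config(structure(cfg, class = "pipeline_config"))
}

validate_config <- function(cfg) {
  if (cfg$n_samples < 20L) stopf("n_samples must be at least 20")
  if (cfg$window_frac <= 0 || cfg$window_frac > 0.5) {
    stopf("window_frac must lie in (0, 0.5]")
  }
  if (cfg$step < 1L) stopf("step must be at least 1")
  if (length(cfg$triangle_thresholds) != 3L ||
      any(diff(cfg$triangle_thresholds) <= 0)) {
    stopf("triangle_thresholds must be 3 strictly ascending values")
  }
  if (!cfg$edge_operator %in% c("prewitt", "roberts", "log")) {
    stopf("edge_operator must be prewitt, roberts or log")
  }
  if (cfg$log_sigma <= 0) stopf("log_sigma must be positive")
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Fields missing from the file keep their [pipeline_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  over <- yaml::read_yaml(path)
  if (is.null(over)) over <- list()
  do.call(pipeline_config, over)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  for (nm in names(x)) {
    cat(sprintf("  %-20s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}
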