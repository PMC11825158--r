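#' Quantification configuration
#'
#' Bundles the tunable thresholds of the quantification pipeline. Defaults
#' follow the conventions used for immature human testis sections: a tubule
#' cross-section counts as *round* when its longest/shortest Feret diameter
#' ratio is strictly below 1.5; a sample is flagged (never excluded) when it
#' has fewer than 25 round tubular cross sections or when its total tubular
#' area falls below 0.015 mm2 (fetal) / 0.003 mm2 (prepubertal).
#'
#' @param roundness_threshold Diameter-ratio threshold; a tubule is round when
#'   `ratio < roundness_threshold` (strict). Must be > 1.
#' @param edge_tolerance Distance in mm from the region-of-interest boundary
#'   within which a tubule vertex marks the tubule as edge-clipped (not
#'   intact). Default 0.002 mm.
#' @param min_round_tubules Minimum number of round tubular cross sections per
#'   section/sample before the `few_round_tubules` QC flag is raised.
#' @param min_total_area_mm2 Minimum total tubular area (mm2) before the
#'   `small_total_area` QC flag is raised. Either a single number or a vector
#'   named by tissue type (`fetal`, `prepubertal`).
#' @param pooling_mode How sections are aggregated to sample level:
#'   `"per_section_mean"` (unweighted mean of defined section-level metric
#'   values) or `"pooled_counts"` (sum counts and areas across sections, then
#'   reapply the formulas).
#' @param alpha Significance level for all hypothesis tests and the normality
#'   gate. Must lie in (0, 1).
#'
#' @return An object of class `quant_config`.
#' @export
quant_config <- function(roundness_threshold = 1.5,
                         edge_tolerance = 0.002,
                         min_round_tubules = 25,
                         min_total_area_mm2 = c(fetal = 0.015, prepubertal = 0.003),
                         pooling_mode = c("per_section_mean", "pooled_counts"),
                         alpha = 0.05) {
  pooling_mode <- match.arg(pooling_mode)
  if (!is.numeric(roundness_threshold) || length(roundness_threshold) != 1L ||
      !is.finite(roundness_threshold) || roundness_threshold <= 1) {
    stop_config("roundness_threshold must be a single finite number > 1")
  }
  if (!is.numeric(edge_tolerance) || length(edge_tolerance) != 1L ||
      !is.finite(edge_tolerance) || edge_tolerance < 0) {
    stop_config("edge_tolerance must be a single non-negative number (mm)")
  }
  if (!is.numeric(min_round_tubules) || length(min_round_tubules) != 1L ||
      min_round_tubules < 0) {
    stop_config("min_round_tubules must be a single non-negative count")
  }
  if (!is.numeric(min_total_area_mm2) || any(min_total_area_mm2 < 0)) {
    stop_config("min_total_area_mm2 must be non-negative (mm2)")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop_config("alpha must lie strictly between 0 and 1")
  }
  structure(
    list(roundness_threshold = roundness_threshold,
         edge_tolerance = edge_tolerance,
         min_round_tubules = as.integer(min_round_tubules),
         min_total_area_mm2 = min_total_area_mm2,
         pooling_mode = pooling_mode,
         alpha = alpha),
    class = "quant_config"
  )
}

#' Read a quantification configuration from a YAML or JSON file
#'
#' Fields present in the file override the defaults of [quant_config()];
#' fields absent keep their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file whose keys mirror the
#'   arguments of [quant_config()].
#' @return A `quant_config` object.
#' @export
read_quant_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop_config("unsupported config format '", ext, "' (use YAML or JSON)")
  }
  if (!is.list(vals)) stop_config("config file must contain a mapping: ", path)
  known <- names(formals(quant_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop_config("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(vals$min_total_area_mm2) && is.list(vals$min_total_area_mm2)) {
    vals$min_total_area_mm2 <- unlist(vals$min_total_area_mm2)
  }
  do.call(quant_config, vals)
}

# Minimum-area QC threshold for a tissue type; falls back to the strictest
# (largest) declared threshold when the tissue type is unknown.
min_area_for <- function(config, tissue_type = NULL) {
  m <- config$min_total_area_mm2
  if (length(m) == 1L && is.null(names(m))) return(unname(m))
  if (!is.null(tissue_type) && length(tissue_type) == 1L &&
      !is.na(tissue_type) && tissue_type %in% names(m)) {
    return(unname(m[[tissue_type]]))
  }
  unname(max(m))
}

# condition helpers -----------------------------------------------------------

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("tq_config_error", "error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("tq_data_error", "error")))
}

stop_analysis <- function(...) {
  stop(errorCondition(paste0(...), class = c("tq_analysis_error", "error")))
}

stop_geometry <- function(...) {
  stop(errorCondition(paste0(...), class = c("tq_geometry_error", "error")))
}
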