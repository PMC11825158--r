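METRIC_NAMES <- c("method1", "method2", "method3", "method4")

#' Section-level quantification metrics
#'
#' Applies the four germ-cell quantification formulas to one section. Only
#' intact tubules enter any count or area:
#'
#' * Method 1 — tubular germ cell density: germ cells / total tubular area
#'   (cells per mm2, all tubule shapes).
#' * Method 2 — spermatogonia per round tubular cross section (S/T): germ
#'   cells in round tubules / number of round tubules.
#' * Method 3 — fertility index (FI): 100 x round tubules containing at
#'   least one germ cell / number of round tubules (percent).
#' * Method 4 — round tubular germ cell density: germ cells in round
#'   tubules / round tubular area (cells per mm2).
#'
#' A metric with a zero denominator is reported missing (`NA`), never an
#' error. QC flags (`few_round_tubules`, `small_total_area`) mark sections
#' below the round-tubule and total-area conventions; they never exclude
#' data.
#'
#' @param features Per-tubule feature table from [compute_tubule_features()].
#' @param config A [quant_config()].
#' @param tissue_type Optional `"fetal"` or `"prepubertal"`; selects the
#'   minimum-area QC threshold.
#' @return One-row data frame (class `section_metrics`).
#' @export
compute_section_metrics <- function(features, config = quant_config(),
                                    tissue_type = NULL) {
  f <- features[features$is_intact, , drop = FALSE]
  n_tub <- nrow(f)
  n_round <- sum(f$is_round)
  total_area <- sum(f$area_mm2)
  round_area <- sum(f$area_mm2[f$is_round])
  n_cells_total <- sum(f$cell_count_total)
  n_cells_in_round <- sum(f$cell_count_total[f$is_round])
  n_round_with_cells <- sum(f$is_round & f$cell_count_total > 0L)

  method1 <- if (total_area > 0) n_cells_total / total_area else NA_real_
  method2 <- if (n_round > 0) n_cells_in_round / n_round else NA_real_
  method3 <- if (n_round > 0) 100 * n_round_with_cells / n_round else NA_real_
  method4 <- if (round_area > 0) n_cells_in_round / round_area else NA_real_

  flags <- character()
  if (n_round < config$min_round_tubules) flags <- c(flags, "few_round_tubules")
  if (total_area < min_area_for(config, tissue_type)) {
    flags <- c(flags, "small_total_area")
  }

  out <- data.frame(
    section_id = attr(features, "section_id") %||% NA_character_,
    sample_id = attr(features, "sample_id") %||% NA_character_,
    n_tubules_analysed = n_tub,
    n_round = n_round,
    total_tubular_area_mm2 = total_area,
    round_tubular_area_mm2 = round_area,
    n_cells_total = n_cells_total,
    n_cells_in_round = n_cells_in_round,
    n_round_with_cells = n_round_with_cells,
    n_cells_AP2G = sum(f$cell_count_AP2G),
    n_cells_MAGEA4 = sum(f$cell_count_MAGEA4),
    method1 = method1, method2 = method2,
    method3 = method3, method4 = method4,
    qc_flags = paste(flags, collapse = ";"))
  class(out) <- c("section_metrics", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate section metrics to sample level
#'
#' Joins the study design and aggregates every sample's sections. In
#' `per_section_mean` mode each metric is the unweighted mean of the
#' section-level values that are defined (sections where a metric is missing
#' are omitted from that metric's mean); in `pooled_counts` mode counts and
#' areas are summed across sections and the four formulas reapplied to the
#' pooled totals. `n_round_total` is always the sum over sections, and QC
#' flags are re-evaluated on the pooled totals.
#'
#' @param sections Data frame of stacked section metrics rows.
#' @param design A [study_design()].
#' @param config A [quant_config()].
#' @return Data frame with one row per sample (class `sample_metrics`).
#' @export
aggregate_by_sample <- function(sections, design, config = quant_config()) {
  sections <- as.data.frame(sections)
  design <- study_design(design)
  unknown <- setdiff(sections$sample_id, design$sample_id)
  if (length(unknown)) {
    stop_data("sample_id(s) absent from study design: ",
              paste(unknown, collapse = ", "))
  }
  samp_ids <- sort(unique(sections$sample_id), method = "radix")
  rows <- lapply(samp_ids, function(sid) {
    s <- sections[sections$sample_id == sid, , drop = FALSE]
    drow <- design[design$sample_id == sid, , drop = FALSE]
    totals <- list(
      n_round = sum(s$n_round),
      total_area = sum(s$total_tubular_area_mm2),
      round_area = sum(s$round_tubular_area_mm2),
      n_cells_total = sum(s$n_cells_total),
      n_cells_in_round = sum(s$n_cells_in_round),
      n_round_with_cells = sum(s$n_round_with_cells))

    if (config$pooling_mode == "per_section_mean") {
      mvals <- vapply(METRIC_NAMES, function(m) {
        v <- s[[m]][!is.na(s[[m]])]
        if (length(v)) mean(v) else NA_real_
      }, numeric(1L))
    } else {
      mvals <- c(
        method1 = if (totals$total_area > 0)
          totals$n_cells_total / totals$total_area else NA_real_,
        method2 = if (totals$n_round > 0)
          totals$n_cells_in_round / totals$n_round else NA_real_,
        method3 = if (totals$n_round > 0)
          100 * totals$n_round_with_cells / totals$n_round else NA_real_,
        method4 = if (totals$round_area > 0)
          totals$n_cells_in_round / totals$round_area else NA_real_)
    }

    flags <- character()
    if (totals$n_round < config$min_round_tubules) {
      flags <- c(flags, "few_round_tubules")
    }
    if (totals$total_area < min_area_for(config, drow$tissue_type)) {
      flags <- c(flags, "small_total_area")
    }

    data.frame(sample_id = sid,
               subject_id = drow$subject_id,
               condition = drow$condition,
               tissue_type = drow$tissue_type,
               n_sections = nrow(s),
               n_round_total = totals$n_round,
               total_tubular_area_mm2 = totals$total_area,
               n_cells_total = totals$n_cells_total,
               method1 = unname(mvals[["method1"]]),
               method2 = unname(mvals[["method2"]]),
               method3 = unname(mvals[["method3"]]),
               method4 = unname(mvals[["method4"]]),
               qc_flags = paste(flags, collapse = ";"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sample_metrics", "data.frame")
  out
}

#' Quantify a set of sections end to end
#'
#' Convenience driver used by the pipeline and the simulator-based tests:
#' runs per-tubule feature extraction and section metrics for every section,
#' then aggregates to sample level.
#'
#' @param sections List of [section_annotation()] objects.
#' @param design A [study_design()].
#' @param config A [quant_config()].
#' @return List with `section_metrics` and `sample_metrics` data frames.
#' @export
quantify_sections <- function(sections, design, config = quant_config()) {
  design <- study_design(design)
  tt <- stats::setNames(design$tissue_type, design$sample_id)
  sm <- lapply(sections, function(sec) {
    feats <- compute_tubule_features(sec, config)
    tissue <- if (sec$sample_id %in% names(tt)) tt[[sec$sample_id]] else NULL
    compute_section_metrics(feats, config, tissue_type = tissue)
  })
  section_metrics <- do.call(rbind, sm)
  rownames(section_metrics) <- NULL
  list(section_metrics = section_metrics,
       sample_metrics = aggregate_by_sample(section_metrics, design, config))
}
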