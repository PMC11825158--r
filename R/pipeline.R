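# Run manifest: JSON record written next to every output set, sufficient to
# re-run the command (config snapshot, inputs with checksums, seed, version).
write_manifest <- function(out_dir, command, config, inputs = character(),
                           seed = NULL) {
  inputs <- as.character(inputs)
  manifest <- list(
    command = command,
    tool = "tubulequant",
    version = as.character(utils::packageVersion("tubulequant")),
    seed = seed,
    config = unclass(config),
    inputs = if (length(inputs)) {
      data.frame(path = basename(inputs),
                 md5 = unname(tools::md5sum(inputs)))
    } else list(),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

ensure_dir <- function(d) {
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

#' Simulate a study and write it to disk
#'
#' Writes one GeoJSON file per section, the study design CSV, the
#' ground-truth tables, and a run manifest.
#'
#' @param out_dir Output directory (created if needed).
#' @param preset Preset name for [sim_preset()], or `NULL` to use the
#'   explicit arguments.
#' @param config,subjects,conditions,sections_per_sample,tissue_type Used
#'   when `preset` is `NULL`; see [simulate_study()].
#' @param seed Integer study seed.
#' @return Invisibly, the simulated study object with an added
#'   `section_files` element.
#' @export
run_simulate <- function(out_dir, preset = "fetal_chemo", seed = 1,
                         config = NULL, subjects = NULL, conditions = NULL,
                         sections_per_sample = NULL, tissue_type = NULL) {
  if (!is.null(preset)) {
    ps <- sim_preset(preset)
    config <- config %||% ps$config
    subjects <- subjects %||% ps$subjects
    conditions <- conditions %||% ps$conditions
    sections_per_sample <- sections_per_sample %||% ps$sections_per_sample
    tissue_type <- tissue_type %||% ps$tissue_type
  }
  study <- simulate_study(config, subjects = subjects,
                          conditions = conditions,
                          sections_per_sample = sections_per_sample,
                          seed = seed, tissue_type = tissue_type)
  ensure_dir(out_dir)
  sec_dir <- ensure_dir(file.path(out_dir, "sections"))
  files <- vapply(study$sections, function(sec) {
    f <- file.path(sec_dir, paste0(sec$section_id, ".geojson"))
    write_section_geojson(sec, f)
    f
  }, character(1L))
  utils::write.csv(study$design, file.path(out_dir, "design.csv"),
                   row.names = FALSE, quote = FALSE)
  ts <- study$truth$samples
  ts$subject_multiplier <- fmt_num(ts$subject_multiplier)
  ts$true_density <- fmt_num(ts$true_density)
  utils::write.csv(ts, file.path(out_dir, "truth_samples.csv"),
                   row.names = FALSE, quote = FALSE)
  tt <- study$truth$tubules
  for (cn in c("semi_major", "semi_minor", "axis_ratio", "area_mm2",
               "expected_cells")) tt[[cn]] <- fmt_num(tt[[cn]])
  utils::write.csv(tt, file.path(out_dir, "truth_tubules.csv"),
                   row.names = FALSE, quote = FALSE)
  write_manifest(out_dir, "simulate", config, inputs = character(), seed = seed)
  study$section_files <- files
  invisible(study)
}

#' Quantify annotated sections from disk
#'
#' Runs the full reader -> geometry -> metrics -> aggregation chain over a
#' set of GeoJSON section files, writing section- and sample-level metrics
#' CSVs and a manifest. Any stage failure aborts with the offending file
#' named.
#'
#' @param section_files Character vector of GeoJSON paths, or a directory
#'   containing `*.geojson`.
#' @param design_file Study design CSV path.
#' @param out_dir Output directory.
#' @param config A [quant_config()].
#' @param scale_mm_per_unit Coordinate scale applied at read time.
#' @return Invisibly, list with `section_metrics` and `sample_metrics`.
#' @export
run_quantify <- function(section_files, design_file, out_dir,
                         config = quant_config(), scale_mm_per_unit = 1) {
  if (length(section_files) == 1L && dir.exists(section_files)) {
    section_files <- sort(list.files(section_files, pattern = "\\.geojson$",
                                     full.names = TRUE), method = "radix")
  }
  if (!length(section_files)) stop_data("no section files to quantify")
  design <- read_design(design_file)
  sections <- lapply(section_files, function(f) {
    tryCatch(read_section_geojson(f, scale_mm_per_unit = scale_mm_per_unit),
             error = function(e) {
               stop_data("failed to read section file '", f, "': ",
                         conditionMessage(e))
             })
  })
  res <- quantify_sections(sections, design, config)
  ensure_dir(out_dir)
  write_metrics_table(res$section_metrics,
                      file.path(out_dir, "section_metrics.csv"))
  write_metrics_table(res$sample_metrics,
                      file.path(out_dir, "sample_metrics.csv"))
  write_manifest(out_dir, "quantify", config,
                 inputs = c(section_files, design_file))
  invisible(res)
}

#' Compare experimental groups for every metric
#'
#' Runs [compare_groups()] for each of the four quantification metrics on a
#' sample-level metrics table, serialising the branch taken, group
#' summaries, omnibus p-values, and the pairwise adjusted-p table.
#'
#' @param sample_metrics Sample-level metrics data frame or path to the CSV
#'   written by [run_quantify()].
#' @param out_dir Output directory.
#' @param config A [quant_config()].
#' @param metrics Which metric columns to compare.
#' @return Invisibly, a named list of `comparison_result` objects.
#' @export
run_compare <- function(sample_metrics, out_dir, config = quant_config(),
                        metrics = METRIC_NAMES) {
  if (is.character(sample_metrics)) {
    sample_metrics <- read_metrics_table(sample_metrics)
  }
  if (length(unique(sample_metrics$condition)) < 2L) {
    stop_analysis("group comparison needs >= 2 conditions")
  }
  results <- list()
  pw_rows <- list()
  om_rows <- list()
  for (m in metrics) {
    res <- compare_groups(sample_metrics, m, config)
    results[[m]] <- res
    om_rows[[m]] <- data.frame(metric = m, test_used = res$test_used,
                               omnibus_p = res$omnibus_p)
    pw <- res$pairwise
    pw$metric <- m
    pw$test_used <- res$test_used
    pw_rows[[m]] <- pw
  }
  ensure_dir(out_dir)
  om <- do.call(rbind, om_rows)
  om$omnibus_p <- fmt_num(om$omnibus_p)
  utils::write.csv(om, file.path(out_dir, "comparisons_omnibus.csv"),
                   row.names = FALSE, quote = FALSE)
  pw <- do.call(rbind, pw_rows)
  rownames(pw) <- NULL
  first <- c("metric", "test_used", "group1", "group2")
  pw <- pw[c(first, setdiff(names(pw), first))]
  for (cn in names(pw)) if (is.numeric(pw[[cn]])) pw[[cn]] <- fmt_num(pw[[cn]])
  utils::write.csv(pw, file.path(out_dir, "comparisons_pairwise.csv"),
                   row.names = FALSE, quote = FALSE)
  write_manifest(out_dir, "compare", config)
  invisible(results)
}

#' Method-agreement correlation analysis
#'
#' Runs [correlate_methods()] (Methods 2-4 against Method 1, overall and
#' stratified by round-tubule count) and writes the nine-row correlation
#' table plus per-pair scatter data with the fit-line parameters.
#'
#' @inheritParams run_compare
#' @param threshold Round-tubule count splitting the strata (default 25).
#' @return Invisibly, the correlation results data frame.
#' @export
run_correlate <- function(sample_metrics, out_dir, config = quant_config(),
                          threshold = 25) {
  if (is.character(sample_metrics)) {
    sample_metrics <- read_metrics_table(sample_metrics)
  }
  if (sum(!is.na(sample_metrics$method1)) < 3L) {
    stop_analysis("correlation needs Method 1 defined for >= 3 samples")
  }
  res <- correlate_methods(sample_metrics, threshold = threshold,
                           config = config)
  if (all(is.na(res$r))) stop_analysis("all correlation strata undefined")
  ensure_dir(out_dir)
  out <- res
  for (cn in c("r", "p", "slope", "intercept")) out[[cn]] <- fmt_num(out[[cn]])
  utils::write.csv(out, file.path(out_dir, "correlations.csv"),
                   row.names = FALSE, quote = FALSE)
  scatter <- sample_metrics[c("sample_id", "subject_id", "condition",
                              "n_round_total", METRIC_NAMES)]
  for (cn in METRIC_NAMES) scatter[[cn]] <- fmt_num(scatter[[cn]])
  utils::write.csv(scatter, file.path(out_dir, "scatter_data.csv"),
                   row.names = FALSE, quote = FALSE)
  write_manifest(out_dir, "correlate", config)
  invisible(res)
}
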