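#' @keywords internal
"_PACKAGE"

GERM_CELL_MARKERS <- c("AP2G", "MAGEA4")

# Coerce to an n x 2 coordinate matrix (mm). Columns x, y; y increases
# downward as in image exports. No pixel-grid semantics.
as_polygon <- function(p) {
  m <- as.matrix(p)
  if (is.data.frame(p)) m <- cbind(p[[1]], p[[2]])
  if (!is.numeric(m) || ncol(m) != 2L) {
    stop_geometry("a polygon must be an n x 2 numeric matrix of vertices")
  }
  storage.mode(m) <- "double"
  # drop an explicitly closed final vertex (first == last)
  n <- nrow(m)
  if (n >= 2L && all(m[n, ] == m[1L, ])) m <- m[-n, , drop = FALSE]
  if (nrow(m) < 3L) stop_geometry("a polygon needs at least 3 distinct vertices")
  if (!all(is.finite(m))) stop_geometry("polygon vertices must be finite")
  colnames(m) <- c("x", "y")
  m
}

#' Construct a section annotation
#'
#' One annotated tissue section: the testicular region of interest (ROI)
#' boundary, the outlined tubule cross-sections, and the clicked germ-cell
#' marks. All coordinates are multiplied by `scale_mm_per_unit` at
#' construction, so downstream geometry is always in mm.
#'
#' @param section_id,sample_id Opaque identifier strings.
#' @param roi Polygon (n x 2 matrix, mm after scaling) bounding the region of
#'   interest.
#' @param tubules List of tubule annotations; each is a list with elements
#'   `tubule_id` (unique string), `outline` (polygon), and optional
#'   `intact_flag` (logical; annotator's basement-membrane call, `NA` when
#'   not provided).
#' @param cells Data frame with columns `cell_id`, `marker` (one of `"AP2G"`
#'   for gonocytes, `"MAGEA4"` for (pre)spermatogonia), `x`, `y`.
#' @param scale_mm_per_unit Positive factor converting input coordinate units
#'   to mm (e.g. the pixel size of the original export).
#'
#' @return An object of class `section_annotation`.
#' @export
section_annotation <- function(section_id, sample_id, roi, tubules, cells,
                               scale_mm_per_unit = 1) {
  if (!is.numeric(scale_mm_per_unit) || length(scale_mm_per_unit) != 1L ||
      !is.finite(scale_mm_per_unit) || scale_mm_per_unit <= 0) {
    stop_config("scale_mm_per_unit must be a single positive number")
  }
  s <- scale_mm_per_unit
  roi <- as_polygon(roi) * s

  if (length(tubules) == 0L) {
    stop_data("section '", section_id, "' contains no tubule annotations")
  }
  tubules <- lapply(tubules, function(tb) {
    if (is.null(tb$tubule_id) || !nzchar(tb$tubule_id)) {
      stop_data("every tubule needs a non-empty tubule_id")
    }
    list(tubule_id = as.character(tb$tubule_id),
         outline = as_polygon(tb$outline) * s,
         intact_flag = if (is.null(tb$intact_flag)) NA else as.logical(tb$intact_flag))
  })
  ids <- vapply(tubules, `[[`, "", "tubule_id")
  if (anyDuplicated(ids)) {
    stop_data("duplicate tubule_id within section '", section_id, "': ",
              paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(tubules) <- ids

  if (is.null(cells) || nrow(as.data.frame(cells)) == 0L) {
    cells <- data.frame(cell_id = character(), marker = character(),
                        x = double(), y = double())
  } else {
    cells <- as.data.frame(cells)
    need <- c("cell_id", "marker", "x", "y")
    miss <- setdiff(need, names(cells))
    if (length(miss)) stop_data("cell table lacks column(s): ",
                                paste(miss, collapse = ", "))
    cells <- cells[need]
    cells$cell_id <- as.character(cells$cell_id)
    cells$marker <- as.character(cells$marker)
    bad <- !(cells$marker %in% GERM_CELL_MARKERS)
    if (any(bad)) {
      stop_data("unknown germ-cell marker '", cells$marker[which(bad)[1L]],
                "' in cell '", cells$cell_id[which(bad)[1L]],
                "' (expected AP2G or MAGEA4)")
    }
    if (anyDuplicated(cells$cell_id)) {
      stop_data("duplicate cell_id within section '", section_id, "'")
    }
    cells$x <- as.double(cells$x) * s
    cells$y <- as.double(cells$y) * s
    if (!all(is.finite(cells$x)) || !all(is.finite(cells$y))) {
      stop_data("cell coordinates must be finite")
    }
    rownames(cells) <- NULL
  }

  obj <- structure(
    list(section_id = as.character(section_id),
         sample_id = as.character(sample_id),
         roi = roi, tubules = tubules, cells = cells,
         scale_mm_per_unit = s),
    class = "section_annotation"
  )
  validate_section(obj)
  obj
}

# Containment check: warn (not error) when annotations stray outside the ROI,
# so noisy real exports still load; simulated data satisfies this exactly.
validate_section <- function(section) {
  roi <- section$roi
  n_out_vert <- 0L
  for (tb in section$tubules) {
    inside <- points_in_polygon(tb$outline[, 1L], tb$outline[, 2L], roi)
    n_out_vert <- n_out_vert + sum(!inside)
  }
  n_out_cell <- 0L
  if (nrow(section$cells)) {
    inside <- points_in_polygon(section$cells$x, section$cells$y, roi)
    n_out_cell <- sum(!inside)
  }
  if (n_out_vert + n_out_cell > 0L) {
    warning("section '", section$section_id, "': ", n_out_vert,
            " tubule vertices and ", n_out_cell,
            " cell marks lie outside the ROI", call. = FALSE)
  }
  invisible(section)
}

#' @export
print.section_annotation <- function(x, ...) {
  cat("<section_annotation> ", x$section_id, " (sample ", x$sample_id, ")\n",
      "  tubules: ", length(x$tubules),
      "  cells: ", nrow(x$cells), "\n", sep = "")
  invisible(x)
}

#' Construct / validate a study design table
#'
#' Maps samples to subjects, experimental conditions and tissue type.
#'
#' @param df Data frame with columns `sample_id`, `subject_id`, `condition`,
#'   `tissue_type` (one of `"fetal"`, `"prepubertal"`).
#' @return The validated data frame with class `study_design`.
#' @export
study_design <- function(df) {
  df <- as.data.frame(df)
  need <- c("sample_id", "subject_id", "condition", "tissue_type")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_data("study design lacks column(s): ",
                              paste(miss, collapse = ", "))
  df <- df[need]
  for (cn in need) df[[cn]] <- as.character(df[[cn]])
  if (anyDuplicated(df$sample_id)) {
    stop_data("duplicate sample_id in study design: ",
              paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  bad <- !(df$tissue_type %in% c("fetal", "prepubertal"))
  if (any(bad)) {
    stop_data("tissue_type must be 'fetal' or 'prepubertal'; got '",
              df$tissue_type[which(bad)[1L]], "'")
  }
  rownames(df) <- NULL
  class(df) <- c("study_design", "data.frame")
  df
}

# stable, locale-independent ordering for opaque identifier strings
id_order <- function(ids) order(ids, method = "radix")
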