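#' Default classification-label mapping
#'
#' Maps the classification labels commonly found in annotation-tool exports
#' to pipeline roles: `roi`, `tubule`, `cell:AP2G`, `cell:MAGEA4`.
#'
#' @return Named character vector (names = export labels, values = roles).
#' @export
default_label_map <- function() {
  c("ROI" = "roi", "Region" = "roi",
    "Tubule" = "tubule", "tubule" = "tubule",
    "AP2G" = "cell:AP2G", "AP2-gamma" = "cell:AP2G", "AP2y" = "cell:AP2G",
    "MAGEA4" = "cell:MAGEA4", "MAGE-A4" = "cell:MAGEA4")
}

# walk a property path like "classification.name" through nested lists
extract_property <- function(props, path) {
  cur <- props
  for (key in strsplit(path, ".", fixed = TRUE)[[1L]]) {
    if (!is.list(cur) || is.null(cur[[key]])) return(NULL)
    cur <- cur[[key]]
  }
  if (is.character(cur) && length(cur) == 1L) cur else NULL
}

#' Read one section from a GeoJSON annotation export
#'
#' Parses an RFC 7946 FeatureCollection of the kind produced by annotation
#' tools: Polygon features are the region of interest and tubule outlines,
#' Point features are germ-cell marks. The role of each feature is looked up
#' from its classification label via `label_map`; features whose label is not
#' mapped (or whose geometry type is neither Polygon nor Point) are skipped
#' with a message reporting the counts. When the export carries no ROI
#' feature, the convex hull of all tubule vertices substitutes for it (also
#' reported).
#'
#' @param path Path to a GeoJSON file.
#' @param scale_mm_per_unit Positive factor converting export units to mm.
#' @param label_map Named character vector mapping classification labels to
#'   roles (`roi`, `tubule`, `cell:AP2G`, `cell:MAGEA4`).
#' @param property_path Where the classification label lives inside feature
#'   properties (default `"classification.name"`).
#' @param section_id,sample_id Identifiers; default to the top-level
#'   `section_id` / `sample_id` members of the file, then to the file name.
#' @return A [section_annotation()].
#' @export
read_section_geojson <- function(path, scale_mm_per_unit = 1,
                                 label_map = default_label_map(),
                                 property_path = "classification.name",
                                 section_id = NULL, sample_id = NULL) {
  if (!is.numeric(scale_mm_per_unit) || length(scale_mm_per_unit) != 1L ||
      !is.finite(scale_mm_per_unit) || scale_mm_per_unit <= 0) {
    stop_config("scale_mm_per_unit must be a single positive number")
  }
  gj <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop_data("malformed GeoJSON in '", path, "': ",
                                  conditionMessage(e)))
  if (!identical(gj$type, "FeatureCollection") || is.null(gj$features)) {
    stop_data("'", path, "' is not a GeoJSON FeatureCollection")
  }

  roi <- NULL
  tubules <- list()
  cells <- list()
  skipped <- 0L

  for (i in seq_along(gj$features)) {
    ft <- gj$features[[i]]
    if (is.null(ft$geometry) || is.null(ft$geometry$type)) {
      stop_data("feature ", i, " of '", path, "' has no geometry")
    }
    gtype <- ft$geometry$type
    label <- extract_property(ft$properties, property_path)
    role <- if (!is.null(label) && label %in% names(label_map)) {
      unname(label_map[[label]])
    } else NULL

    if (is.null(role) || !(gtype %in% c("Polygon", "Point"))) {
      skipped <- skipped + 1L
      next
    }
    if (gtype == "Polygon") {
      ring <- ft$geometry$coordinates[[1L]]
      if (is.null(ring) || length(ring) < 3L) {
        stop_data("feature ", i, " of '", path, "' has an invalid Polygon ring")
      }
      coords <- do.call(rbind, lapply(ring, function(v) {
        as.double(unlist(v)[1:2])
      }))
      if (identical(role, "roi")) {
        roi <- coords
      } else if (identical(role, "tubule")) {
        oid <- ft$properties$object_id %||% ft$id %||%
          sprintf("tubule_%03d", length(tubules) + 1L)
        tubules[[length(tubules) + 1L]] <- list(
          tubule_id = as.character(oid),
          outline = coords,
          intact_flag = if (is.null(ft$properties$intact)) NA
                        else as.logical(ft$properties$intact))
      } else {
        skipped <- skipped + 1L
      }
    } else { # Point
      if (!startsWith(role, "cell:")) { skipped <- skipped + 1L; next }
      xy <- as.double(unlist(ft$geometry$coordinates)[1:2])
      cid <- ft$properties$object_id %||% ft$id %||%
        sprintf("cell_%04d", length(cells) + 1L)
      cells[[length(cells) + 1L]] <- data.frame(
        cell_id = as.character(cid),
        marker = sub("^cell:", "", role),
        x = xy[1L], y = xy[2L])
    }
  }

  if (skipped > 0L) {
    message("read_section_geojson: skipped ", skipped,
            " feature(s) with unmapped labels or unsupported geometry in '",
            basename(path), "'")
  }
  if (length(tubules) == 0L) {
    stop_data("'", path, "' contains no tubule features")
  }
  if (is.null(roi)) {
    allv <- do.call(rbind, lapply(tubules, `[[`, "outline"))
    roi <- allv[grDevices::chull(allv), , drop = FALSE]
    message("read_section_geojson: no ROI feature in '", basename(path),
            "'; using convex hull of all tubule vertices")
  }

  base <- sub("\\.[^.]*$", "", basename(path))
  section_annotation(
    section_id = section_id %||% gj$section_id %||% base,
    sample_id = sample_id %||% gj$sample_id %||% base,
    roi = roi, tubules = tubules,
    cells = if (length(cells)) do.call(rbind, cells) else NULL,
    scale_mm_per_unit = scale_mm_per_unit)
}

#' Read one section from plain CSV tables
#'
#' Table equivalent of the GeoJSON reader: the polygon table holds one vertex
#' per row (`section_id, object_id, role, vertex_index, x, y`, with role
#' `roi` or `tubule` and an optional `intact` column), the point table one
#' germ-cell mark per row (`section_id, cell_id, marker, x, y`). Vertices are
#' ordered by `vertex_index`, so row order does not matter.
#'
#' @param polygon_table,point_table CSV file paths.
#' @param scale_mm_per_unit Positive factor converting units to mm.
#' @param sample_id Optional sample identifier (defaults to the section id).
#' @return A [section_annotation()].
#' @export
read_section_tables <- function(polygon_table, point_table,
                                scale_mm_per_unit = 1, sample_id = NULL) {
  pol <- utils::read.csv(polygon_table, stringsAsFactors = FALSE)
  need <- c("section_id", "object_id", "role", "vertex_index", "x", "y")
  miss <- setdiff(need, names(pol))
  if (length(miss)) {
    stop_data("polygon table lacks column(s): ", paste(miss, collapse = ", "))
  }
  pts <- utils::read.csv(point_table, stringsAsFactors = FALSE)
  need_p <- c("section_id", "cell_id", "marker", "x", "y")
  miss <- setdiff(need_p, names(pts))
  if (length(miss)) {
    stop_data("point table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(pol[c("object_id", "vertex_index")])) {
    stop_data("duplicate (object_id, vertex_index) pair in polygon table")
  }
  bad <- which(!(pts$marker %in% GERM_CELL_MARKERS))
  if (length(bad)) {
    stop_data("point table row ", bad[1L], ": unknown marker '",
              pts$marker[bad[1L]], "'")
  }

  sec_id <- unique(pol$section_id)
  if (length(sec_id) != 1L) {
    stop_data("polygon table must describe exactly one section; found: ",
              paste(sec_id, collapse = ", "))
  }

  roi <- NULL
  tubules <- list()
  for (oid in unique(pol$object_id)) {
    rows <- pol[pol$object_id == oid, , drop = FALSE]
    rows <- rows[order(rows$vertex_index), , drop = FALSE]
    coords <- cbind(rows$x, rows$y)
    role <- unique(rows$role)
    if (length(role) != 1L) {
      stop_data("object '", oid, "' has inconsistent roles")
    }
    if (role == "roi") {
      roi <- coords
    } else if (role == "tubule") {
      iflag <- if ("intact" %in% names(rows)) rows$intact[1L] else NA
      tubules[[length(tubules) + 1L]] <- list(
        tubule_id = as.character(oid), outline = coords,
        intact_flag = if (is.na(iflag) || iflag == "") NA else as.logical(iflag))
    } else {
      stop_data("object '", oid, "': unknown role '", role, "'")
    }
  }
  if (length(tubules) == 0L) {
    stop_data("polygon table contains no tubule objects")
  }
  if (is.null(roi)) {
    allv <- do.call(rbind, lapply(tubules, `[[`, "outline"))
    roi <- allv[grDevices::chull(allv), , drop = FALSE]
    message("read_section_tables: no roi object; using convex hull of ",
            "all tubule vertices")
  }

  cells <- if (nrow(pts)) {
    data.frame(cell_id = as.character(pts$cell_id), marker = pts$marker,
               x = pts$x, y = pts$y)
  } else NULL

  section_annotation(section_id = sec_id,
                     sample_id = sample_id %||% sec_id,
                     roi = roi, tubules = tubules, cells = cells,
                     scale_mm_per_unit = scale_mm_per_unit)
}

#' Read a study design CSV
#'
#' @param path CSV with header `sample_id, subject_id, condition,
#'   tissue_type`.
#' @return A validated [study_design()].
#' @export
read_design <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  study_design(df)
}

# format a numeric for CSV output: 12 significant digits, plain decimal
fmt_num <- function(x) {
  out <- ifelse(is.na(x), "", sprintf("%.12g", x))
  out
}

#' Write a metrics table to CSV
#'
#' Writes section- or sample-level metrics with a stable column order.
#' Missing metric values become empty fields; numeric values are written as
#' decimal strings with 12 significant digits so a write/read round trip
#' reproduces them exactly at that precision.
#'
#' @param records Data frame of section or sample metrics (one level only).
#' @param path Output CSV path.
#' @export
write_metrics_table <- function(records, path) {
  df <- as.data.frame(records)
  has_section <- "section_id" %in% names(df)
  has_sample_only <- !has_section && "sample_id" %in% names(df)
  if (!has_section && !has_sample_only) {
    stop_config("records must be section-level or sample-level metrics")
  }
  out <- df
  for (cn in names(out)) {
    if (is.numeric(out[[cn]]) && !is.integer(out[[cn]])) {
      out[[cn]] <- fmt_num(out[[cn]])
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read back a metrics table written by [write_metrics_table()]
#' @param path CSV path.
#' @return Data frame with numeric metric columns restored (`NA` for empty).
#' @export
read_metrics_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  char_cols <- c("section_id", "sample_id", "subject_id", "condition",
                 "tissue_type", "qc_flags")
  for (cn in names(df)) {
    if (cn %in% char_cols) {
      df[[cn]] <- as.character(ifelse(is.na(df[[cn]]), "", df[[cn]]))
    } else {
      df[[cn]] <- as.numeric(df[[cn]])
    }
  }
  df
}

#' Write a section annotation as GeoJSON
#'
#' Inverse of [read_section_geojson()] (coordinates in mm, scale 1): the ROI
#' and tubule outlines become Polygon features and germ-cell marks Point
#' features, each carrying its classification label under
#' `classification.name`.
#'
#' @param section A [section_annotation()].
#' @param path Output path.
#' @export
write_section_geojson <- function(section, path) {
  close_ring <- function(m) {
    m <- rbind(m, m[1L, ])
    lapply(seq_len(nrow(m)), function(i) c(m[i, 1L], m[i, 2L]))
  }
  feats <- list()
  feats[[1L]] <- list(
    type = "Feature",
    geometry = list(type = "Polygon", coordinates = list(close_ring(section$roi))),
    properties = list(classification = list(name = "ROI")))
  for (tb in section$tubules) {
    props <- list(classification = list(name = "Tubule"),
                  object_id = tb$tubule_id)
    if (!is.na(tb$intact_flag)) props$intact <- tb$intact_flag
    feats[[length(feats) + 1L]] <- list(
      type = "Feature",
      geometry = list(type = "Polygon",
                      coordinates = list(close_ring(tb$outline))),
      properties = props)
  }
  if (nrow(section$cells)) {
    for (i in seq_len(nrow(section$cells))) {
      feats[[length(feats) + 1L]] <- list(
        type = "Feature",
        geometry = list(type = "Point",
                        coordinates = c(section$cells$x[i], section$cells$y[i])),
        properties = list(classification = list(name = section$cells$marker[i]),
                          object_id = section$cells$cell_id[i]))
    }
  }
  obj <- list(type = "FeatureCollection",
              section_id = section$section_id,
              sample_id = section$sample_id,
              features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
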