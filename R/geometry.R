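#' Polygon area by the shoelace formula
#'
#' Area of a simple polygon, independent of vertex orientation.
#'
#' @param p Polygon: n x 2 numeric matrix of vertices (mm); closure between
#'   the last and first vertex is implicit.
#' @return Area in mm2 (positive).
#' @export
polygon_area <- function(p) {
  p <- as_polygon(p)
  n <- nrow(p)
  j <- c(n, seq_len(n - 1L))
  a <- 0.5 * abs(sum(p[j, 1L] * p[, 2L] - p[, 1L] * p[j, 2L]))
  ext <- max(abs(p)) ^ 2
  if (a <= .Machine$double.eps * max(ext, 1)) {
    stop_geometry("degenerate (zero-area) polygon")
  }
  a
}

#' Longest and shortest Feret diameters of a polygon
#'
#' Formalises caliper measurement of a tubule outline: the longest diameter is
#' the maximum Feret diameter (largest distance between any two vertices of
#' the convex hull); the shortest diameter is the minimum Feret diameter
#' (minimum width over all directions), computed exactly on the convex hull by
#' rotating calipers over hull edges. Concavities of the outline do not enter:
#' manual diameters span the shape, not its indentations.
#'
#' @inheritParams polygon_area
#' @return Named numeric vector `c(long = , short = )` in mm.
#' @export
feret_diameters <- function(p) {
  p <- as_polygon(p)
  h <- grDevices::chull(p)
  if (length(h) < 3L) stop_geometry("degenerate polygon: convex hull has < 3 vertices")
  hp <- p[h, , drop = FALSE]
  nh <- nrow(hp)

  # longest: exhaustive over hull vertex pairs (the global max is attained here)
  dx <- outer(hp[, 1L], hp[, 1L], "-")
  dy <- outer(hp[, 2L], hp[, 2L], "-")
  dmax <- sqrt(max(dx * dx + dy * dy))

  # shortest: min over hull edges of the farthest vertex from the edge line
  nxt <- c(seq_len(nh)[-1L], 1L)
  ex <- hp[nxt, 1L] - hp[, 1L]
  ey <- hp[nxt, 2L] - hp[, 2L]
  len <- sqrt(ex * ex + ey * ey)
  wmin <- Inf
  for (i in which(len > 0)) {
    d <- abs((hp[, 1L] - hp[i, 1L]) * ey[i] - (hp[, 2L] - hp[i, 2L]) * ex[i]) / len[i]
    w <- max(d)
    if (w < wmin) wmin <- w
  }
  if (!is.finite(wmin) || wmin <= 0) stop_geometry("degenerate polygon: zero width")
  c(long = dmax, short = wmin)
}

#' Classify a tubule cross-section as round
#'
#' A tubule is round when its longest/shortest diameter ratio is strictly
#' below the threshold; a ratio exactly at the threshold is not round.
#'
#' @param ratio Diameter ratio(s), >= 1.
#' @param threshold Roundness threshold (> 1), default 1.5.
#' @return Logical vector.
#' @export
classify_round <- function(ratio, threshold = 1.5) {
  stopifnot(is.numeric(ratio), is.numeric(threshold), threshold > 1)
  ratio < threshold
}

#' Point-in-polygon test (closed-region convention)
#'
#' Even-odd (ray casting) rule for interiors; points on the boundary count as
#' inside, because annotators click nuclei straddling the outline.
#'
#' @param px,py Numeric vectors of point coordinates.
#' @param poly Polygon (n x 2 matrix).
#' @return Logical vector, one element per point.
#' @export
points_in_polygon <- function(px, py, poly) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  np <- length(px)
  if (np == 0L) return(logical(0))
  x2 <- poly[, 1L]; y2 <- poly[, 2L]
  x1 <- x2[c(n, seq_len(n - 1L))]; y1 <- y2[c(n, seq_len(n - 1L))]
  tol <- 1e-12 * max(1, max(abs(poly)))

  # edge-wise quantities as np x n matrices (edges vary along columns)
  PX <- matrix(px, np, n); PY <- matrix(py, np, n)
  X1 <- matrix(x1, np, n, byrow = TRUE); Y1 <- matrix(y1, np, n, byrow = TRUE)
  X2 <- matrix(x2, np, n, byrow = TRUE); Y2 <- matrix(y2, np, n, byrow = TRUE)

  # boundary: zero cross product and inside the segment's bounding box
  cr <- (X2 - X1) * (PY - Y1) - (Y2 - Y1) * (PX - X1)
  etol <- tol * (abs(X2 - X1) + abs(Y2 - Y1) + 1)
  on_seg <- abs(cr) <= etol &
    PX >= pmin(X1, X2) - tol & PX <= pmax(X1, X2) + tol &
    PY >= pmin(Y1, Y2) - tol & PY <= pmax(Y1, Y2) + tol
  on_edge <- rowSums(on_seg) > 0L

  # even-odd crossing rule
  crosses <- (Y1 > PY) != (Y2 > PY)
  dy <- Y2 - Y1
  dy[dy == 0] <- 1  # edges that cannot cross; masked by `crosses`
  xi <- X1 + (PY - Y1) * (X2 - X1) / dy
  inside <- rowSums(crosses & (PX < xi)) %% 2L == 1L

  inside | on_edge
}

#' @rdname points_in_polygon
#' @param pt Length-2 numeric vector (x, y) for the single-point form.
#' @export
point_in_polygon <- function(pt, poly) {
  points_in_polygon(pt[1L], pt[2L], poly)
}

# minimum distance from points to a polygon's boundary segments
dist_to_boundary <- function(px, py, poly) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  nxt <- c(seq_len(n)[-1L], 1L)
  d2 <- rep(Inf, length(px))
  for (i in seq_len(n)) {
    x1 <- poly[i, 1L]; y1 <- poly[i, 2L]
    ex <- poly[nxt[i], 1L] - x1; ey <- poly[nxt[i], 2L] - y1
    L2 <- ex * ex + ey * ey
    t <- if (L2 > 0) pmin(1, pmax(0, ((px - x1) * ex + (py - y1) * ey) / L2)) else 0
    ddx <- px - (x1 + t * ex); ddy <- py - (y1 + t * ey)
    d2 <- pmin(d2, ddx * ddx + ddy * ddy)
  }
  sqrt(d2)
}

#' Flag intact (non-edge-clipped) tubules
#'
#' A tubule whose basement membrane runs off the section edge must be
#' excluded from quantification. When the annotator supplied an explicit
#' intact flag it wins; otherwise a tubule is not intact if any outline
#' vertex lies outside the ROI or within `edge_tolerance` of the ROI
#' boundary.
#'
#' @param section A [section_annotation()].
#' @param edge_tolerance Distance in mm; default 0.002.
#' @return Named logical vector, one element per tubule.
#' @export
flag_intact_tubules <- function(section, edge_tolerance = 0.002) {
  roi <- section$roi
  out <- vapply(section$tubules, function(tb) {
    if (!is.na(tb$intact_flag)) return(as.logical(tb$intact_flag))
    vx <- tb$outline[, 1L]; vy <- tb$outline[, 2L]
    if (!all(points_in_polygon(vx, vy, roi))) return(FALSE)
    all(dist_to_boundary(vx, vy, roi) > edge_tolerance)
  }, logical(1L))
  names(out) <- vapply(section$tubules, `[[`, "", "tubule_id")
  out
}

#' Assign germ-cell marks to tubules
#'
#' Each cell mark is assigned to the first tubule (ascending `tubule_id`)
#' whose outline contains it; boundary contact counts as containment. Cells
#' contained in no tubule (interstitial marks) are returned unassigned and
#' never enter any metric. Overlapping tubule annotations trigger a warning;
#' the ascending-id tie-break keeps the assignment deterministic.
#'
#' @param section A [section_annotation()].
#' @return List with `assignment` (character vector parallel to
#'   `section$cells`, the containing `tubule_id` or `NA`), and
#'   `unassigned` (character vector of unassigned `cell_id`s).
#' @export
assign_cells <- function(section) {
  cells <- section$cells
  nc <- nrow(cells)
  assignment <- rep(NA_character_, nc)
  if (nc == 0L) {
    return(list(assignment = assignment, unassigned = character()))
  }
  ids <- vapply(section$tubules, `[[`, "", "tubule_id")
  hits <- integer(nc)
  for (k in id_order(ids)) {
    tb <- section$tubules[[k]]
    bb <- tb$outline
    cand <- which(cells$x >= min(bb[, 1L]) & cells$x <= max(bb[, 1L]) &
                  cells$y >= min(bb[, 2L]) & cells$y <= max(bb[, 2L]))
    if (!length(cand)) next
    inside <- points_in_polygon(cells$x[cand], cells$y[cand], tb$outline)
    win <- cand[inside]
    hits[win] <- hits[win] + 1L
    take <- win[is.na(assignment[win])]
    assignment[take] <- tb$tubule_id
  }
  if (any(hits > 1L)) {
    warning("section '", section$section_id, "': ", sum(hits > 1L),
            " cell mark(s) fall inside more than one tubule outline ",
            "(overlapping annotations); first-containment by ascending ",
            "tubule_id applied", call. = FALSE)
  }
  list(assignment = assignment,
       unassigned = cells$cell_id[is.na(assignment)])
}

#' Per-tubule shape and count features
#'
#' Combines, for every tubule of a section: polygon area, longest/shortest
#' Feret diameters and their ratio, the round classification, the intactness
#' flag, and the assigned germ-cell counts (total and per marker). Rows are
#' ordered by ascending `tubule_id`.
#'
#' @param section A [section_annotation()].
#' @param config A [quant_config()].
#' @return Data frame with one row per tubule and attributes `section_id`,
#'   `sample_id`.
#' @export
compute_tubule_features <- function(section, config = quant_config()) {
  ids <- vapply(section$tubules, `[[`, "", "tubule_id")
  ord <- id_order(ids)
  intact <- flag_intact_tubules(section, config$edge_tolerance)
  asg <- assign_cells(section)

  counts_total <- integer(length(ids))
  counts_by <- matrix(0L, length(ids), length(GERM_CELL_MARKERS),
                      dimnames = list(ids, GERM_CELL_MARKERS))
  if (nrow(section$cells)) {
    ok <- !is.na(asg$assignment)
    if (any(ok)) {
      tab <- table(factor(asg$assignment[ok], levels = ids),
                   factor(section$cells$marker[ok], levels = GERM_CELL_MARKERS))
      counts_by <- matrix(as.integer(tab), nrow = length(ids),
                          dimnames = dimnames(counts_by))
      counts_total <- as.integer(rowSums(counts_by))
    }
  }

  nt <- length(ord)
  area <- dlong <- dshort <- numeric(nt)
  for (m in seq_len(nt)) {
    tb <- section$tubules[[ord[m]]]
    area[m] <- tryCatch(polygon_area(tb$outline), tq_geometry_error = function(e) {
      stop_geometry("tubule '", tb$tubule_id, "': ", conditionMessage(e))
    })
    fd <- tryCatch(feret_diameters(tb$outline), tq_geometry_error = function(e) {
      stop_geometry("tubule '", tb$tubule_id, "': ", conditionMessage(e))
    })
    dlong[m] <- fd[["long"]]; dshort[m] <- fd[["short"]]
  }
  ratio <- dlong / dshort
  out <- data.frame(tubule_id = ids[ord],
                    area_mm2 = area,
                    diameter_long = dlong,
                    diameter_short = dshort,
                    roundness_ratio = ratio,
                    is_round = classify_round(ratio, config$roundness_threshold),
                    is_intact = unname(intact[ids[ord]]),
                    cell_count_total = counts_total[ord],
                    cell_count_AP2G = counts_by[ord, "AP2G"],
                    cell_count_MAGEA4 = counts_by[ord, "MAGEA4"])
  rownames(out) <- NULL
  attr(out, "section_id") <- section$section_id
  attr(out, "sample_id") <- section$sample_id
  out
}
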