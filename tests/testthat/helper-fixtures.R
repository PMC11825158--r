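# In-code fixtures: small hand-built sections and matched file pairs.

unit_square <- function(side = 1, offset = c(0, 0)) {
  rbind(c(0, 0), c(side, 0), c(side, side), c(0, side)) +
    matrix(offset, 4, 2, byrow = TRUE)
}

# a 10x10 mm ROI with one square tubule and configurable cells
toy_section <- function(cells = data.frame(cell_id = "c1", marker = "MAGEA4",
                                           x = 2.5, y = 2.5),
                        tubules = list(list(tubule_id = "t1",
                                            outline = unit_square(1, c(2, 2)),
                                            intact_flag = NA)),
                        section_id = "toy", sample_id = "toyA") {
  section_annotation(section_id = section_id, sample_id = sample_id,
                     roi = unit_square(10), tubules = tubules, cells = cells,
                     scale_mm_per_unit = 1)
}

toy_design <- function(sample_ids = "toyA", tissue_type = "fetal") {
  study_design(data.frame(sample_id = sample_ids,
                          subject_id = paste0("subj_", seq_along(sample_ids)),
                          condition = "control",
                          tissue_type = tissue_type))
}

# write the same toy content as a GeoJSON file and as CSV tables;
# returns the three paths (golden pair for reader-equivalence tests)
write_golden_pair <- function(dir) {
  gj <- file.path(dir, "sec.geojson")
  sec <- section_annotation(
    section_id = "sec", sample_id = "sec",
    roi = unit_square(10),
    tubules = list(
      list(tubule_id = "tA", outline = unit_square(1, c(1, 1)), intact_flag = NA),
      list(tubule_id = "tB", outline = unit_square(2, c(5, 5)), intact_flag = NA)),
    cells = data.frame(cell_id = c("c1", "c2", "c3"),
                       marker = c("MAGEA4", "MAGEA4", "AP2G"),
                       x = c(1.5, 6, 6.5), y = c(1.5, 6, 6.2)))
  write_section_geojson(sec, gj)

  pol <- do.call(rbind, c(
    list(data.frame(section_id = "sec", object_id = "roi0", role = "roi",
                    vertex_index = 1:4, x = unit_square(10)[, 1],
                    y = unit_square(10)[, 2])),
    lapply(sec$tubules, function(tb) {
      data.frame(section_id = "sec", object_id = tb$tubule_id,
                 role = "tubule", vertex_index = seq_len(nrow(tb$outline)),
                 x = tb$outline[, 1], y = tb$outline[, 2])
    })))
  pts <- data.frame(section_id = "sec", cell_id = sec$cells$cell_id,
                    marker = sec$cells$marker, x = sec$cells$x,
                    y = sec$cells$y)
  pol_f <- file.path(dir, "polygons.csv")
  pts_f <- file.path(dir, "points.csv")
  utils::write.csv(pol, pol_f, row.names = FALSE)
  utils::write.csv(pts, pts_f, row.names = FALSE)
  list(geojson = gj, polygons = pol_f, points = pts_f)
}

# structurally equal section comparison (ignores list ordering details)
expect_sections_equal <- function(a, b) {
  expect_equal(a$section_id, b$section_id)
  expect_equal(length(a$tubules), length(b$tubules))
  for (id in names(a$tubules)) {
    expect_equal(unname(a$tubules[[id]]$outline),
                 unname(b$tubules[[id]]$outline))
  }
  oa <- order(a$cells$cell_id); ob <- order(b$cells$cell_id)
  expect_equal(a$cells[oa, c("marker", "x", "y")],
               b$cells[ob, c("marker", "x", "y")],
               ignore_attr = TRUE)
}

# uniformly rescale every coordinate of a section by s
scale_section <- function(section, s) {
  section_annotation(
    section_id = section$section_id, sample_id = section$sample_id,
    roi = section$roi, tubules = section$tubules, cells = section$cells,
    scale_mm_per_unit = s)
}
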