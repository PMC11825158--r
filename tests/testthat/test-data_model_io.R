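test_that("GeoJSON reader maps features, applies scale, skips unknowns", {
  dir <- withr::local_tempdir()
  gj <- file.path(dir, "s1.geojson")
  feats <- list(
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(list(c(0, 0), c(100, 0),
                                                 c(100, 100), c(0, 100), c(0, 0)))),
         properties = list(classification = list(name = "ROI"))),
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(list(c(10, 10), c(20, 10),
                                                 c(20, 20), c(10, 20)))),
         properties = list(classification = list(name = "Tubule"),
                           object_id = "t1")),
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(list(c(40, 40), c(60, 40),
                                                 c(60, 55), c(40, 55)))),
         properties = list(classification = list(name = "Tubule"),
                           object_id = "t2")),
    list(type = "Feature",
         geometry = list(type = "Point", coordinates = c(15, 15)),
         properties = list(classification = list(name = "MAGE-A4"))),
    list(type = "Feature",
         geometry = list(type = "Point", coordinates = c(45, 45)),
         properties = list(classification = list(name = "MAGE-A4"))),
    list(type = "Feature",
         geometry = list(type = "Point", coordinates = c(50, 50)),
         properties = list(classification = list(name = "MAGE-A4"))))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       gj, auto_unbox = TRUE, digits = NA)

  sec <- read_section_geojson(gj, scale_mm_per_unit = 0.001)
  expect_s3_class(sec, "section_annotation")
  expect_length(sec$tubules, 2)
  expect_equal(nrow(sec$cells), 3)
  expect_true(all(sec$cells$marker == "MAGEA4"))
  expect_equal(sec$tubules[["t1"]]$outline[1, ], c(x = 0.01, y = 0.01))

  # doubling the scale doubles every coordinate exactly
  sec2 <- read_section_geojson(gj, scale_mm_per_unit = 0.002)
  expect_identical(sec2$tubules[["t1"]]$outline, sec$tubules[["t1"]]$outline * 2)
  expect_identical(sec2$cells$x, sec$cells$x * 2)

  # a LineString feature is skipped with a message; the rest still loads
  feats2 <- c(feats, list(list(
    type = "Feature",
    geometry = list(type = "LineString",
                    coordinates = list(c(0, 0), c(5, 5))),
    properties = list(classification = list(name = "Tubule")))))
  gj2 <- file.path(dir, "s2.geojson")
  jsonlite::write_json(list(type = "FeatureCollection", features = feats2),
                       gj2, auto_unbox = TRUE, digits = NA)
  expect_message(sec3 <- read_section_geojson(gj2, 0.001), "skipped 1")
  expect_length(sec3$tubules, 2)
})

test_that("GeoJSON reader errors: malformed file, no tubules, bad scale", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.geojson")
  writeLines("{not json", bad)
  expect_error(read_section_geojson(bad), class = "tq_data_error")

  empty <- file.path(dir, "empty.geojson")
  jsonlite::write_json(list(type = "FeatureCollection", features = list()),
                       empty, auto_unbox = TRUE)
  expect_error(read_section_geojson(empty), class = "tq_data_error")

  expect_error(read_section_geojson(bad, scale_mm_per_unit = 0),
               class = "tq_config_error")
})

test_that("table reader: vertex ordering, marker validation, golden pair", {
  dir <- withr::local_tempdir()
  paths <- write_golden_pair(dir)

  from_gj <- read_section_geojson(paths$geojson)
  from_tab <- read_section_tables(paths$polygons, paths$points)
  expect_sections_equal(from_gj, from_tab)

  # shuffling vertex rows must not change the polygons
  pol <- utils::read.csv(paths$polygons)
  set.seed(1)
  shuf <- file.path(dir, "shuffled.csv")
  utils::write.csv(pol[sample(nrow(pol)), ], shuf, row.names = FALSE)
  from_shuf <- read_section_tables(shuf, paths$points)
  expect_sections_equal(from_tab, from_shuf)

  # unknown marker names the offending row
  pts <- utils::read.csv(paths$points)
  pts$marker[2] <- "FOO"
  badp <- file.path(dir, "badpts.csv")
  utils::write.csv(pts, badp, row.names = FALSE)
  expect_error(read_section_tables(paths$polygons, badp), "row 2",
               class = "tq_data_error")

  # missing column is a schema error
  pol2 <- pol[setdiff(names(pol), "vertex_index")]
  badc <- file.path(dir, "badcol.csv")
  utils::write.csv(pol2, badc, row.names = FALSE)
  expect_error(read_section_tables(badc, paths$points), "vertex_index",
               class = "tq_data_error")

  # duplicated (object_id, vertex_index) is an integrity error
  dup <- rbind(pol, pol[5, ])
  dupf <- file.path(dir, "dup.csv")
  utils::write.csv(dup, dupf, row.names = FALSE)
  expect_error(read_section_tables(dupf, paths$points), "duplicate",
               class = "tq_data_error")
})

test_that("reading with scale s scales lengths by s and areas by s^2", {
  dir <- withr::local_tempdir()
  paths <- write_golden_pair(dir)
  s1 <- read_section_geojson(paths$geojson, scale_mm_per_unit = 1)
  s2 <- read_section_geojson(paths$geojson, scale_mm_per_unit = 2.5)
  f1 <- compute_tubule_features(s1)
  f2 <- compute_tubule_features(s2)
  expect_equal(f2$diameter_long, f1$diameter_long * 2.5, tolerance = 1e-12)
  expect_equal(f2$area_mm2, f1$area_mm2 * 2.5 ^ 2, tolerance = 1e-12)
  expect_equal(f2$roundness_ratio, f1$roundness_ratio, tolerance = 1e-12)
})

test_that("study design validation", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "design.csv")
  d <- expand.grid(subject_id = paste0("s", 1:6),
                   condition = c("control", "cisplatin", "carboplatin"),
                   stringsAsFactors = FALSE)
  d$sample_id <- paste(d$subject_id, d$condition, sep = "_")
  d$tissue_type <- "fetal"
  utils::write.csv(d, f, row.names = FALSE)
  des <- read_design(f)
  expect_s3_class(des, "study_design")
  expect_equal(nrow(des), 18)

  utils::write.csv(rbind(d, d[1, ]), f, row.names = FALSE)
  expect_error(read_design(f), class = "tq_data_error")

  d$tissue_type[3] <- "adult"
  utils::write.csv(d, f, row.names = FALSE)
  expect_error(read_design(f), "adult", class = "tq_data_error")
})

test_that("metrics writer round-trips at 12 significant digits", {
  dir <- withr::local_tempdir()
  sec <- toy_section()
  f <- compute_tubule_features(sec)
  m <- compute_section_metrics(f, tissue_type = "fetal")
  m2 <- m; m2$section_id <- "toy2"
  # make methods 2-4 undefined in the second record
  m2$n_round <- 0L; m2$method2 <- NA; m2$method3 <- NA; m2$method4 <- NA
  recs <- rbind(m, m2)
  recs$method1 <- c(123.456789012345, 0.000123456789012)
  path <- file.path(dir, "metrics.csv")
  write_metrics_table(recs, path)

  txt <- readLines(path)
  expect_length(txt, 3)
  # undefined metrics appear as empty fields, not "NA"
  expect_false(grepl("NA", txt[3]))

  back <- read_metrics_table(path)
  expect_identical(back$method1, as.numeric(sprintf("%.12g", recs$method1)))
  expect_true(is.na(back$method2[2]))
  # write -> read -> write is byte-identical
  path2 <- file.path(dir, "metrics2.csv")
  write_metrics_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("cell marks outside the ROI raise a containment warning", {
  expect_warning(
    toy_section(cells = data.frame(cell_id = "far", marker = "AP2G",
                                   x = 50, y = 50)),
    "outside the ROI")
})
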