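# hand-built feature tables exercise the four formulas directly
fake_features <- function(n_round, n_other = 0, cells_round = 0,
                          cells_other = 0, area_round = 0.0025,
                          area_other = 0.0025, round_with_cells = NULL) {
  n <- n_round + n_other
  cells <- integer(n)
  if (n_round > 0 && cells_round > 0) {
    # spread cells over the first `round_with_cells` round tubules
    k <- round_with_cells %||% n_round
    base <- rep(cells_round %/% k, k)
    base[seq_len(cells_round %% k)] <- base[seq_len(cells_round %% k)] + 1L
    cells[seq_len(k)] <- base
  }
  if (n_other > 0 && cells_other > 0) {
    cells[n_round + 1] <- cells_other
  }
  df <- data.frame(
    tubule_id = sprintf("t%03d", seq_len(n)),
    area_mm2 = c(rep(area_round, n_round), rep(area_other, n_other)),
    diameter_long = 1, diameter_short = 1,
    roundness_ratio = c(rep(1.2, n_round), rep(2.0, n_other)),
    is_round = c(rep(TRUE, n_round), rep(FALSE, n_other)),
    is_intact = TRUE,
    cell_count_total = cells,
    cell_count_AP2G = 0L,
    cell_count_MAGEA4 = cells)
  attr(df, "section_id") <- "fake"
  attr(df, "sample_id") <- "fakeA"
  df
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the four formulas give their textbook values", {
  # 30 cells over 0.05 mm2 of tubule -> density 600 cells/mm2
  f <- fake_features(n_round = 10, n_other = 10, cells_round = 20,
                     cells_other = 10, area_round = 0.0025,
                     area_other = 0.0025)
  m <- compute_section_metrics(f, tissue_type = "fetal")
  expect_equal(m$method1, 30 / 0.05)

  # 20 cells in 8 round tubules (area 0.02 mm2), 7 of them occupied
  f <- fake_features(n_round = 8, cells_round = 20, area_round = 0.0025,
                     round_with_cells = 7)
  m <- compute_section_metrics(f, tissue_type = "fetal")
  expect_equal(m$method2, 2.5)
  expect_equal(m$method3, 87.5)
  expect_equal(m$method4, 1000)

  # zero round tubules: Method 1 defined, 2-4 missing, QC flag raised
  f <- fake_features(n_round = 0, n_other = 4, cells_other = 12,
                     area_other = 0.0025)
  m <- compute_section_metrics(f, tissue_type = "fetal")
  expect_equal(m$method1, 1200)
  expect_true(is.na(m$method2) && is.na(m$method3) && is.na(m$method4))
  expect_match(m$qc_flags, "few_round_tubules")
  expect_match(m$qc_flags, "small_total_area")  # 0.01 < 0.015 fetal
})

test_that("only intact tubules enter counts and areas", {
  f <- fake_features(n_round = 4, cells_round = 8)
  f$is_intact[1] <- FALSE
  m <- compute_section_metrics(f, tissue_type = "prepubertal")
  expect_equal(m$n_tubules_analysed, 3)
  expect_equal(m$n_cells_total, sum(f$cell_count_total[-1]))
  expect_equal(m$total_tubular_area_mm2, sum(f$area_mm2[-1]))
})

test_that("a section with zero intact tubules yields all-missing metrics", {
  f <- fake_features(n_round = 2, cells_round = 4)
  f$is_intact <- FALSE
  m <- compute_section_metrics(f, tissue_type = "fetal")
  expect_equal(m$n_tubules_analysed, 0)
  expect_true(all(is.na(c(m$method1, m$method2, m$method3, m$method4))))
  expect_match(m$qc_flags, "few_round_tubules")
})

test_that("metric identities hold on simulated sections", {
  set.seed(33)
  for (i in 1:15) {
    sim <- simulate_section(sim_config(n_tubules = 15), density = 800)
    f <- compute_tubule_features(sim$section)
    m <- compute_section_metrics(f, tissue_type = "fetal")
    # method2 = method4 * mean round-tubule area
    if (!is.na(m$method2) && !is.na(m$method4) && m$method4 > 0) {
      lhs <- m$method2
      rhs <- m$method4 * (m$round_tubular_area_mm2 / m$n_round)
      expect_lt(abs(lhs - rhs) / max(lhs, 1e-300), 1e-12)
    }
    if (!is.na(m$method3)) {
      expect_gte(m$method3, 0)
      expect_lte(m$method3, 100)
    }
    expect_lte(m$n_round, m$n_tubules_analysed)
    expect_lte(m$n_round_with_cells, max(m$n_round, 0))
    expect_lte(m$n_cells_in_round, m$n_cells_total)
    expect_lte(m$round_tubular_area_mm2, m$total_tubular_area_mm2 + 1e-15)
  }
})

test_that("all-round sections make method1 and method4 coincide exactly", {
  set.seed(44)
  sim <- simulate_section(sim_config(n_tubules = 12, aspect_sdlog = 0,
                                     aspect_meanlog = log(1e-9)),
                          density = 700)
  f <- compute_tubule_features(sim$section)
  f <- f[f$is_intact, ]
  expect_true(all(f$is_round))
  m <- compute_section_metrics(f, tissue_type = "fetal")
  expect_identical(m$method1, m$method4)
  expect_identical(m$n_cells_in_round, m$n_cells_total)
})

test_that("rescaling coordinates: methods 2-3 invariant, 1 and 4 scale 1/s^2", {
  set.seed(55)
  sim <- simulate_section(sim_config(n_tubules = 12), density = 900)
  s <- 3
  sec1 <- sim$section
  sec2 <- scale_section(sec1, s)
  m1 <- compute_section_metrics(compute_tubule_features(sec1))
  # edge tolerance is a physical length; scale it with the coordinates
  cfg2 <- quant_config(edge_tolerance = 0.002 * s)
  m2 <- compute_section_metrics(compute_tubule_features(sec2, cfg2))
  expect_equal(m2$method2, m1$method2, tolerance = 1e-9)
  expect_equal(m2$method3, m1$method3, tolerance = 1e-9)
  expect_equal(m2$method1, m1$method1 / s ^ 2, tolerance = 1e-9)
  expect_equal(m2$method4, m1$method4 / s ^ 2, tolerance = 1e-9)
})

test_that("adding a cell inside a round tubule never decreases any metric", {
  f <- fake_features(n_round = 5, n_other = 3, cells_round = 10,
                     cells_other = 4, round_with_cells = 4)
  m0 <- compute_section_metrics(f, tissue_type = "fetal")
  f2 <- f
  f2$cell_count_total[2] <- f2$cell_count_total[2] + 1L
  f2$cell_count_MAGEA4[2] <- f2$cell_count_MAGEA4[2] + 1L
  m1 <- compute_section_metrics(f2, tissue_type = "fetal")
  for (mm in c("method1", "method2", "method3", "method4")) {
    expect_gte(m1[[mm]], m0[[mm]])
  }
})

test_that("sample aggregation: means, pooling and omission rules", {
  s1 <- compute_section_metrics(fake_features(5, cells_round = 10,
                                              area_round = 0.004), # m1 = 500
                                tissue_type = "fetal")
  s2 <- s1; s2$section_id <- "fake2"
  # second section: 30 cells over 0.02 -> m1 = 1500
  s2$n_cells_total <- 30; s2$n_cells_in_round <- 30
  s2$total_tubular_area_mm2 <- 0.02; s2$round_tubular_area_mm2 <- 0.02
  s2$method1 <- 1500; s2$method4 <- 1500
  secs <- rbind(s1, s2)
  design <- data.frame(sample_id = "fakeA", subject_id = "p1",
                       condition = "control", tissue_type = "fetal")

  agg <- aggregate_by_sample(secs, design, quant_config())
  expect_equal(agg$method1, mean(c(s1$method1, 1500)))
  expect_equal(agg$n_round_total, 10)

  pooled <- aggregate_by_sample(secs, design,
                                quant_config(pooling_mode = "pooled_counts"))
  expect_equal(pooled$method1,
               (s1$n_cells_total + 30) / (s1$total_tubular_area_mm2 + 0.02))

  # a metric missing in one section is omitted from that metric's mean
  s3 <- s2; s3$section_id <- "fake3"
  s3$n_round <- 0; s3$method2 <- NA; s3$method3 <- NA; s3$method4 <- NA
  agg2 <- aggregate_by_sample(rbind(s1, s3), design, quant_config())
  expect_equal(agg2$method2, s1$method2)

  expect_error(
    aggregate_by_sample(rbind(s1, transform(s2, sample_id = "ghost")),
                        design, quant_config()),
    class = "tq_data_error")
})
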