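#' Simulation configuration
#'
#' Parameters of the synthetic annotated-section generator. A section is a
#' `width` x `height` mm rectangle of tissue; tubule cross-sections are
#' ellipse-shaped 64-gons with lognormal areas and lognormal excess aspect
#' ratios, placed without overlap by dart throwing; germ cells are a Poisson
#' (optionally negative-binomial) point process inside tubules with
#' intensity `density` per mm2 of tubular area.
#'
#' Defaults emulate organotypic-culture fragments of immature human testis:
#' sections of ~1.5 mm across holding a few dozen tubule cross-sections of
#' median area 0.005 mm2 (about 80 um across), with roughly half the
#' interior profiles round at the 1.5 diameter-ratio threshold, and germ
#' cell densities of several hundred cells per mm2 of tubule.
#'
#' @param width,height Section extent in mm.
#' @param n_tubules Number of tubule cross-sections attempted per section
#'   (drawn as Poisson with this mean when `tubule_count_random = TRUE`).
#' @param tubule_count_random Draw the per-section tubule count from a
#'   Poisson distribution instead of fixing it.
#' @param area_meanlog,area_sdlog Lognormal parameters of the tubule profile
#'   area (mm2).
#' @param aspect_meanlog,aspect_sdlog Lognormal parameters of the *excess*
#'   aspect ratio: axis ratio = 1 + Lognormal(meanlog, sdlog), so ratios are
#'   always >= 1. The defaults put about half the profiles below the 1.5
#'   round threshold; see [aspect_meanlog_for_round_fraction()].
#' @param density Germ cells per mm2 of tubular area (the true lambda).
#' @param subject_sd SD of the multiplicative lognormal subject effect on
#'   `density` (0 disables it). The effect is drawn once per subject.
#' @param dispersion Negative-binomial overdispersion of per-tubule counts
#'   (`0` = Poisson; otherwise counts are NB with size `1/dispersion`).
#' @param prop_ap2g Probability that a simulated germ cell is an AP2G+
#'   gonocyte rather than a MAGEA4+ (pre)spermatogonium.
#' @param n_vertices Vertices per tubule polygon (default 64).
#' @param max_attempts Dart-throwing attempts per tubule before giving up.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(width = 1.5, height = 1.5,
                       n_tubules = 25, tubule_count_random = FALSE,
                       area_meanlog = log(0.005), area_sdlog = 0.5,
                       aspect_meanlog = log(0.5), aspect_sdlog = 0.6,
                       density = 690, subject_sd = 0.25,
                       dispersion = 0, prop_ap2g = 0.4,
                       n_vertices = 64, max_attempts = 10000) {
  if (width <= 0 || height <= 0) stop_config("section width/height must be positive")
  if (n_tubules < 1) stop_config("n_tubules must be >= 1")
  if (area_sdlog < 0 || aspect_sdlog < 0) stop_config("sdlog parameters must be >= 0")
  if (density < 0) stop_config("density must be >= 0")
  if (subject_sd < 0) stop_config("subject_sd must be >= 0")
  if (dispersion < 0) stop_config("dispersion must be >= 0")
  if (prop_ap2g < 0 || prop_ap2g > 1) stop_config("prop_ap2g must be in [0, 1]")
  if (n_vertices < 8) stop_config("n_vertices must be >= 8")
  structure(as.list(environment()), class = "sim_config")
}

#' Aspect-ratio meanlog giving a target round fraction
#'
#' With axis ratio = 1 + Lognormal(meanlog, sdlog) and the 1.5 round
#' threshold, P(round) = P(Lognormal < 0.5). Solving for `meanlog` gives the
#' parameter that makes the expected round fraction equal `frac`.
#'
#' @param frac Target fraction of profiles with axis ratio < `threshold`.
#' @param sdlog Lognormal sdlog (default 0.6).
#' @param threshold Roundness threshold (default 1.5).
#' @return The `aspect_meanlog` value to pass to [sim_config()].
#' @export
aspect_meanlog_for_round_fraction <- function(frac, sdlog = 0.6,
                                              threshold = 1.5) {
  stopifnot(frac > 0, frac < 1, threshold > 1)
  log(threshold - 1) - stats::qnorm(frac) * sdlog
}

# ellipse as an inscribed n-gon, rotated by theta, centred at (cx, cy)
ellipse_polygon <- function(cx, cy, a, b, theta, n = 64) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  ex <- a * cos(t); ey <- b * sin(t)
  ct <- cos(theta); st <- sin(theta)
  cbind(cx + ex * ct - ey * st, cy + ex * st + ey * ct)
}

# Sutherland-Hodgman clip of a polygon against the rectangle [0,W]x[0,H]
clip_to_rect <- function(poly, W, H) {
  clip_half <- function(pts, inside, intersect) {
    n <- nrow(pts)
    if (n == 0L) return(pts)
    out <- matrix(numeric(0), 0L, 2L)
    for (i in seq_len(n)) {
      cur <- pts[i, ]; prev <- pts[if (i == 1L) n else i - 1L, ]
      cin <- inside(cur); pin <- inside(prev)
      if (cin) {
        if (!pin) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (pin) {
        out <- rbind(out, intersect(prev, cur))
      }
    }
    out
  }
  ix <- function(p1, p2, x) { t <- (x - p1[1L]) / (p2[1L] - p1[1L]); c(x, p1[2L] + t * (p2[2L] - p1[2L])) }
  iy <- function(p1, p2, y) { t <- (y - p1[2L]) / (p2[2L] - p1[2L]); c(p1[1L] + t * (p2[1L] - p1[1L]), y) }
  p <- poly
  p <- clip_half(p, function(q) q[1L] >= 0, function(a, b) ix(a, b, 0))
  p <- clip_half(p, function(q) q[1L] <= W, function(a, b) ix(a, b, W))
  p <- clip_half(p, function(q) q[2L] >= 0, function(a, b) iy(a, b, 0))
  p <- clip_half(p, function(q) q[2L] <= H, function(a, b) iy(a, b, H))
  p
}

# uniform points inside a polygon by rejection sampling in its bounding box
sample_in_polygon <- function(n, poly) {
  if (n == 0L) return(matrix(numeric(0), 0L, 2L))
  xr <- range(poly[, 1L]); yr <- range(poly[, 2L])
  out <- matrix(NA_real_, n, 2L)
  got <- 0L
  while (got < n) {
    m <- max(32L, 2L * (n - got))
    px <- stats::runif(m, xr[1L], xr[2L])
    py <- stats::runif(m, yr[1L], yr[2L])
    ok <- points_in_polygon(px, py, poly)
    take <- min(n - got, sum(ok))
    if (take > 0L) {
      idx <- which(ok)[seq_len(take)]
      out[got + seq_len(take), ] <- cbind(px[idx], py[idx])
      got <- got + take
    }
  }
  out
}

#' Simulate one annotated section
#'
#' Draws tubule profiles (ellipse 64-gons with lognormal area and aspect
#' ratio, random orientation) placed without overlap by dart throwing,
#' clips profiles crossing the section boundary (ground-truth flagged not
#' intact), and scatters germ cells inside each profile as a Poisson (or
#' negative-binomial) process with the section's true density. Uses the
#' current RNG state; seed upstream for reproducibility.
#'
#' @param config A [sim_config()].
#' @param density True germ-cell density for this section (defaults to
#'   `config$density`).
#' @param section_id,sample_id Identifiers for the generated section.
#' @return List with `section` (a [section_annotation()]) and `truth` (list
#'   with the section's `density` and a per-tubule data frame `tubules`:
#'   true semi-axes, axis ratio, clipped status, polygon area, expected and
#'   realised cell counts).
#' @export
simulate_section <- function(config = sim_config(), density = config$density,
                             section_id = "sim_section", sample_id = section_id) {
  W <- config$width; H <- config$height
  n <- if (config$tubule_count_random) stats::rpois(1L, config$n_tubules)
       else as.integer(config$n_tubules)
  n <- max(n, 1L)

  areas <- stats::rlnorm(n, config$area_meanlog, config$area_sdlog)
  aspects <- 1 + stats::rlnorm(n, config$aspect_meanlog, config$aspect_sdlog)
  bax <- sqrt(areas / (pi * aspects))
  aax <- bax * aspects
  thetas <- stats::runif(n, 0, pi)

  # dart-throwing with a conservative bounding-circle separation test
  px <- numeric(0); py <- numeric(0); pr <- numeric(0)
  placed <- logical(n)
  for (i in seq_len(n)) {
    for (att in seq_len(config$max_attempts)) {
      cx <- stats::runif(1, 0, W); cy <- stats::runif(1, 0, H)
      if (!length(px) || all((cx - px) ^ 2 + (cy - py) ^ 2 > (aax[i] + pr) ^ 2)) {
        px <- c(px, cx); py <- c(py, cy); pr <- c(pr, aax[i])
        placed[i] <- TRUE
        break
      }
    }
  }
  if (sum(placed) < n / 2) {
    stop_config("tubule packing infeasible (placed ", sum(placed), " of ", n,
                "); reduce n_tubules or enlarge the section")
  }
  if (any(!placed)) {
    message("simulate_section: placement shortfall, ", sum(!placed), " of ",
            n, " tubules dropped")
  }

  idx <- which(placed)
  # centres were appended in placement order = order of idx
  tubules <- list()
  t_i <- integer(0); t_clip <- logical(0); t_area <- t_mu <- numeric(0)
  t_n <- integer(0)
  cx_all <- cy_all <- numeric(0); mk_all <- character(0)
  for (j in seq_along(idx)) {
    i <- idx[j]
    poly <- ellipse_polygon(px[j], py[j], aax[i], bax[i], thetas[i],
                            config$n_vertices)
    clipped <- any(poly[, 1L] < 0 | poly[, 1L] > W |
                   poly[, 2L] < 0 | poly[, 2L] > H)
    if (clipped) {
      poly <- clip_to_rect(poly, W, H)
      if (nrow(poly) < 3L) next
      a2 <- tryCatch(polygon_area(poly), tq_geometry_error = function(e) 0)
      if (a2 <= 0) next
    }
    tid <- sprintf("t%03d", length(tubules) + 1L)
    area_poly <- polygon_area(poly)
    mu <- density * area_poly
    n_cells <- if (config$dispersion > 0) {
      stats::rnbinom(1L, size = 1 / config$dispersion, mu = mu)
    } else {
      stats::rpois(1L, mu)
    }
    if (n_cells > 0L) {
      xy <- sample_in_polygon(n_cells, poly)
      mk <- ifelse(stats::runif(n_cells) < config$prop_ap2g, "AP2G", "MAGEA4")
      cx_all <- c(cx_all, xy[, 1L]); cy_all <- c(cy_all, xy[, 2L])
      mk_all <- c(mk_all, mk)
    }
    tubules[[length(tubules) + 1L]] <- list(tubule_id = tid, outline = poly,
                                            intact_flag = NA)
    t_i <- c(t_i, i); t_clip <- c(t_clip, clipped)
    t_area <- c(t_area, area_poly); t_mu <- c(t_mu, mu)
    t_n <- c(t_n, n_cells)
  }
  if (!length(tubules)) stop_config("no tubules survived placement/clipping")
  cells <- if (length(cx_all)) {
    data.frame(cell_id = sprintf("c%05d", seq_along(cx_all)),
               marker = mk_all, x = cx_all, y = cy_all)
  } else NULL
  truth_tub <- data.frame(
    tubule_id = vapply(tubules, `[[`, "", "tubule_id"),
    semi_major = aax[t_i], semi_minor = bax[t_i],
    axis_ratio = aspects[t_i], clipped = t_clip,
    area_mm2 = t_area, expected_cells = t_mu, n_cells = t_n)

  roi <- rbind(c(0, 0), c(W, 0), c(W, H), c(0, H))
  section <- section_annotation(
    section_id = section_id, sample_id = sample_id, roi = roi,
    tubules = tubules, cells = cells, scale_mm_per_unit = 1)
  list(section = section,
       truth = list(density = density, tubules = truth_tub))
}

# deterministic sub-seed for the (seed, subject, condition, section) stream,
# kept below 2^31 so set.seed() accepts it
derive_seed <- function(seed, i, j, k) {
  p <- 2147483629
  h <- seed %% p
  for (v in c(i, j, k)) h <- (h * 69069 + v + 1) %% p
  as.integer(h)
}

#' Simulate a full study
#'
#' Generates a multi-subject, multi-condition study in the layout of the
#' tissue experiments the pipeline targets: each subject receives a
#' once-drawn multiplicative density effect, each condition multiplies the
#' base density by its effect size, and every subject x condition sample
#' contributes `sections_per_sample` sections. One RNG stream per
#' (seed, subject, condition, section) means adding sections never perturbs
#' existing ones, and an identical seed reproduces the study exactly.
#'
#' @param config A [sim_config()]; `config$density` is the control-level
#'   density.
#' @param subjects Number of subjects (>= 2).
#' @param conditions Named numeric vector of density multipliers, e.g.
#'   `c(control = 1, cisplatin = 0.705)`.
#' @param sections_per_sample Sections per subject x condition sample
#'   (default 4: two sections from each of two replicate fragments).
#' @param seed Integer study seed.
#' @param tissue_type `"fetal"` or `"prepubertal"` for the design table.
#' @return List with `sections` (list of [section_annotation()]), `design`
#'   (a [study_design()]), and `truth` (per-sample true densities plus the
#'   per-section truth objects).
#' @export
simulate_study <- function(config = sim_config(), subjects = 6,
                           conditions = c(control = 1),
                           sections_per_sample = 4, seed = 1,
                           tissue_type = "fetal") {
  if (subjects < 2) stop_config("need >= 2 subjects")
  if (length(conditions) < 1 || is.null(names(conditions))) {
    stop_config("conditions must be a named vector of density multipliers")
  }
  sections <- list()
  design_rows <- list()
  truth_samples <- list()
  truth_sections <- list()
  for (i in seq_len(subjects)) {
    set.seed(derive_seed(seed, i, 0L, 0L))
    subj_mult <- if (config$subject_sd > 0) {
      stats::rlnorm(1L, meanlog = -config$subject_sd ^ 2 / 2,
                    sdlog = config$subject_sd)
    } else 1
    subject_id <- sprintf("subj%02d", i)
    for (j in seq_along(conditions)) {
      cond <- names(conditions)[j]
      sample_id <- sprintf("%s_%s", subject_id, cond)
      lambda <- config$density * subj_mult * conditions[[j]]
      design_rows[[length(design_rows) + 1L]] <- data.frame(
        sample_id = sample_id, subject_id = subject_id,
        condition = cond, tissue_type = tissue_type)
      truth_samples[[length(truth_samples) + 1L]] <- data.frame(
        sample_id = sample_id, subject_id = subject_id, condition = cond,
        subject_multiplier = subj_mult, condition_multiplier = conditions[[j]],
        true_density = lambda)
      for (k in seq_len(sections_per_sample)) {
        set.seed(derive_seed(seed, i, j, k))
        section_id <- sprintf("%s_sec%d", sample_id, k)
        sim <- simulate_section(config, density = lambda,
                                section_id = section_id,
                                sample_id = sample_id)
        sections[[length(sections) + 1L]] <- sim$section
        tt <- sim$truth$tubules
        tt$section_id <- section_id
        truth_sections[[length(truth_sections) + 1L]] <- tt
      }
    }
  }
  design <- study_design(do.call(rbind, design_rows))
  list(sections = sections, design = design,
       truth = list(samples = do.call(rbind, truth_samples),
                    tubules = do.call(rbind, truth_sections),
                    seed = seed,
                    conditions = conditions))
}

#' Built-in study presets
#'
#' `fetal_chemo`: second-trimester fetal testis fragments exposed in vitro
#' to vehicle control, cisplatin or carboplatin; control density 690.2
#' cells/mm2 with treated-group multipliers 0.7052 and 0.7212 (the ratios of
#' the printed group means), 6 subjects, mixed AP2G/MAGEA4 marks.
#' `prepubertal_cryo`: prepubertal biopsy fragments, four conditions
#' (fresh control, cryopreserved, fresh cultured, cryopreserved cultured)
#' with base density 1175 cells/mm2 and multipliers 1 / 0.800 / 0.530 /
#' 0.514 taken from the round-tubular-density group means; MAGEA4 marks
#' only. Both presets are starting points for simulation studies, not claims
#' of distributional fidelity to any real cohort.
#'
#' @param name `"fetal_chemo"` or `"prepubertal_cryo"`.
#' @return List with `config` ([sim_config()]), `conditions`, `subjects`,
#'   `sections_per_sample`, `tissue_type`.
#' @export
sim_preset <- function(name = c("fetal_chemo", "prepubertal_cryo")) {
  name <- match.arg(name)
  if (name == "fetal_chemo") {
    list(config = sim_config(width = 1.2, height = 1.2, n_tubules = 20,
                             density = 690.2, prop_ap2g = 0.4),
         conditions = c(control = 1,
                        cisplatin = 486.7 / 690.2,
                        carboplatin = 497.8 / 690.2),
         subjects = 6, sections_per_sample = 4, tissue_type = "fetal")
  } else {
    list(config = sim_config(width = 1.2, height = 1.2, n_tubules = 20,
                             density = 1175, prop_ap2g = 0,
                             aspect_meanlog = aspect_meanlog_for_round_fraction(0.35)),
         conditions = c(control = 1,
                        cryopreserved = 939.4 / 1175,
                        fresh_cultured = 623.2 / 1175,
                        cryo_cultured = 604.5 / 1175),
         subjects = 6, sections_per_sample = 4, tissue_type = "prepubertal")
  }
}
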