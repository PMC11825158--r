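#' Pearson correlation with best-fit line
#'
#' Product-moment correlation with a two-sided p-value from the t transform
#' on n - 2 degrees of freedom, plus the least-squares line used for the
#' best-fit overlay in method-agreement scatter plots.
#'
#' @param x,y Equal-length numeric vectors (n >= 3), finite, each with
#'   nonzero variance.
#' @return List with `n`, `r`, `p`, `slope`, `intercept`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop_analysis("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  if (!all(ok)) stop_analysis("x and y must be finite")
  n <- length(x)
  if (n < 3L) stop_analysis("need at least 3 pairs for a correlation")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop_analysis("undefined correlation: zero variance in x or y")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  slope <- ct$estimate * stats::sd(y) / stats::sd(x)
  list(n = n,
       r = unname(ct$estimate),
       p = unname(ct$p.value),
       slope = unname(slope),
       intercept = mean(y) - unname(slope) * mean(x))
}

# Dunn's post-hoc test after Kruskal-Wallis: pairwise z statistics on mean
# ranks with the ties correction, Bonferroni-adjusted over all pairs.
dunn_test <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  tie_tab <- table(values)
  ties <- sum(tie_tab ^ 3 - tie_tab) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  lv <- levels(groups)
  k <- length(lv)
  pairs <- utils::combn(lv, 2L)
  npairs <- ncol(pairs)
  out <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                    estimate = NA_real_, statistic = NA_real_,
                    p_unadj = NA_real_, p_adj = NA_real_)
  for (i in seq_len(npairs)) {
    g1 <- pairs[1L, i]; g2 <- pairs[2L, i]
    se <- sqrt((N * (N + 1) / 12 - ties) * (1 / ns[[g1]] + 1 / ns[[g2]]))
    z <- (rbar[[g2]] - rbar[[g1]]) / se
    p <- 2 * stats::pnorm(-abs(z))
    out$statistic[i] <- z
    out$p_unadj[i] <- p
    out$p_adj[i] <- min(1, p * npairs)
  }
  out
}

# Tukey pairwise comparisons from a fitted aov: studentized-range p-values,
# honest about zero residual variance (p = 0 for any nonzero difference).
tukey_pairs <- function(fit, term, data) {
  mse <- sum(stats::residuals(fit) ^ 2) / stats::df.residual(fit)
  mns <- tapply(data$.value, data$.group, mean)
  ns <- tapply(data$.value, data$.group, length)
  lv <- names(mns)
  k <- length(lv)
  pairs <- utils::combn(lv, 2L)
  out <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                    estimate = NA_real_, statistic = NA_real_,
                    p_unadj = NA_real_, p_adj = NA_real_)
  dfres <- stats::df.residual(fit)
  for (i in seq_len(ncol(pairs))) {
    g1 <- pairs[1L, i]; g2 <- pairs[2L, i]
    diff <- mns[[g2]] - mns[[g1]]
    se_t <- sqrt(mse * (1 / ns[[g1]] + 1 / ns[[g2]]))
    if (se_t == 0) {
      tval <- if (diff == 0) 0 else sign(diff) * Inf
      p_un <- if (diff == 0) 1 else 0
      p_tk <- p_un
    } else {
      tval <- diff / se_t
      p_un <- 2 * stats::pt(-abs(tval), dfres)
      p_tk <- stats::ptukey(sqrt(2) * abs(tval), nmeans = k, df = dfres,
                            lower.tail = FALSE)
    }
    out$estimate[i] <- diff
    out$statistic[i] <- tval
    out$p_unadj[i] <- p_un
    out$p_adj[i] <- p_tk
  }
  out
}

#' Compare experimental groups for one metric
#'
#' Normality-gated group comparison mirroring common practice for these
#' data: per-group Shapiro-Wilk tests at `alpha`; when every group passes,
#' an additive two-factor ANOVA with condition and subject as crossed
#' factors (a randomized-block model, each subject contributing every
#' condition) followed by Tukey pairwise comparisons on condition; otherwise
#' a Kruskal-Wallis test on condition followed by Dunn's pairwise test with
#' Bonferroni adjustment. Groups too small or constant to assess normality
#' pass the gate. Samples missing the metric are dropped (with a message).
#'
#' @param samples Sample-level metrics data frame (see
#'   [aggregate_by_sample()]); needs columns `condition`, `subject_id` and
#'   the metric.
#' @param metric Metric column name (e.g. `"method1"`).
#' @param config A [quant_config()]; supplies `alpha`.
#' @return Object of class `comparison_result`: a list with `metric`,
#'   `test_used` (`"anova_tukey"` or `"kruskal_dunn"`), `groups` (n, mean,
#'   sd per group), `omnibus_p`, `pairwise` (adjusted p per pair,
#'   significance at `alpha`), `alpha`, and `model_note` recording the
#'   blocking assumption.
#' @export
compare_groups <- function(samples, metric, config = quant_config()) {
  if (!metric %in% names(samples)) {
    stop_analysis("metric '", metric, "' not present in sample metrics")
  }
  d <- data.frame(.value = samples[[metric]],
                  .group = as.character(samples$condition),
                  .block = as.character(samples$subject_id))
  n_drop <- sum(is.na(d$.value))
  if (n_drop > 0L) {
    message("compare_groups(", metric, "): dropped ", n_drop,
            " sample(s) with the metric undefined")
  }
  d <- d[!is.na(d$.value), , drop = FALSE]
  usable <- names(which(table(d$.group) >= 2L))
  d <- d[d$.group %in% usable, , drop = FALSE]
  if (length(usable) < 2L) {
    stop_analysis("compare_groups needs >= 2 groups with >= 2 samples each")
  }
  d$.group <- factor(d$.group)
  d$.block <- factor(d$.block)

  normal <- vapply(split(d$.value, d$.group), function(v) {
    if (length(v) < 3L || stats::var(v) == 0) return(TRUE)  # cannot assess
    stats::shapiro.test(v)$p.value > config$alpha
  }, logical(1L))

  summaries <- do.call(rbind, lapply(levels(d$.group), function(g) {
    v <- d$.value[d$.group == g]
    data.frame(group = g, n = length(v), mean = mean(v), sd = stats::sd(v))
  }))

  if (all(normal)) {
    test_used <- "anova_tukey"
    # block on subject only when it leaves residual degrees of freedom
    use_block <- nlevels(d$.block) > 1L &&
      (nrow(d) - nlevels(d$.group) - nlevels(d$.block) + 1L) > 0L
    fit <- if (use_block) {
      stats::aov(.value ~ .group + .block, data = d)
    } else {
      stats::aov(.value ~ .group, data = d)
    }
    tab <- summary(fit)[[1L]]
    rn <- trimws(rownames(tab))
    ms_res <- tab[rn == "Residuals", "Mean Sq"]
    if (is.finite(ms_res) && ms_res == 0) {
      # perfect within-group fit: any between-group variation is exact
      omnibus_p <- if (tab[rn == ".group", "Sum Sq"] > 0) 0 else 1
    } else {
      omnibus_p <- tab[rn == ".group", "Pr(>F)"]
    }
    pw <- tukey_pairs(fit, ".group", d)
  } else {
    test_used <- "kruskal_dunn"
    kw <- stats::kruskal.test(d$.value, d$.group)
    omnibus_p <- kw$p.value
    pw <- dunn_test(d$.value, d$.group)
  }
  pw$significant <- pw$p_adj < config$alpha

  structure(
    list(metric = metric, test_used = test_used, groups = summaries,
         omnibus_p = unname(omnibus_p), pairwise = pw,
         alpha = config$alpha,
         normality = data.frame(group = names(normal), pass = unname(normal)),
         model_note = paste("two-factor additive model: condition + subject",
                           "(randomized block; subjects crossed with conditions)")),
    class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result> metric:", x$metric, " test:", x$test_used,
      " omnibus p =", format(x$omnibus_p, digits = 4), "\n")
  print(x$pairwise, digits = 4)
  invisible(x)
}

#' Method-agreement correlations against Method 1
#'
#' Pearson correlation of each round-tubule-dependent metric (Methods 2-4)
#' against the tubular germ cell density (Method 1) on sample-level values,
#' overall and stratified by the sample's total round-tubule count
#' (`n_round_total < threshold` vs `>= threshold`). Samples missing either
#' metric of a pair are dropped pairwise; strata with fewer than 3 pairs are
#' reported with `r` and `p` undefined.
#'
#' @param samples Sample-level metrics data frame.
#' @param threshold Round-tubule count splitting the strata (default 25).
#' @param config A [quant_config()].
#' @return Data frame with columns `method`, `stratum` (`all`,
#'   `below_threshold`, `at_or_above_threshold`), `n`, `r`, `p`, `slope`,
#'   `intercept`.
#' @export
correlate_methods <- function(samples, threshold = 25,
                              config = quant_config()) {
  strata <- list(
    all = rep(TRUE, nrow(samples)),
    below_threshold = samples$n_round_total < threshold,
    at_or_above_threshold = samples$n_round_total >= threshold)
  rows <- list()
  for (m in c("method2", "method3", "method4")) {
    for (s in names(strata)) {
      keep <- strata[[s]] & !is.na(samples$method1) & !is.na(samples[[m]])
      n_pairs <- sum(keep)
      dropped <- sum(strata[[s]]) - n_pairs
      if (dropped > 0L && s == "all") {
        message("correlate_methods(", m, "): dropped ", dropped,
                " sample(s) with undefined values")
      }
      row <- data.frame(method = m, stratum = s, n = n_pairs,
                        r = NA_real_, p = NA_real_,
                        slope = NA_real_, intercept = NA_real_)
      if (n_pairs >= 3L) {
        res <- tryCatch(
          pearson_correlation(samples$method1[keep], samples[[m]][keep]),
          tq_analysis_error = function(e) NULL)
        if (!is.null(res)) {
          row$r <- res$r; row$p <- res$p
          row$slope <- res$slope; row$intercept <- res$intercept
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
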