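#!/usr/bin/env Rscript
# Step 3: group comparisons per metric (normality-gated ANOVA+Tukey or
# Kruskal-Wallis+Dunn), asking whether each quantification method detects
# the simulated density reductions.

suppressPackageStartupMessages(library(tubulequant))

for (preset in c("fetal_chemo", "prepubertal_cryo")) {
  q <- file.path("results", preset, "quant", "sample_metrics.csv")
  out <- file.path("results", preset, "compare")
  res <- suppressMessages(run_compare(q, out))
  cat(preset, ":\n", sep = "")
  for (m in names(res)) {
    r <- res[[m]]
    sig <- r$pairwise[r$pairwise$significant, , drop = FALSE]
    cat(sprintf("  %s [%s] omnibus p = %.4g; significant pairs: %s\n",
                m, r$test_used, r$omnibus_p,
                if (nrow(sig)) paste(sig$group1, "vs", sig$group2,
                                     collapse = "; ") else "none"))
  }
}
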