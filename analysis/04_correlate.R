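#!/usr/bin/env Rscript
# Step 4: method-agreement analysis. Pearson correlation of Methods 2-4
# against Method 1 on sample-level values, overall and stratified by the
# <25 / >=25 round-tubule convention.

suppressPackageStartupMessages(library(tubulequant))

for (preset in c("fetal_chemo", "prepubertal_cryo")) {
  q <- file.path("results", preset, "quant", "sample_metrics.csv")
  out <- file.path("results", preset, "correlate")
  res <- suppressMessages(run_correlate(q, out))
  cat(preset, ":\n", sep = "")
  for (i in seq_len(nrow(res))) {
    cat(sprintf("  %s vs method1 [%s]: r = %s (n = %d)\n",
                res$method[i], res$stratum[i],
                ifelse(is.na(res$r[i]), "undefined",
                       sprintf("%.3f", res$r[i])), res$n[i]))
  }
}
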