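#!/usr/bin/env Rscript
# Step 1: generate the two synthetic studies the analysis runs on.
#
# fetal_chemo: 6 fetal-tissue subjects x {control, cisplatin, carboplatin},
# 4 sections per sample, control density 690.2 cells/mm2 and treated-group
# multipliers 0.7052 / 0.7212.
# prepubertal_cryo: 6 prepubertal subjects x {control, cryopreserved,
# fresh_cultured, cryo_cultured}, base density 1175 cells/mm2.
#
# Section files (bulky GeoJSON) go to scratch/; they are regenerated on
# demand and reproducible from the seed recorded in each manifest.

suppressPackageStartupMessages(library(tubulequant))

seed <- 20260919
for (preset in c("fetal_chemo", "prepubertal_cryo")) {
  out <- file.path("scratch", "sim", preset)
  st <- run_simulate(out, preset = preset, seed = seed)
  cat(sprintf("%s: %d sections, %d samples -> %s\n", preset,
              length(st$sections), nrow(st$design), out))
  tr <- st$truth$samples
  cat("  true density range across samples:",
      sprintf("%.0f-%.0f cells/mm2\n", min(tr$true_density),
              max(tr$true_density)))
}
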