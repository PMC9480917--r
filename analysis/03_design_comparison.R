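#!/usr/bin/env Rscript
# Fast vs slow ER design comparison at matched scan time and noise: voxelwise
# estimate reliability (beta SEs), preferred-fingertip amplitudes and tuning
# width per design. Writes results/design_comparison.tsv.

library(somatomap)

dir.create("results", showWarnings = FALSE)

cmp <- experiment_fast_vs_slow(pipeline_config(seed = 1), n_runs = 4)
write.table(cmp, "results/design_comparison.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

print(cmp, digits = 3)
cat(sprintf(
  "\nMean beta SE ratio slow/fast: %.2f (efficiency theory predicts %.2f).\n",
  attr(cmp, "se_ratio"), attr(cmp, "predicted_se_ratio")
))
cat("The fast design yields more reliable estimates at equal scan time,\n")
cat("while both designs recover the same response amplitudes on average.\n")
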