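#!/usr/bin/env Rscript
# Circularity-bias control: recentered ROI tuning curves for untuned (pure
# noise) voxels, recentered either on an independent preference map or on the
# same data's argmax. Writes results/circularity_bias.tsv.

library(somatomap)

dir.create("results", showWarnings = FALSE)

set.seed(1)
nv <- 5000
betas <- matrix(rnorm(nv * 5), nv, 5) # untuned voxels: no real preference
indep <- sample(1:5, nv, replace = TRUE)
circ <- max.col(betas)

ci <- recenter_and_average(betas, indep, 1:nv)
cc <- recenter_and_average(betas, circ, 1:nv)
out <- data.frame(
  position = ci$position,
  independent = ci$value,
  circular = cc$value,
  n_independent = ci$n_voxels,
  n_circular = cc$n_voxels
)
write.table(out, "results/circularity_bias.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

se <- sd(betas) / sqrt(nv)
peak <- function(curve) {
  curve$value[curve$position == 0] -
    mean(curve$value[abs(curve$position) >= 1], na.rm = TRUE)
}
cat("Offset-0 minus off-center mean for untuned voxels:\n")
cat(sprintf("  independent recentering: %+.4f (%.1f SE) - flat, as it must be\n",
            peak(ci), peak(ci) / se))
cat(sprintf("  circular recentering:    %+.4f (%.1f SE) - spurious tuning\n",
            peak(cc), peak(cc) / se))
cat("\nRecentering voxel tuning curves on a preference estimated from the\n")
cat("same data manufactures a peak out of noise; the preference map must\n")
cat("come from an independent dataset (here, the phase-encoded localizer).\n")
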