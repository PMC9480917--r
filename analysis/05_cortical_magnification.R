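#!/usr/bin/env Rscript
# Cortical magnification: geodesic distances between consecutive fingertip
# representations delineated by the phase-encoded analysis of the simulated
# patch. Writes results/magnification.tsv.

library(somatomap)

dir.create("results", showWarnings = FALSE)

res <- run_pipeline(pipeline_config(seed = 1))
patch <- res$patch
spacing_mm <- 1.5 # nominal voxel size of the emulated acquisition

d <- cortical_distances(res$phase$regions, patch$grid_shape,
                        spacing = spacing_mm,
                        axis = patch$somatotopic_axis)
out <- data.frame(pair = c("1-2", "2-3", "3-4", "4-5"), distance_mm = d)
write.table(out, "results/magnification.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

print(out)
cat(sprintf("\nMean consecutive-fingertip distance: %.1f mm at %.1f-mm voxels.\n",
            mean(d, na.rm = TRUE), spacing_mm))
cat("The synthetic patch has a uniform somatotopic gradient, so distances\n")
cat("are roughly equal across pairs; real maps show larger thumb-index\n")
cat("separations than ring-pinky ones.\n")
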