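#!/usr/bin/env Rscript
# End-to-end simulated mapping experiment: synthetic somatotopic patch,
# phase-encoded localizer, two-step GLM on concatenated fast + slow ER runs,
# voxelwise pRF fits and per-area ROI tuning. Writes maps and summaries under
# results/pipeline/.

library(somatomap)

res <- run_pipeline(pipeline_config(seed = 1, out_dir = "results/pipeline"))

cat("Phase-encoded localizer: fingertip regions in the S1 band\n")
cat("  voxels per region:", lengths(res$phase$regions), "\n")
cat(sprintf("  significant voxels (Hochberg-corrected p < %.2f): %d\n",
            res$config$alpha, sum(res$phase$map$significant)))

resp <- res$patch$voxels$responsive
cat(sprintf(
  "\nER analysis: %d of %d truly responsive voxels pass the any-positive\n",
  sum(res$glm$fdr_any$rejected & resp), sum(resp)
))
cat(sprintf("F test at FDR q = %.2f.\n", res$config$fdr_q))

cat("\nROI tuning (recentered 9-point curves):\n")
for (r in res$roi) {
  cat(sprintf("  %-9s n = %3d  mean pRF sigma = %5.2f  curve FWHM = %6.2f\n",
              r$area, r$n_voxels, r$mean_prf_sigma, r$fwhm))
}
cat("\nTuning width increases from BA3b through BA1 and BA2 toward the\n")
cat("near-flat post-BA2 band, and from BA4a toward BA6, matching the\n")
cat("generative gradient.\n")
cat("\nStage timings (s):\n")
print(round(res$timings, 2))
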