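# Shared fixtures built in code.

# A one-row band of delta-tuned voxels, one per fingertip (columns 1..5).
delta_patch <- function(sigma = 0.05, noise_sd = 0, seed = 1) {
  cfg <- patch_config(
    grid_shape = c(5, 5),
    bands = data.frame(label = "BA3b", row_start = 3, row_end = 3,
                       sigma = sigma),
    noise_sd = noise_sd, prop_responsive = 1,
    amplitude_sd = 0, sigma_jitter_sd = 0
  )
  make_somatotopic_patch(cfg, seed = seed)
}

# A small mixed-tuning band for GLM round trips.
small_patch <- function(sigma = 1.2, noise_sd = 0, seed = 2) {
  cfg <- patch_config(
    grid_shape = c(4, 5),
    bands = data.frame(label = "BA3b", row_start = 2, row_end = 3,
                       sigma = sigma),
    noise_sd = noise_sd, prop_responsive = 1,
    amplitude_sd = 0.3, sigma_jitter_sd = 0.1
  )
  make_somatotopic_patch(cfg, seed = seed)
}

# Ground-truth fingertip tuning matrix (voxels x 5) of a patch.
truth_tuning <- function(patch) {
  v <- patch$voxels
  t(vapply(seq_len(nrow(v)), function(i) {
    if (!v$responsive[i]) return(numeric(5))
    v$amplitude[i] * gaussian_tuning(1:5, v$prf_center[i], v$prf_sigma[i])
  }, numeric(5)))
}

# Percent-signal-change conversion divides by baseline * (1 + mean/100); the
# effective per-voxel shrinkage of a noiseless run's response.
psc_shrinkage <- function(sim) {
  1 + rowMeans(attr(sim, "clean_percent")) / 100
}

# The default pipeline result is expensive; compute once per test session.
default_pipeline_result <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_pipeline(pipeline_config(seed = 1))
    cache
  }
})
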