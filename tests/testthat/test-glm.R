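test_that("noiseless GLM recovers ground-truth amplitudes exactly", {
  hrf <- double_gamma_hrf(dt = 2)
  patch <- small_patch()
  s <- generate_fast_er_sequence(seed = 11)
  sim <- simulate_run(patch, s, hrf, drift_amplitude = 0, noise_sd = 0)
  ts <- percent_signal_change(sim)
  fit <- fingertip_amplitudes(ts, s, hrf)
  truth <- truth_tuning(patch) / psc_shrinkage(sim)
  resp <- patch$voxels$responsive
  expect_lt(max(abs(fit$betas[resp, 1:5] - truth[resp, ])), 1e-8)
})

test_that("rank-deficient designs are reported with offending columns", {
  ts <- run_timeseries(matrix(rnorm(50), 1, 50))
  X <- cbind(a = rnorm(50), b = rnorm(50))
  X <- cbind(X, c = X[, 1] + X[, 2])
  expect_error(fit_glm(ts, X), "rank deficient")
})

test_that("null t statistics follow Student-t and SEs scale with noise", {
  s <- generate_fast_er_sequence(seed = 12)
  hrf <- double_gamma_hrf(dt = 2)
  X <- build_design(s, "canonical", hrf, intercept = TRUE)
  set.seed(6)
  Y <- matrix(rnorm(10000 * 126), 10000, 126)
  fit <- fit_glm(run_timeseries(Y), X)
  tstat <- fit$betas[, 1] / fit$beta_se[, 1]
  ks <- stats::ks.test(tstat, stats::pt, df = fit$dof)
  expect_gt(ks$p.value, 0.001)
  # doubling the noise SD doubles the SE in expectation
  fit2 <- fit_glm(run_timeseries(2 * Y), X)
  expect_equal(mean(fit2$beta_se[, 1]) / mean(fit$beta_se[, 1]), 2,
               tolerance = 1e-6)
})

test_that("FIR deconvolution recovers the HRF for slow and fast designs", {
  hrf <- double_gamma_hrf(dt = 2)
  patch <- small_patch()
  truth <- truth_tuning(patch)
  for (gen in list(generate_slow_er_sequence, generate_fast_er_sequence)) {
    s <- gen(seed = 13)
    sim <- simulate_run(patch, s, hrf, drift_amplitude = 0, noise_sd = 0)
    ts <- percent_signal_change(sim)
    dec <- estimate_voxel_hrfs(ts, s)
    shrink <- psc_shrinkage(sim)
    v <- which(patch$voxels$responsive)[1]
    pred <- outer(truth[v, ], hrf$samples) / shrink[v]
    expect_lt(max(abs(dec$hrfs[v, , ] - pred)), 1e-8)
  }
})

test_that("fast ER yields smaller estimate SEs than slow ER at matched time", {
  hrf <- double_gamma_hrf(dt = 2)
  cfg <- patch_config(grid_shape = c(8, 15),
    bands = data.frame(label = "BA3b", row_start = 2, row_end = 7,
                       sigma = 1.0),
    noise_sd = 1.5, prop_responsive = 1,
    amplitude_sd = 0.3, sigma_jitter_sd = 0.1)
  patch <- make_somatotopic_patch(cfg, seed = 3)
  run_one <- function(gen, seeds) {
    sims <- lapply(seeds, function(sd) {
      s <- gen(seed = sd)
      list(seq = s, ts = percent_signal_change(
        simulate_run(patch, s, hrf, drift_amplitude = 0, seed = sd + 500)
      ))
    })
    cc <- concatenate_runs(lapply(sims, `[[`, "ts"),
                           lapply(sims, `[[`, "seq"))
    fit <- fingertip_amplitudes(cc$ts, cc$seq, hrf)
    mean(fit$beta_se[, 1:5])
  }
  se_fast <- run_one(generate_fast_er_sequence, 1:2)
  se_slow <- run_one(generate_slow_er_sequence, 3:4)
  expect_lt(se_fast, se_slow)
})

test_that("participant HRF averaging is exact, symmetric and robust to noise", {
  hrf <- double_gamma_hrf(dt = 2)
  patch <- small_patch()
  s <- generate_fast_er_sequence(seed = 14)
  ts <- percent_signal_change(simulate_run(patch, s, hrf,
                                           drift_amplitude = 0, noise_sd = 0))
  dec <- estimate_voxel_hrfs(ts, s)
  resp <- which(patch$voxels$responsive)
  pref <- round(pmin(pmax(patch$voxels$prf_center[resp], 1), 5))
  regions <- split(resp, factor(pref, 1:5))
  doms <- as.integer(names(regions))
  ph <- participant_average_hrf(dec$hrfs, regions, doms)
  expect_equal(ph$samples, hrf$samples, tolerance = 1e-6)
  expect_equal(sum(ph$samples) * 2, 1, tolerance = 1e-9)
  # permuting the regions leaves the average unchanged
  perm <- c(3, 1, 5, 2, 4)
  ph2 <- participant_average_hrf(dec$hrfs, regions[perm], doms[perm])
  expect_equal(ph2$samples, ph$samples, tolerance = 1e-12)
  # empty regions are dropped with a warning; all-empty errors
  expect_warning(
    ph3 <- participant_average_hrf(dec$hrfs, c(regions[1:4], list(integer(0))),
                                   c(doms[1:4], 5L)),
    "empty"
  )
  expect_error(
    suppressWarnings(participant_average_hrf(dec$hrfs, list(integer(0)), 1L)),
    "all regions"
  )
  # noisy recovery stays highly correlated with the truth
  tsn <- percent_signal_change(simulate_run(patch, s, hrf,
                                            drift_amplitude = 0, seed = 20))
  decn <- estimate_voxel_hrfs(tsn, s)
  phn <- participant_average_hrf(decn$hrfs, regions, doms)
  expect_gt(stats::cor(phn$samples, hrf$samples), 0.95)
})

test_that("contrast families behave on delta-tuned and equal-beta voxels", {
  hrf <- double_gamma_hrf(dt = 2)
  patch <- delta_patch(sigma = 0.01)
  s <- generate_fast_er_sequence(seed = 15)
  ts <- percent_signal_change(simulate_run(patch, s, hrf,
                                           drift_amplitude = 0, noise_sd = 0))
  fit <- fingertip_amplitudes(ts, s, hrf)
  # add tiny noise floor so t statistics are finite
  fitn <- fit_glm(run_timeseries(ts$values +
                                   matrix(rnorm(length(ts$values), 0, 1e-6),
                                          nrow(ts$values))), fit$X)
  pref <- compute_contrasts(fitn, "preference")
  vox <- which(patch$voxels$row == 3) # delta voxels, fingertips 1..5
  for (i in seq_along(vox)) {
    expect_equal(which.max(pref$stat[vox[i], ]), i)
    expect_true(all(pref$p[vox[i], i] < 1e-6))
    expect_true(all(pref$stat[vox[i], -i] < 0))
  }
  # flat voxel (background, beta ~ 0): preference t ~ 0
  bg <- which(patch$voxels$row == 1)[1]
  expect_lt(abs(pref$stat[bg, 1]), 5)
  act <- compute_contrasts(fitn, "activation")
  expect_true(all(act$p[cbind(vox, 1:5)] < 1e-6))
})

test_that("F-test type-I error is near nominal on null data", {
  s <- generate_fast_er_sequence(seed = 16)
  X <- build_design(s, "canonical", double_gamma_hrf(dt = 2),
                    intercept = TRUE)
  set.seed(8)
  Y <- matrix(rnorm(5000 * 126), 5000, 126)
  fit <- fit_glm(run_timeseries(Y), X)
  fmap <- compute_contrasts(fit, "main_effect_F")
  rate <- mean(fmap$p < 0.05)
  expect_lt(abs(rate - 0.05), 4 * sqrt(0.05 * 0.95 / 5000))
  fany <- compute_contrasts(fit, "any_positive_F")
  rate2 <- mean(fany$p < 0.05)
  expect_lt(abs(rate2 - 0.05), 4 * sqrt(0.05 * 0.95 / 5000))
})

test_that("BH step-up matches hand computations", {
  expect_true(fdr_step_up(0.04, 0.05)$rejected)
  # thresholds q*i/m = 0.0125, 0.025, 0.0375, 0.05: 0.04 > 0.0375, so only
  # the first two are rejected
  r <- fdr_step_up(c(0.01, 0.02, 0.04, 0.9), 0.05)
  expect_equal(r$rejected, c(TRUE, TRUE, FALSE, FALSE))
  # but 0.0374 <= 0.0375 brings the first three in
  r2 <- fdr_step_up(c(0.01, 0.02, 0.0374, 0.9), 0.05)
  expect_equal(r2$rejected, c(TRUE, TRUE, TRUE, FALSE))
  expect_error(fdr_step_up(c(-0.1, 0.5)), "0, 1")
})

test_that("delay ratio is zero for canonical data and tracks delays", {
  hrf <- double_gamma_hrf(dt = 2)
  patch <- small_patch()
  s <- generate_fast_er_sequence(seed = 17)
  resp <- which(patch$voxels$responsive)
  ratio_for <- function(kernel) {
    ts <- percent_signal_change(simulate_run(patch, s, kernel,
                                             drift_amplitude = 0,
                                             noise_sd = 0))
    stats::median(delay_ratio(ts, s, hrf)[resp], na.rm = TRUE)
  }
  r0 <- ratio_for(hrf)
  expect_lt(abs(r0), 1e-6)
  # HRF shifted 2 s earlier / later (one TR on this grid)
  earlier <- empirical_hrf(c(hrf$samples[-1], 0), dt = 2)
  later <- empirical_hrf(c(0, hrf$samples[-20]), dt = 2)
  r_early <- ratio_for(earlier)
  r_late <- ratio_for(later)
  expect_gt(r_early, 0) # larger ratio = shorter delay
  expect_lt(r_late, 0)
  expect_true(r_late < r0 && r0 < r_early)
})

test_that("beta SE ratio across designs tracks the efficiency prediction", {
  hrf <- double_gamma_hrf(dt = 2)
  cfg <- patch_config(grid_shape = c(4, 10),
    bands = data.frame(label = "BA3b", row_start = 2, row_end = 3,
                       sigma = 1.0),
    noise_sd = 1.5, prop_responsive = 1,
    amplitude_sd = 0.2, sigma_jitter_sd = 0.1)
  patch <- make_somatotopic_patch(cfg, seed = 4)
  nsim <- 100
  mean_se <- function(gen, base_seed) {
    mean(vapply(seq_len(nsim), function(i) {
      s <- gen(seed = base_seed + i)
      ts <- percent_signal_change(
        simulate_run(patch, s, hrf, drift_amplitude = 0,
                     seed = base_seed + 1000 + i)
      )
      mean(fingertip_amplitudes(ts, s, hrf)$beta_se[, 1:5])
    }, numeric(1)))
  }
  se_fast <- mean_se(generate_fast_er_sequence, 0)
  se_slow <- mean_se(generate_slow_er_sequence, 5000)
  eff_fast <- mean(vapply(1:50, function(i) {
    design_efficiencies(generate_fast_er_sequence(seed = i))$detection
  }, numeric(1)))
  eff_slow <- mean(vapply(1:50, function(i) {
    design_efficiencies(generate_slow_er_sequence(seed = i))$detection
  }, numeric(1)))
  predicted <- sqrt(eff_fast / eff_slow)
  observed <- se_slow / se_fast
  expect_lt(abs(observed / predicted - 1), 0.15)
})
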