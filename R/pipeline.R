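#' Pipeline configuration
#'
#' Assembles and validates the configuration for the end-to-end simulated
#' experiment. The defaults mirror the study conditions: TR 2 s, one forward
#' and one reverse 9-cycle phase-encoded localizer, four runs each of the
#' fast and slow ER designs (scan time equated by construction, 126 TRs per
#' run), canonical double-gamma HRF, and 0.05 significance levels for both
#' familywise (phase map) and FDR (ER maps) control.
#'
#' @param seed top-level integer seed; per-stage seeds are derived with
#'   \code{\link{child_seed}}
#' @param patch a \code{\link{patch_config}}
#' @param n_runs_fast,n_runs_slow ER run counts
#' @param n_cycles phase-encoded cycles per run
#' @param n_phase_runs phase-encoded runs per direction (the localizer
#'   aggregates runs across sessions; same-direction runs are averaged
#'   cycle-aligned before the Fourier analysis)
#' @param delay_compensation_trs phase-encoded shift parameter k
#' @param alpha,fdr_q significance levels
#' @param out_dir optional output directory for TSV reports
#' @return list of class \code{pipeline_config}
#' @export
pipeline_config <- function(seed = 1, patch = patch_config(),
                            n_runs_fast = 4, n_runs_slow = 4,
                            n_cycles = 9, n_phase_runs = 3,
                            delay_compensation_trs = 1,
                            alpha = 0.05, fdr_q = 0.05, out_dir = NULL) {
  stopifnot(n_runs_fast >= 1, n_runs_slow >= 1, n_cycles >= 2,
            n_phase_runs >= 1)
  structure(
    list(seed = seed, patch = patch, n_runs_fast = n_runs_fast,
         n_runs_slow = n_runs_slow, n_cycles = n_cycles,
         n_phase_runs = n_phase_runs,
         delay_compensation_trs = delay_compensation_trs,
         alpha = alpha, fdr_q = fdr_q, out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Run the full simulated mapping experiment
#'
#' Simulate a somatotopic patch and all runs; preprocess (percent signal
#' change, 0.01-Hz high pass); analyze the phase-encoded localizer (combine
#' directions, phase/coherence, Hochberg-corrected inference, fingertip
#' region delineation in the primary somatosensory band); run the two-step
#' GLM on the concatenated ER runs; fit voxelwise pRFs; and build recentered
#' ROI tuning curves per area band. Fully deterministic given the config
#' seed.
#'
#' @param cfg a \code{\link{pipeline_config}}
#' @return list with elements \code{patch}, \code{phase} (phase map +
#'   regions), \code{glm} (participant HRF, amplitudes, contrasts),
#'   \code{prf} (voxelwise fits), \code{roi} (per-band recentered tuning
#'   curves and FWHMs), \code{timings} (per-stage seconds)
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  hrf <- double_gamma_hrf(dt = 2)
  patch <- make_somatotopic_patch(cfg$patch, seed = child_seed(cfg$seed, 1))
  timings["patch"] <- tic() - t0

  # --- phase-encoded localizer -------------------------------------------
  t0 <- tic()
  seq_fwd <- generate_phase_encoded_sequence("forward", cfg$n_cycles)
  seq_rev <- generate_phase_encoded_sequence("reverse", cfg$n_cycles)
  avg_direction <- function(s, stage0) {
    runs <- lapply(seq_len(cfg$n_phase_runs), function(r) {
      preprocess_run(simulate_run(patch, s, hrf, steady_state = TRUE,
                                  seed = child_seed(cfg$seed, stage0 + r)))
    })
    vals <- Reduce(`+`, lapply(runs, function(x) x$values)) / length(runs)
    run_timeseries(vals, runs[[1]]$tr, runs[[1]]$units)
  }
  fwd <- avg_direction(seq_fwd, 300)
  rev <- avg_direction(seq_rev, 400)
  combined <- combine_forward_reverse(fwd, rev, cfg$delay_compensation_trs)
  pm <- phase_map(combined, period_s = 20, alpha = cfg$alpha)
  s1_rows <- band_rows(patch, c("BA3b", "BA1", "BA2"))
  pm_s1 <- pm
  pm_s1$fingertip_bin[!patch$voxels$row %in% s1_rows] <- NA
  regions_tab <- delineate_fingertip_regions(pm_s1, patch$grid_shape,
                                             axis = patch$somatotopic_axis)
  regions <- split(regions_tab$voxel, factor(regions_tab$fingertip, 1:5))
  timings["phase"] <- tic() - t0

  # --- event-related runs -------------------------------------------------
  t0 <- tic()
  fast <- simulate_er_runs(patch, "fast", cfg$n_runs_fast, hrf, cfg$seed, 10)
  slow <- simulate_er_runs(patch, "slow", cfg$n_runs_slow, hrf, cfg$seed, 30)
  all_runs <- concatenate_runs(c(fast$ts, slow$ts), c(fast$seqs, slow$seqs))
  timings["simulate_er"] <- tic() - t0

  # --- two-step GLM -------------------------------------------------------
  t0 <- tic()
  dec <- estimate_voxel_hrfs(all_runs$ts, all_runs$seq)
  nonempty <- lengths(regions) > 0
  part_hrf <- participant_average_hrf(dec$hrfs, regions[nonempty],
                                      dominant = (1:5)[nonempty])
  amp <- fingertip_amplitudes(all_runs$ts, all_runs$seq, part_hrf)
  main_f <- compute_contrasts(amp, "main_effect_F")
  anypos_f <- compute_contrasts(amp, "any_positive_F")
  fdr_main <- fdr_step_up(main_f$p, cfg$fdr_q)
  fdr_any <- fdr_step_up(anypos_f$p, cfg$fdr_q)
  timings["glm"] <- tic() - t0

  # --- pRF fitting (thresholded voxels only) ------------------------------
  t0 <- tic()
  fit_mask <- fdr_any$rejected
  prf <- data.frame(center = rep(NA_real_, nrow(amp$betas)),
                    sigma = NA_real_, amplitude = NA_real_, fwhm = NA_real_,
                    rss = NA_real_, responsive = FALSE)
  if (any(fit_mask)) {
    prf[fit_mask, ] <- fit_prf_map(amp$betas[fit_mask, 1:5, drop = FALSE])
  }
  prf$center_masked <- ifelse(fdr_main$rejected, prf$center, NA)
  timings["prf"] <- tic() - t0

  # --- ROI tuning ---------------------------------------------------------
  t0 <- tic()
  pref_from_phase <- phase_to_fingertip(pm$phase)
  roi <- lapply(setdiff(unique(patch$voxels$area), "background"), function(a) {
    vox <- which(patch$voxels$area == a & fit_mask & !is.na(pm$phase))
    if (length(vox) < 5) return(NULL)
    curve <- recenter_and_average(amp$betas[, 1:5], pref_from_phase, vox)
    fw <- fit_tuning_fwhm(curve, "sigma_floor")
    list(area = a, n_voxels = length(vox), curve = curve, fwhm = fw$fwhm,
         mean_prf_sigma = mean(prf$sigma[vox], na.rm = TRUE))
  })
  roi <- Filter(Negate(is.null), roi)
  timings["roi"] <- tic() - t0

  out <- list(
    patch = patch, phase = list(map = pm, regions = regions),
    glm = list(participant_hrf = part_hrf, amplitudes = amp,
               main_effect = main_f, any_positive = anypos_f,
               fdr_main = fdr_main, fdr_any = fdr_any),
    prf = prf, roi = roi, timings = timings, config = cfg
  )
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(out, cfg$out_dir)
  out
}

preprocess_run <- function(ts, cutoff_hz = 0.01) {
  highpass_filter(percent_signal_change(ts), cutoff_hz)
}

band_rows <- function(patch, labels) {
  b <- patch$config$bands
  unlist(lapply(labels, function(l) {
    i <- match(l, b$label)
    if (is.na(i)) integer(0) else b$row_start[i]:b$row_end[i]
  }))
}

simulate_er_runs <- function(patch, kind, n_runs, hrf, seed, stage0) {
  seqs <- list(); tss <- list()
  for (r in seq_len(n_runs)) {
    s <- if (kind == "fast") {
      generate_fast_er_sequence(seed = child_seed(seed, stage0 + 2 * r))
    } else {
      generate_slow_er_sequence(seed = child_seed(seed, stage0 + 2 * r))
    }
    ts <- simulate_run(patch, s, hrf, seed = child_seed(seed, stage0 + 2 * r + 1))
    seqs[[r]] <- s
    tss[[r]] <- preprocess_run(ts)
  }
  list(seqs = seqs, ts = tss)
}

write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE
  )
  wt(cbind(out$patch$voxels[, c("row", "col", "area")], out$phase$map),
     "phase_map.tsv")
  wt(data.frame(out$patch$voxels[, c("row", "col", "area")],
                out$prf, betas = out$glm$amplitudes$betas[, 1:5]),
     "prf_map.tsv")
  roi_tab <- do.call(rbind, lapply(out$roi, function(r) {
    data.frame(area = r$area, n_voxels = r$n_voxels, fwhm = r$fwhm,
               mean_prf_sigma = r$mean_prf_sigma)
  }))
  if (!is.null(roi_tab)) wt(roi_tab, "roi_summary.tsv")
  invisible(dir)
}

#' Reproduce the design-efficiency comparison table
#'
#' Draws random sequences of each design variant, computes their detection,
#' HRF-estimation and difference-detection efficiencies, and summarizes
#' mean and SD per cell. The selected-fast column scores \code{n_select}
#' draws by detection efficiency and keeps the best \code{top_k}.
#'
#' @param n_draws random draws per design
#' @param n_select draws for the selection column
#' @param top_k sequences retained in the selection column
#' @param seed integer seed
#' @return list with \code{table} (data.frame: design x the three
#'   efficiencies, mean and sd) and \code{selected_detection} (mean of the
#'   selected sequences' detection efficiencies)
#' @export
experiment_table1 <- function(n_draws = 1000, n_select = 50000, top_k = 20,
                              seed = 1) {
  hrf <- double_gamma_hrf(dt = 2)
  gens <- list(
    fast_er = function(s) generate_fast_er_sequence(seed = s),
    slow_er = function(s) generate_slow_er_sequence(seed = s),
    fast_er_fullrand = function(s) generate_fullrand_er_sequence(seed = s),
    fast_er_nonull = function(s) generate_nonull_er_sequence(seed = s)
  )
  rows <- list()
  for (nm in names(gens)) {
    effs <- vapply(seq_len(n_draws), function(i) {
      e <- suppressWarnings(
        design_efficiencies(gens[[nm]](child_seed(seed, i * 7 + match(nm, names(gens)))),
                            hrf = hrf)
      )
      c(e$detection, e$hrf_estimation, e$difference_detection)
    }, numeric(3))
    rows[[nm]] <- data.frame(
      design = nm,
      detection = mean(effs[1, ]), detection_sd = stats::sd(effs[1, ]),
      hrf_estimation = mean(effs[2, ]), hrf_estimation_sd = stats::sd(effs[2, ]),
      difference_detection = mean(effs[3, ]),
      difference_detection_sd = stats::sd(effs[3, ])
    )
  }
  sel <- optimize_fast_er(n_select, top_k, seed = child_seed(seed, 999))
  list(
    table = do.call(rbind, c(rows, list(data.frame(
      design = "fast_er_selected",
      detection = mean(sel$efficiencies),
      detection_sd = stats::sd(sel$efficiencies),
      hrf_estimation = NA, hrf_estimation_sd = NA,
      difference_detection = NA, difference_detection_sd = NA
    )))),
    selected_detection = mean(sel$efficiencies)
  )
}

#' Compare fast and slow ER designs at matched scan time
#'
#' Simulates matched-noise, matched-duration fast and slow ER datasets over
#' the same patch, runs the amplitude GLM with the true HRF, and reports the
#' mean voxelwise beta standard error, the mean preferred-fingertip
#' amplitude, and the recentered tuning FWHM for each design, together with
#' the efficiency prediction for the SE ratio.
#'
#' @param cfg a \code{\link{pipeline_config}}
#' @param n_runs runs per design
#' @return data.frame with one row per design plus attributes
#'   \code{se_ratio} (slow/fast) and \code{predicted_se_ratio}
#'   (\code{sqrt(E_fast / E_slow)} from the design efficiencies)
#' @export
experiment_fast_vs_slow <- function(cfg = pipeline_config(), n_runs = 4) {
  hrf <- double_gamma_hrf(dt = 2)
  patch <- make_somatotopic_patch(cfg$patch, seed = child_seed(cfg$seed, 1))
  resp <- which(patch$voxels$responsive)
  truth_pref <- round(pmin(pmax(patch$voxels$prf_center[resp], 1), 5))

  run_design <- function(kind, stage0) {
    sim <- simulate_er_runs(patch, kind, n_runs, hrf, cfg$seed, stage0)
    cat <- concatenate_runs(sim$ts, sim$seqs)
    fit <- fingertip_amplitudes(cat$ts, cat$seq, hrf)
    se <- fit$beta_se[resp, 1:5]
    pref_amp <- fit$betas[cbind(resp, truth_pref)]
    curve <- recenter_and_average(fit$betas[, 1:5],
                                  round(pmin(pmax(patch$voxels$prf_center, 1), 5)),
                                  resp)
    fw <- fit_tuning_fwhm(curve, "offset_nonpositive")
    eff <- mean(vapply(sim$seqs, function(s) {
      design_efficiencies(s, hrf = hrf)$detection
    }, numeric(1)))
    list(mean_se = mean(se), mean_pref_amp = mean(pref_amp),
         fwhm = fw$fwhm, detection = eff)
  }
  fast <- run_design("fast", 100)
  slow <- run_design("slow", 200)
  out <- data.frame(
    design = c("fast_er", "slow_er"),
    mean_beta_se = c(fast$mean_se, slow$mean_se),
    mean_preferred_amplitude = c(fast$mean_pref_amp, slow$mean_pref_amp),
    tuning_fwhm = c(fast$fwhm, slow$fwhm),
    detection_efficiency = c(fast$detection, slow$detection)
  )
  attr(out, "se_ratio") <- slow$mean_se / fast$mean_se
  attr(out, "predicted_se_ratio") <- sqrt(fast$detection / slow$detection)
  out
}
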