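#' Combine forward and reverse phase-encoded runs
#'
#' Compensates the hemodynamic delay and averages the two stimulation
#' directions: the forward-order run is circularly shifted backwards by
#' \code{k} TRs; the reverse-order run is shifted backwards by \code{k + 1}
#' TRs and time-reversed (array reversal, mapping sample \code{n} to
#' \code{-n - 1} modulo the run length; the combined index is therefore
#' \code{k - n}, and this alignment is what makes the construction exact);
#' the two series are then averaged samplewise.
#'
#' Because any residual response delay enters the two directions with
#' opposite signs, it cancels exactly in the average's phase: a voxel
#' preferring fingertip \code{i} lands on phase \code{(2i - 1) * pi / 5}
#' regardless of the hemodynamic delay.
#'
#' @param fwd \code{run_timeseries} of the forward (thumb-to-pinky) run
#' @param rev \code{run_timeseries} of the reverse run, same shape
#' @param k integer delay compensation in TRs (typically 1 or 2)
#' @return averaged \code{run_timeseries}
#' @export
combine_forward_reverse <- function(fwd, rev, k) {
  if (!all(dim(fwd$values) == dim(rev$values))) {
    stop("forward and reverse runs must have identical dimensions")
  }
  n <- ncol(fwd$values)
  idx_fwd <- ((seq_len(n) - 1 + k) %% n) + 1
  idx_rev <- ((k - (seq_len(n) - 1)) %% n) + 1
  run_timeseries(
    (fwd$values[, idx_fwd, drop = FALSE] + rev$values[, idx_rev, drop = FALSE]) / 2,
    fwd$tr, fwd$units, fwd$run_boundaries
  )
}

#' Fourier phase and coherence at the stimulation frequency
#'
#' For each voxel, computes the phase of the Fourier component at the
#' stimulation frequency (1 / \code{period_s}; 0.05 Hz for a 20-s cycle) and
#' its coherence: the amplitude at that frequency divided by the
#' root-sum-square of amplitudes at all nonzero frequencies. The phase
#' convention places a cosine peaking at cycle time \code{t0} at phase
#' \code{2 pi t0 / period}, so fingertips 1-5 map to odd multiples of
#' \code{pi / 5}. Constant voxels have coherence 0 and undefined (NA) phase.
#'
#' @param ts \code{run_timeseries} whose length is an integer number of cycles
#' @param period_s stimulation period, seconds
#' @return data.frame with columns \code{phase} (radians in [0, 2 pi)) and
#'   \code{coherence} (in [0, 1])
#' @export
phase_coherence <- function(ts, period_s = 20) {
  n <- ncol(ts$values)
  cycle_trs <- period_s / ts$tr
  if (abs(n / cycle_trs - round(n / cycle_trs)) > 1e-9) {
    stop("run length must be an integer number of stimulation cycles")
  }
  target_bin <- n / cycle_trs # index of the stimulation frequency in the DFT
  x <- ts$values - rowMeans(ts$values)
  F <- t(apply(x, 1, stats::fft))
  half <- 2:(floor(n / 2) + 1)
  amp2 <- abs(F[, half, drop = FALSE])^2
  target_amp <- abs(F[, target_bin + 1])
  total <- sqrt(rowSums(amp2))
  coherence <- ifelse(total > 0, target_amp / total, 0)
  phase <- (-Arg(F[, target_bin + 1])) %% (2 * pi)
  phase[total == 0 | target_amp == 0] <- NA_real_
  data.frame(phase = phase, coherence = coherence)
}

#' Convert coherence to a p-value
#'
#' Under independent Gaussian noise, the squared coherence is the R-squared
#' of a sine-plus-cosine regression at the target frequency, so
#' \deqn{F = (C^2/2) / ((1 - C^2)/(n - 3))} follows an F(2, n-3) distribution
#' under the null of no periodic response.
#'
#' @param coherence coherence value(s) in [0, 1]
#' @param n_samples number of time samples
#' @return p-value(s), decreasing in coherence
#' @export
coherence_p_value <- function(coherence, n_samples) {
  if (n_samples <= 3) stop("need more than 3 samples for the F test")
  c2 <- pmin(coherence^2, 1)
  f <- (c2 / 2) / ((1 - c2) / (n_samples - 3))
  p <- stats::pf(f, 2, n_samples - 3, lower.tail = FALSE)
  p[c2 >= 1] <- 0
  p
}

#' Stagewise Bonferroni (Hochberg step-up) correction
#'
#' Hochberg's step-up procedure: with ordered p-values p(1) <= ... <= p(m),
#' reject all hypotheses up to the largest i with
#' p(i) <= alpha / (m - i + 1). Controls the familywise error rate for
#' independent or positively dependent tests.
#'
#' @param p_values vector of p-values in [0, 1]
#' @param alpha familywise error level
#' @return logical rejection mask aligned with \code{p_values}
#' @export
stagewise_bonferroni <- function(p_values, alpha = 0.05) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  rej <- rep(FALSE, length(p_values))
  rej[ok] <- stats::p.adjust(p_values[ok], method = "hochberg") <= alpha
  rej
}

#' Assign phases to fingertip bins
#'
#' Divides [0, 2 pi) into five contiguous bins of width 2 pi / 5 centered on
#' the exact fingertip phases (2i - 1) pi / 5, so bin i covers
#' ((2i - 2) pi / 5, 2i pi / 5].
#'
#' @param phase radians in [0, 2 pi)
#' @return integer fingertip bin 1-5 (NA where phase is NA)
#' @export
phase_to_fingertip <- function(phase) {
  bin <- ceiling((phase %% (2 * pi)) / (2 * pi / 5))
  bin[bin == 0] <- 1L
  as.integer(pmin(bin, 5L))
}

#' Phase-encoded map with corrected inference
#'
#' Convenience wrapper: phase and coherence per voxel, F-test p-values,
#' Hochberg correction across all supplied voxels, and fingertip bins for
#' suprathreshold voxels.
#'
#' @param ts combined \code{run_timeseries} (see
#'   \code{\link{combine_forward_reverse}})
#' @param period_s stimulation period, seconds
#' @param alpha corrected significance level
#' @return data.frame with \code{phase}, \code{coherence}, \code{p_value},
#'   \code{significant}, \code{fingertip_bin} (NA below threshold)
#' @export
phase_map <- function(ts, period_s = 20, alpha = 0.05) {
  pc <- phase_coherence(ts, period_s)
  pc$p_value <- coherence_p_value(pc$coherence, ncol(ts$values))
  pc$significant <- stagewise_bonferroni(pc$p_value, alpha)
  pc$fingertip_bin <- ifelse(pc$significant, phase_to_fingertip(pc$phase), NA)
  pc
}

# 4-connected components of a logical mask on a grid; returns an integer
# label vector (0 = background) in row-major voxel order matching
# cortical_patch$voxels.
grid_components <- function(mask, grid_shape) {
  nr <- grid_shape[1]; nc <- grid_shape[2]
  stopifnot(length(mask) == nr * nc)
  lab <- integer(length(mask))
  cur <- 0L
  idx_of <- function(r, c) (r - 1L) * nc + c
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      r <- (v - 1L) %/% nc + 1L
      c <- (v - 1L) %% nc + 1L
      for (nb in list(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))) {
        if (nb[1] >= 1 && nb[1] <= nr && nb[2] >= 1 && nb[2] <= nc) {
          w <- idx_of(nb[1], nb[2])
          if (mask[w] && lab[w] == 0L) {
            lab[w] <- cur
            queue <- c(queue, w)
          }
        }
      }
    }
  }
  lab
}

#' Delineate fingertip-specific regions from a phase map
#'
#' Bins suprathreshold voxels into the five fingertip phase bins, extracts
#' 4-connected clusters per bin, and retains per bin the largest cluster
#' provided the clusters' centroids progress monotonically along the
#' somatotopic axis; isolated out-of-order clusters are dropped.
#'
#' @param pm data.frame from \code{\link{phase_map}} in row-major grid order
#' @param grid_shape c(rows, cols)
#' @param axis \code{"col"} (default) or \code{"row"}: direction along which
#'   the fingertip progression is expected
#' @return data.frame with one row per retained voxel: \code{voxel} (index),
#'   \code{fingertip}, \code{cluster}; zero rows if nothing survives
#' @export
delineate_fingertip_regions <- function(pm, grid_shape, axis = "col") {
  nr <- grid_shape[1]; nc <- grid_shape[2]
  coord <- if (axis == "col") {
    rep(seq_len(nc), times = nr)
  } else {
    rep(seq_len(nr), each = nc)
  }
  picks <- list()
  centroids <- rep(NA_real_, 5)
  for (f in 1:5) {
    mask <- !is.na(pm$fingertip_bin) & pm$fingertip_bin == f
    lab <- grid_components(mask, grid_shape)
    if (all(lab == 0L)) next
    sizes <- tabulate(lab)
    main <- which.max(sizes)
    vox <- which(lab == main)
    picks[[f]] <- vox
    centroids[f] <- mean(coord[vox])
  }
  present <- which(!is.na(centroids))
  if (length(present) >= 2) {
    # enforce monotone progression: greedily drop fingertips whose centroid
    # breaks the ordering along the axis
    keep <- present
    repeat {
      d <- diff(centroids[keep])
      bad <- which(d <= 0)
      if (length(bad) == 0) break
      keep <- keep[-(bad[1] + 1)]
    }
    drop <- setdiff(present, keep)
    for (f in drop) picks[f] <- list(NULL)
  }
  out <- do.call(rbind, lapply(1:5, function(f) {
    if (f > length(picks) || is.null(picks[[f]])) return(NULL)
    data.frame(voxel = picks[[f]], fingertip = f, cluster = f)
  }))
  if (is.null(out)) {
    out <- data.frame(voxel = integer(0), fingertip = integer(0),
                      cluster = integer(0))
  }
  out
}
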