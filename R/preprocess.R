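#' Construct a run timeseries
#'
#' Voxels-by-TRs container shared by simulation, preprocessing and analysis.
#'
#' @param values numeric matrix, voxels x TRs
#' @param tr TR duration, seconds
#' @param units \code{"raw"} or \code{"percent_signal_change"}
#' @param run_boundaries 0-based TR indices at which runs start
#' @return an object of class \code{run_timeseries}
#' @export
run_timeseries <- function(values, tr = 2, units = "raw", run_boundaries = 0L) {
  values <- as.matrix(values)
  structure(
    list(values = values, tr = tr, units = units,
         run_boundaries = as.integer(run_boundaries)),
    class = "run_timeseries"
  )
}

#' @export
print.run_timeseries <- function(x, ...) {
  cat(sprintf(
    "<run_timeseries: %d voxels x %d TRs (%s), %d run(s)>\n",
    nrow(x$values), ncol(x$values), x$units, length(x$run_boundaries)
  ))
  invisible(x)
}

# Discrete-cosine basis spanning frequencies below `cutoff_hz` (plus DC) for a
# segment of `n` samples at `tr` seconds.
dct_lowfreq_basis <- function(n, tr, cutoff_hz) {
  kmax <- floor(2 * n * tr * cutoff_hz)
  t <- seq_len(n) - 0.5
  B <- matrix(1 / sqrt(n), n, 1)
  if (kmax >= 1) {
    B <- cbind(B, vapply(seq_len(kmax), function(k) {
      sqrt(2 / n) * cos(pi * k * t / n)
    }, numeric(n)))
  }
  B
}

#' High-pass filter a timeseries
#'
#' Removes slow drift by projecting out the discrete-cosine components below
#' \code{cutoff_hz} (and the mean), per run. This is the exact, phase-free
#' drift filter standard in fMRI analysis; frequencies at or below the cutoff
#' are attenuated essentially completely and pass-band frequencies are
#' untouched.
#'
#' @param ts a \code{run_timeseries}
#' @param cutoff_hz high-pass cutoff in Hz (must be below Nyquist)
#' @return filtered \code{run_timeseries}
#' @export
highpass_filter <- function(ts, cutoff_hz = 0.01) {
  nyquist <- 1 / (2 * ts$tr)
  if (cutoff_hz >= nyquist) {
    stop(sprintf("cutoff (%g Hz) must be below Nyquist (%g Hz)", cutoff_hz, nyquist))
  }
  n <- ncol(ts$values)
  starts <- c(ts$run_boundaries, n)
  out <- ts$values
  for (r in seq_len(length(starts) - 1)) {
    idx <- (starts[r] + 1L):starts[r + 1L]
    B <- dct_lowfreq_basis(length(idx), ts$tr, cutoff_hz)
    seg <- out[, idx, drop = FALSE]
    out[, idx] <- seg - (seg %*% B) %*% t(B)
  }
  run_timeseries(out, ts$tr, ts$units, ts$run_boundaries)
}

#' Convert a timeseries to percent signal change
#'
#' Each voxel is rescaled as \code{100 * (x - mean) / mean} using its
#' (pre-filtering) run mean. Voxels with non-positive means cannot be
#' expressed as percent change; they are flagged and their rows set to
#' \code{NA}.
#'
#' @param ts a \code{run_timeseries} in raw units
#' @return \code{run_timeseries} in percent-signal-change units, with a
#'   logical attribute \code{"masked"} marking unusable voxels
#' @export
percent_signal_change <- function(ts) {
  if (ts$units == "percent_signal_change") return(ts)
  n <- ncol(ts$values)
  starts <- c(ts$run_boundaries, n)
  out <- ts$values
  masked <- rep(FALSE, nrow(out))
  for (r in seq_len(length(starts) - 1)) {
    idx <- (starts[r] + 1L):starts[r + 1L]
    m <- rowMeans(ts$values[, idx, drop = FALSE])
    bad <- m <= 0
    masked <- masked | bad
    m[bad] <- NA_real_
    out[, idx] <- 100 * (ts$values[, idx, drop = FALSE] - m) / m
  }
  if (any(masked)) {
    warning(sprintf("%d voxel(s) with non-positive mean masked", sum(masked)))
  }
  res <- run_timeseries(out, ts$tr, "percent_signal_change", ts$run_boundaries)
  attr(res, "masked") <- masked
  res
}

#' Concatenate runs for joint analysis
#'
#' Stacks timeseries along time and offsets each sequence's onsets by the
#' cumulative TR count. Run boundaries are recorded on both outputs so that
#' design construction restarts the HRF convolution at each boundary and
#' per-run intercepts can be modelled.
#'
#' @param ts_list list of \code{run_timeseries} with equal voxel counts
#' @param seq_list list of \code{event_sequence}, one per run
#' @return list with elements \code{ts} and \code{seq}
#' @export
concatenate_runs <- function(ts_list, seq_list) {
  stopifnot(length(ts_list) == length(seq_list))
  nv <- vapply(ts_list, function(t) nrow(t$values), integer(1))
  if (length(unique(nv)) != 1) stop("voxel counts differ across runs")
  trs <- vapply(ts_list, function(t) t$tr, numeric(1))
  stopifnot(length(unique(trs)) == 1)
  lens <- vapply(seq_list, function(s) s$n_TRs, integer(1))
  for (i in seq_along(ts_list)) {
    if (ncol(ts_list[[i]]$values) != lens[i]) {
      stop("timeseries and sequence TR counts differ in run ", i)
    }
  }
  offsets <- cumsum(c(0L, lens[-length(lens)]))
  values <- do.call(cbind, lapply(ts_list, function(t) t$values))
  onsets <- unlist(mapply(function(s, o) s$onsets + o,
                          seq_list, offsets, SIMPLIFY = FALSE))
  conds <- unlist(lapply(seq_list, function(s) s$conditions))
  seq <- event_sequence(onsets, conds, sum(lens), tr = trs[1],
                        kind = seq_list[[1]]$kind)
  seq$run_boundaries <- offsets
  ts <- run_timeseries(values, trs[1], ts_list[[1]]$units, offsets)
  list(ts = ts, seq = seq)
}
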