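#' Default configuration for a synthetic somatotopic patch
#'
#' Describes a 2D cortical patch (rows x columns of voxels) containing
#' parallel area bands. Within each band, preferred fingertips (pRF centers)
#' increase monotonically along the somatotopic axis (columns), spanning the
#' full [0.5, 5.5] fingertip range; tuning width (pRF sigma) increases from
#' BA3b toward BA2 and post-BA2, and from BA4a toward BA6, with post-BA2 and
#' BA6 carrying near-flat tuning. Amplitudes target roughly 1% peak signal
#' change: responses are expressed in units of the unit-integral HRF
#' regressor, whose isolated-event peak is about 0.39, so the default
#' amplitude 2.5 gives a peak response near 0.97% for a perfectly preferred
#' fingertip.
#'
#' @param grid_shape c(rows, cols) of the voxel grid
#' @param bands data.frame with columns \code{label}, \code{row_start},
#'   \code{row_end}, \code{sigma} (band-mean pRF spread, fingertip units)
#' @param amplitude mean response amplitude (unit-integral HRF regressor units)
#' @param amplitude_sd across-voxel SD of amplitude
#' @param sigma_jitter_sd lognormal SD of voxelwise sigma around the band mean
#' @param baseline raw signal baseline (arbitrary scanner units)
#' @param noise_sd white-noise SD in percent signal change per TR
#' @param prop_responsive proportion of in-band voxels that respond at all
#' @return a list of class \code{patch_config}
#' @export
patch_config <- function(grid_shape = c(40, 40),
                         bands = default_bands(),
                         amplitude = 2.5, amplitude_sd = 0.3,
                         sigma_jitter_sd = 0.15,
                         baseline = 1000, noise_sd = 1.5,
                         prop_responsive = 0.85) {
  cfg <- list(
    grid_shape = grid_shape, bands = bands, amplitude = amplitude,
    amplitude_sd = amplitude_sd, sigma_jitter_sd = sigma_jitter_sd,
    baseline = baseline, noise_sd = noise_sd,
    prop_responsive = prop_responsive
  )
  if (any(bands$row_end > grid_shape[1]) || any(bands$row_start < 1)) {
    stop("band rows exceed the grid")
  }
  if (any(bands$row_start > bands$row_end)) stop("band rows inverted")
  if (any(bands$sigma <= 0)) stop("band sigma must be positive")
  class(cfg) <- "patch_config"
  cfg
}

#' @rdname patch_config
#' @export
default_bands <- function() {
  data.frame(
    label = c("BA3b", "BA1", "BA2", "post_BA2", "BA4a", "BA6"),
    row_start = c(5, 9, 13, 17, 25, 29),
    row_end = c(8, 12, 16, 20, 28, 32),
    sigma = c(0.8, 1.5, 3.0, 20, 1.0, 8.0),
    stringsAsFactors = FALSE
  )
}

#' Gaussian fingertip tuning curve
#'
#' Unit-peak Gaussian over fingertip index, \code{exp(-(f - center)^2 /
#' (2 sigma^2))}, evaluated at fingertips \code{f}.
#'
#' @param f fingertip indices (typically 1:5)
#' @param center pRF center, fingertip units
#' @param sigma pRF spread, fingertip units
#' @return numeric vector of tuning weights in (0, 1]
#' @export
gaussian_tuning <- function(f, center, sigma) {
  exp(-(f - center)^2 / (2 * sigma^2))
}

#' Generate a synthetic somatotopic cortical patch
#'
#' Lays out ground-truth voxel pRFs on a grid according to a
#' \code{\link{patch_config}}: monotone center progressions along the
#' somatotopic axis inside each band, band-specific tuning widths, and a
#' non-responsive background.
#'
#' @param config a \code{patch_config}
#' @param seed integer seed
#' @return an object of class \code{cortical_patch}: list with
#'   \code{grid_shape}, \code{somatotopic_axis} (\code{"col"}) and
#'   \code{voxels}, a data.frame with one row per grid cell (row-major order)
#'   holding \code{row}, \code{col}, \code{area}, \code{prf_center},
#'   \code{prf_sigma}, \code{amplitude}, \code{baseline}, \code{noise_sd},
#'   \code{responsive}
#' @export
make_somatotopic_patch <- function(config = patch_config(), seed = NULL) {
  with_seed(seed, {
    nr <- config$grid_shape[1]
    nc <- config$grid_shape[2]
    vox <- expand.grid(col = seq_len(nc), row = seq_len(nr))[, 2:1]
    vox$area <- "background"
    for (b in seq_len(nrow(config$bands))) {
      band <- config$bands[b, ]
      vox$area[vox$row >= band$row_start & vox$row <= band$row_end] <- band$label
    }
    # centers: linear in column position, spanning [0.5, 5.5] per band
    vox$prf_center <- 0.5 + 5 * (vox$col - 0.5) / nc
    vox$prf_sigma <- NA_real_
    for (b in seq_len(nrow(config$bands))) {
      band <- config$bands[b, ]
      sel <- vox$area == band$label
      vox$prf_sigma[sel] <- band$sigma *
        exp(stats::rnorm(sum(sel), 0, config$sigma_jitter_sd))
    }
    vox$responsive <- vox$area != "background" &
      stats::runif(nrow(vox)) < config$prop_responsive
    vox$amplitude <- ifelse(
      vox$responsive,
      pmax(0.5, stats::rnorm(nrow(vox), config$amplitude, config$amplitude_sd)),
      0
    )
    vox$prf_center[!vox$responsive & vox$area == "background"] <- NA_real_
    vox$prf_sigma[vox$area == "background"] <- NA_real_
    vox$baseline <- config$baseline
    vox$noise_sd <- config$noise_sd
    structure(
      list(grid_shape = config$grid_shape, somatotopic_axis = "col",
           voxels = vox, config = config),
      class = "cortical_patch"
    )
  })
}

#' @export
print.cortical_patch <- function(x, ...) {
  cat(sprintf(
    "<cortical_patch %dx%d: %d responsive voxels in %d bands>\n",
    x$grid_shape[1], x$grid_shape[2], sum(x$voxels$responsive),
    length(setdiff(unique(x$voxels$area), "background"))
  ))
  invisible(x)
}

#' Simulate a BOLD run over a synthetic patch
#'
#' Forward model inverting the analysis assumptions: each voxel's clean
#' response (percent signal change) is the sum over fingertips of
#' \code{amplitude * G(f; center, sigma)} times the fingertip's
#' canonical-HRF-convolved regressor; drift (a random sum of discrete-cosine
#' components below 0.01 Hz) and white Gaussian noise are added in percent
#' units and the whole expressed around the voxel baseline:
#' \code{baseline * (1 + (response + drift + noise) / 100)}.
#'
#' @param patch a \code{cortical_patch}
#' @param seq an \code{event_sequence}
#' @param hrf \code{hrf_model} used for the forward convolution
#' @param drift_amplitude SD of each low-frequency drift coefficient, percent
#' @param seed integer seed
#' @param noise_sd override the patch's per-voxel noise SD (percent); use 0
#'   for noiseless data
#' @param hrf_delay_jitter_s optional per-voxel uniform HRF onset jitter
#'   (+/- this many seconds, rounded to the TR grid); default off
#' @param steady_state use circular convolution, appropriate for cyclic
#'   (phase-encoded) stimulation where the run samples an ongoing periodic
#'   response rather than a response starting from rest
#' @return a \code{run_timeseries} in raw units with attribute
#'   \code{"clean_percent"} (the noiseless response, for reference)
#' @export
simulate_run <- function(patch, seq, hrf = double_gamma_hrf(dt = seq$tr),
                         drift_amplitude = 0.5, seed = NULL,
                         noise_sd = NULL, hrf_delay_jitter_s = 0,
                         steady_state = FALSE) {
  with_seed(seed, {
    X <- if (steady_state) {
      circular_design(seq, hrf)
    } else {
      build_design(seq, "canonical", hrf)
    }
    n <- seq$n_TRs
    vox <- patch$voxels
    nv <- nrow(vox)
    tuning <- matrix(0, nv, 5)
    resp <- which(vox$responsive)
    for (f in 1:5) {
      tuning[resp, f] <- vox$amplitude[resp] *
        gaussian_tuning(f, vox$prf_center[resp], vox$prf_sigma[resp])
    }
    clean <- tuning %*% t(X)
    if (hrf_delay_jitter_s > 0) {
      shift_trs <- round(stats::runif(nv, -hrf_delay_jitter_s,
                                      hrf_delay_jitter_s) / seq$tr)
      for (v in resp) {
        if (shift_trs[v] != 0) {
          clean[v, ] <- shift_pad(clean[v, ], shift_trs[v])
        }
      }
    }
    pct <- clean
    if (drift_amplitude > 0) {
      B <- dct_lowfreq_basis(n, seq$tr, 0.01)[, -1, drop = FALSE]
      if (ncol(B) > 0) {
        coefs <- matrix(stats::rnorm(nv * ncol(B), 0, drift_amplitude),
                        nv, ncol(B))
        pct <- pct + coefs %*% t(B) * sqrt(n)
      }
    }
    sd_use <- noise_sd %||% vox$noise_sd
    if (any(sd_use > 0)) {
      pct <- pct + matrix(stats::rnorm(nv * n, 0, 1), nv, n) * sd_use
    }
    values <- vox$baseline * (1 + pct / 100)
    out <- run_timeseries(values, seq$tr, "raw")
    attr(out, "clean_percent") <- clean
    out
  })
}

# Canonical design built with circular convolution: the steady-state
# response to a periodic stimulus observed over an integer number of cycles.
circular_design <- function(seq, hrf) {
  n <- seq$n_TRs
  ev <- matrix(0, n, 5)
  keep <- seq$conditions > 0
  ev[cbind(seq$onsets[keep] + 1L, seq$conditions[keep])] <- 1
  kern <- c(hrf$samples, rep(0, n - length(hrf$samples)))
  K <- stats::fft(kern)
  X <- seq$tr * Re(stats::mvfft(stats::mvfft(ev) * K, inverse = TRUE)) / n
  colnames(X) <- paste0("finger", 1:5)
  X
}

shift_pad <- function(x, k) {
  n <- length(x)
  if (k > 0) c(rep(0, k), x[seq_len(n - k)])
  else if (k < 0) c(x[(-k + 1):n], rep(0, -k))
  else x
}
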