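#' Double-gamma hemodynamic response function
#'
#' Samples the canonical HRF modelled as a difference of two gamma densities,
#' with the positive peak at \code{peak1_delay} seconds, the undershoot peak at
#' \code{undershoot_delay} seconds, and the undershoot scaled by
#' \code{1/peak_ratio}. Gamma densities are parameterized with
#' \code{shape = delay + 1, scale = 1} so that each density's mode falls
#' exactly at the stated delay.
#'
#' @param peak1_delay delay of the first (positive) peak, seconds
#' @param undershoot_delay delay of the (negative) undershoot peak, seconds
#' @param peak_ratio ratio of positive to negative peak amplitude
#' @param dt sampling interval in seconds (typically one TR)
#' @param duration total sampled duration in seconds
#' @param normalization \code{"unit_integral"} scales so that
#'   \code{sum(samples) * dt == 1}; \code{"unit_peak"} scales to maximum 1.
#' @return an object of class \code{hrf_model} with elements \code{samples},
#'   \code{dt}, \code{normalization} and \code{params}
#' @examples
#' h <- double_gamma_hrf()
#' which.max(h$samples) # peak at t = 6 s on a 2-s grid
#' @export
double_gamma_hrf <- function(peak1_delay = 6, undershoot_delay = 16,
                             peak_ratio = 6, dt = 2, duration = 40,
                             normalization = c("unit_integral", "unit_peak")) {
  normalization <- match.arg(normalization)
  if (dt <= 0) stop("dt must be positive")
  if (peak1_delay <= 0 || undershoot_delay <= 0) {
    stop("HRF peak delays must be positive")
  }
  t <- seq(0, duration - dt, by = dt)
  h <- stats::dgamma(t, shape = peak1_delay + 1, scale = 1) -
    stats::dgamma(t, shape = undershoot_delay + 1, scale = 1) / peak_ratio
  h <- switch(normalization,
    unit_integral = h / (sum(h) * dt),
    unit_peak = h / max(h)
  )
  structure(
    list(
      samples = h, dt = dt, normalization = normalization,
      params = list(
        peak1_delay = peak1_delay, undershoot_delay = undershoot_delay,
        peak_ratio = peak_ratio, duration = duration
      ),
      kind = "double_gamma"
    ),
    class = "hrf_model"
  )
}

#' Construct an HRF model from measured samples
#'
#' Wraps an empirical response (e.g. a participant-average FIR estimate) as an
#' \code{hrf_model} usable wherever the canonical HRF is.
#'
#' @param samples response values at \code{dt} spacing, starting at lag 0
#' @param dt sampling interval, seconds
#' @param normalization \code{"unit_integral"} (default) or \code{"unit_peak"}
#' @return an \code{hrf_model}
#' @export
empirical_hrf <- function(samples, dt = 2,
                          normalization = c("unit_integral", "unit_peak")) {
  normalization <- match.arg(normalization)
  samples <- switch(normalization,
    unit_integral = samples / (sum(samples) * dt),
    unit_peak = samples / max(samples)
  )
  structure(
    list(samples = samples, dt = dt, normalization = normalization,
         params = list(), kind = "empirical"),
    class = "hrf_model"
  )
}

#' Temporal derivative of a sampled HRF
#'
#' First difference of the sampled HRF (padded with a trailing zero), the
#' standard finite-difference proxy for the response's sensitivity to a small
#' latency shift.
#'
#' @param hrf an \code{hrf_model}
#' @return numeric vector of the same length as \code{hrf$samples}
#' @export
hrf_derivative <- function(hrf) {
  c(diff(hrf$samples), 0)
}

# Causal discrete convolution truncated to the input length.
convolve_events <- function(x, kernel) {
  stats::convolve(x, rev(kernel), type = "open")[seq_along(x)]
}

#' Build a GLM design matrix from an event sequence
#'
#' Builds the TR-resolution design matrix for a stimulation sequence under one
#' of three bases. Regressors approximate continuous-time convolution
#' integrals: events are unit-area impulses, so every regressor carries a
#' factor of the TR duration. With a unit-integral HRF an isolated event's
#' canonical regressor integrates to one. Null events contribute nothing.
#'
#' For sequences carrying run boundaries (see \code{\link{concatenate_runs}})
#' the convolution restarts at every boundary, and \code{intercept = TRUE}
#' adds one intercept column per run.
#'
#' @param seq an \code{\link{event_sequence}}
#' @param basis \code{"canonical"} (5 columns), \code{"canonical_plus_derivative"}
#'   (10 columns: 5 canonical then 5 derivative), or \code{"fir"}
#'   (\code{5 * n_fir_points} columns of shifted unit-area impulses)
#' @param hrf an \code{hrf_model}; ignored for \code{basis = "fir"}
#' @param n_fir_points number of FIR lags per fingertip
#' @param intercept add per-run intercept column(s)
#' @return numeric matrix with \code{attr "labels"} and \code{attr "basis"};
#'   intercept columns are labelled \code{run<k>_intercept}
#' @export
build_design <- function(seq, basis = c("canonical", "canonical_plus_derivative", "fir"),
                         hrf = double_gamma_hrf(dt = seq$tr),
                         n_fir_points = 20, intercept = FALSE) {
  basis <- match.arg(basis)
  if (length(seq$conditions) == 0 || all(seq$conditions == 0)) {
    stop("event sequence has no stimulation events")
  }
  bounds <- seq$run_boundaries %||% 0L
  n <- seq$n_TRs
  dt <- seq$tr
  starts <- c(bounds, n)
  n_runs <- length(bounds)

  ev <- matrix(0, n, 5)
  keep <- seq$conditions > 0
  ev[cbind(seq$onsets[keep] + 1L, seq$conditions[keep])] <- 1

  per_run <- function(build_one) {
    out <- NULL
    for (r in seq_len(n_runs)) {
      idx <- (starts[r] + 1L):starts[r + 1L]
      out <- rbind(out, build_one(ev[idx, , drop = FALSE]))
    }
    out
  }

  canon_block <- function(kernel) {
    per_run(function(e) dt * apply(e, 2, convolve_events, kernel = kernel))
  }

  if (basis == "canonical") {
    X <- canon_block(hrf$samples)
    labels <- paste0("finger", 1:5)
  } else if (basis == "canonical_plus_derivative") {
    X <- cbind(canon_block(hrf$samples), canon_block(hrf_derivative(hrf) / dt))
    labels <- c(paste0("finger", 1:5), paste0("finger", 1:5, "_deriv"))
  } else {
    X <- per_run(function(e) {
      nr <- nrow(e)
      Xf <- matrix(0, nr, 5 * n_fir_points)
      for (f in 1:5) {
        for (k in 0:(n_fir_points - 1)) {
          Xf[, (f - 1) * n_fir_points + k + 1] <-
            c(rep(0, k), e[seq_len(nr - k), f])
        }
      }
      dt * Xf
    })
    labels <- paste0(
      "finger", rep(1:5, each = n_fir_points),
      "_lag", rep(0:(n_fir_points - 1), 5)
    )
  }

  if (intercept) {
    ic <- matrix(0, n, n_runs)
    for (r in seq_len(n_runs)) ic[(starts[r] + 1L):starts[r + 1L], r] <- 1
    X <- cbind(X, ic)
    labels <- c(labels, paste0("run", seq_len(n_runs), "_intercept"))
  }
  colnames(X) <- labels
  attr(X, "basis") <- basis
  attr(X, "labels") <- labels
  X
}
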