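#' Construct an event sequence
#'
#' The shared container for all stimulation designs: a run of \code{n_TRs}
#' volumes at \code{tr} seconds each, with fingertip events (conditions 1-5,
#' thumb = 1 to pinky = 5) or null events (condition 0) whose onsets coincide
#' with volume acquisitions.
#'
#' @param onsets integer onsets in TRs (0-based), strictly increasing
#' @param conditions integer conditions in 0:5 (0 = null event)
#' @param n_TRs run length in TRs
#' @param tr TR duration, seconds
#' @param kind design label, e.g. \code{"fast_er"}, \code{"slow_er"},
#'   \code{"phase_fwd"}, \code{"phase_rev"}
#' @return an object of class \code{event_sequence}
#' @export
event_sequence <- function(onsets, conditions, n_TRs, tr = 2, kind = "custom") {
  onsets <- as.integer(onsets)
  conditions <- as.integer(conditions)
  if (length(onsets) != length(conditions)) {
    stop("onsets and conditions must have equal length")
  }
  if (any(diff(onsets) <= 0)) stop("onsets must be strictly increasing")
  if (any(onsets < 0L) || any(onsets >= n_TRs)) {
    stop("onsets must lie in [0, n_TRs)")
  }
  if (any(!conditions %in% 0:5)) stop("conditions must be in 0:5")
  structure(
    list(onsets = onsets, conditions = conditions,
         n_TRs = as.integer(n_TRs), tr = tr, kind = kind,
         run_boundaries = 0L),
    class = "event_sequence"
  )
}

#' @export
print.event_sequence <- function(x, ...) {
  cat(sprintf(
    "<event_sequence '%s': %d events (%d stimulation) in %d TRs of %g s>\n",
    x$kind, length(x$onsets), sum(x$conditions > 0), x$n_TRs, x$tr
  ))
  invisible(x)
}

#' @export
as.data.frame.event_sequence <- function(x, ...) {
  data.frame(
    onset_s = x$onsets * x$tr,
    duration_s = x$tr,
    condition = x$conditions
  )
}

#' Write or read an event sequence as tab-separated values
#'
#' Three columns (\code{onset_s}, \code{duration_s}, \code{condition}) with
#' nulls encoded as condition 0, in BIDS-events-compatible column order.
#'
#' @param seq an \code{event_sequence}
#' @param path file path
#' @return \code{write_events_tsv} returns \code{path} invisibly;
#'   \code{read_events_tsv} returns an \code{event_sequence}
#' @export
write_events_tsv <- function(seq, path) {
  utils::write.table(as.data.frame(seq), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_events_tsv
#' @param n_TRs,tr,kind sequence metadata not stored in the table
#' @export
read_events_tsv <- function(path, n_TRs, tr = 2, kind = "custom") {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  event_sequence(round(d$onset_s / tr), d$condition, n_TRs, tr, kind)
}

#' Mean onset-to-onset interval between stimulation events
#'
#' @param seq an \code{event_sequence}
#' @return mean ITI in seconds (null events are skipped, not counted as trials)
#' @export
sequence_mean_iti <- function(seq) {
  on <- seq$onsets[seq$conditions > 0]
  mean(diff(on)) * seq$tr
}

block_of_21 <- function() {
  sample(c(rep(0L, 6), rep(1:5, each = 3)))
}

#' Generate a fast event-related sequence
#'
#' 126 events on consecutive TRs: six blocks of 21 events, each holding
#' exactly six null events and three stimulation events per fingertip in
#' random order. The balanced blocks yield a mean stimulation ITI of exactly
#' 2.8 s whenever the run starts and ends with a stimulation event; averaged
#' over draws the mean ITI is 2.8 s.
#'
#' @param seed integer seed (or \code{NULL} to use the current RNG stream)
#' @param tr TR duration, seconds
#' @return an \code{event_sequence} of kind \code{"fast_er"}
#' @export
generate_fast_er_sequence <- function(seed = NULL, tr = 2) {
  conds <- with_seed(seed, unlist(lapply(1:6, function(b) block_of_21())))
  event_sequence(0:125, conds, n_TRs = 126, tr = tr, kind = "fast_er")
}

#' Generate a fully randomized fast ER sequence
#'
#' Same event multiset as \code{\link{generate_fast_er_sequence}} (90
#' stimulation + 36 null events) but shuffled uniformly over the whole run
#' instead of within 21-event blocks.
#'
#' @inheritParams generate_fast_er_sequence
#' @return an \code{event_sequence} of kind \code{"fast_er_fullrand"}
#' @export
generate_fullrand_er_sequence <- function(seed = NULL, tr = 2) {
  conds <- with_seed(seed, sample(c(rep(0L, 36), rep(1:5, each = 18))))
  event_sequence(0:125, conds, n_TRs = 126, tr = tr, kind = "fast_er_fullrand")
}

#' Generate a fast ER sequence without null events
#'
#' The 90 stimulation events of the fast design (six blocks of 15, three per
#' fingertip) on consecutive TRs with the null events - and their scan time -
#' removed, so the run covers only the 90-TR stimulation period. With every
#' TR stimulated the five regressors sum to a near-constant, which is why
#' this variant's detection and HRF-estimation efficiencies collapse while
#' pairwise-difference efficiency survives.
#'
#' @inheritParams generate_fast_er_sequence
#' @return an \code{event_sequence} of kind \code{"fast_er_nonull"}
#' @export
generate_nonull_er_sequence <- function(seed = NULL, tr = 2) {
  conds <- with_seed(
    seed,
    unlist(lapply(1:6, function(b) sample(rep(1:5, each = 3))))
  )
  event_sequence(0:89, conds, n_TRs = 90, tr = tr, kind = "fast_er_nonull")
}

#' Generate a slow event-related sequence
#'
#' Thirty stimulation events (six per fingertip) separated by random
#' onset-to-onset intervals drawn uniformly from 2-6 TRs (4-12 s in 2-s
#' steps, mean 8 s), with the constraint that no two consecutive events
#' stimulate the same fingertip. Sequences exceeding the run length are
#' rejected and redrawn.
#'
#' @inheritParams generate_fast_er_sequence
#' @param n_TRs run length in TRs (126 TRs = 252 s acquisition)
#' @param max_attempts rejection-sampling cap
#' @return an \code{event_sequence} of kind \code{"slow_er"}
#' @export
generate_slow_er_sequence <- function(seed = NULL, n_TRs = 126, tr = 2,
                                      max_attempts = 10000) {
  if (n_TRs < 30 * 2) {
    stop("n_TRs too short to place 30 events with minimum 2-TR gaps")
  }
  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      conds <- draw_no_repeat_conditions()
      if (is.null(conds)) next
      gaps <- sample(2:6, 29, replace = TRUE)
      onsets <- cumsum(c(0L, gaps))
      if (max(onsets) < n_TRs) {
        return(event_sequence(onsets, conds, n_TRs, tr, kind = "slow_er"))
      }
    }
    stop(sprintf(
      "could not place 30 slow-ER events within %d TRs in %d attempts",
      n_TRs, max_attempts
    ))
  })
}

# Random ordering of six events per fingertip with no immediate repeats;
# returns NULL when the sequential draw paints itself into a corner.
draw_no_repeat_conditions <- function() {
  conds <- integer(30)
  pool <- rep(1:5, each = 6)
  conds[1] <- sample(1:5, 1)
  pool <- pool[-match(conds[1], pool)]
  for (i in 2:30) {
    avail <- unique(pool[pool != conds[i - 1]])
    if (length(avail) == 0) return(NULL)
    conds[i] <- if (length(avail) == 1) avail else sample(avail, 1)
    pool <- pool[-match(conds[i], pool)]
  }
  conds
}

#' Generate a phase-encoded (traveling-wave) sequence
#'
#' Each fingertip is stimulated for 4 s (2 TRs) in somatotopic order; one
#' cycle covers the five fingertips in 20 s and is repeated \code{n_cycles}
#' times. Forward order runs thumb to pinky, reverse order pinky to thumb.
#'
#' @param direction \code{"forward"} or \code{"reverse"}
#' @param n_cycles number of 20-s cycles
#' @param tr TR duration, seconds
#' @return an \code{event_sequence} of kind \code{"phase_fwd"} or
#'   \code{"phase_rev"}
#' @export
generate_phase_encoded_sequence <- function(direction = c("forward", "reverse"),
                                            n_cycles = 9, tr = 2) {
  direction <- match.arg(direction)
  order5 <- if (direction == "forward") 1:5 else 5:1
  cycle <- rep(order5, each = 2)
  conds <- rep(cycle, n_cycles)
  n <- length(conds)
  event_sequence(0:(n - 1), conds, n_TRs = n, tr = tr,
                 kind = if (direction == "forward") "phase_fwd" else "phase_rev")
}

#' Contrast efficiency of a design matrix
#'
#' The reciprocal of the average variance trace of a set of contrast
#' estimates under unit-variance white noise:
#' \deqn{E = 1 / [ (1/K) \sum_k Tr( C_k (X'X)^{-1} C_k' ) ].}
#' Scale-equivariant: scaling \code{X} by \code{a} multiplies the result by
#' \code{a^2}. Higher values mean statistically more efficient designs.
#'
#' @param X design matrix (full column rank)
#' @param contrasts list of contrast matrices, each with \code{ncol(X)} columns
#' @return positive scalar efficiency
#' @export
contrast_efficiency <- function(X, contrasts) {
  XtX <- crossprod(X)
  if (rcond(XtX) < 1e-12) {
    stop("design matrix is rank deficient; cannot invert X'X", call. = FALSE)
  }
  XtXi <- tryCatch(
    chol2inv(chol(XtX)),
    error = function(e) stop(
      "design matrix is rank deficient; cannot invert X'X", call. = FALSE
    )
  )
  traces <- vapply(contrasts, function(C) {
    C <- matrix(C, ncol = ncol(X))
    sum(diag(C %*% XtXi %*% t(C)))
  }, numeric(1))
  1 / mean(traces)
}

# Contrast constructors (zero-padded to p columns).
detection_contrasts <- function(p) {
  lapply(1:5, function(i) {
    C <- matrix(0, 1, p); C[1, i] <- 1; C
  })
}

pairwise_contrasts <- function(p) {
  out <- list()
  for (i in 1:4) {
    for (j in (i + 1):5) {
      C <- matrix(0, 1, p); C[1, i] <- 1; C[1, j] <- -1
      out[[length(out) + 1]] <- C
    }
  }
  out
}

fir_selection_contrasts <- function(p, n_fir_points) {
  lapply(1:5, function(f) {
    C <- matrix(0, n_fir_points, p)
    C[cbind(1:n_fir_points, (f - 1) * n_fir_points + 1:n_fir_points)] <- 1
    C
  })
}

#' Detection, HRF-estimation and difference-detection efficiencies
#'
#' Computes the three efficiency summaries for one stimulation sequence:
#' \describe{
#'   \item{detection}{fingertip-vs-baseline contrasts on the
#'     canonical-HRF-convolved design;}
#'   \item{hrf_estimation}{per-fingertip FIR-block selection contrasts on the
#'     FIR design (the event matrix's shifted copies, one per lag);}
#'   \item{difference_detection}{the 10 pairwise fingertip contrasts on the
#'     canonical design.}
#' }
#' A baseline (intercept) column is modelled by default; dropping it removes
#' the collinearity penalty on designs whose regressors sum to a constant.
#' When a design's FIR matrix is rank deficient (fewer TRs than FIR
#' regressors) the Moore-Penrose pseudoinverse is used and a warning raised.
#'
#' @param seq an \code{\link{event_sequence}} with at least one event per
#'   fingertip
#' @param hrf canonical \code{hrf_model} (unit integral by default)
#' @param n_fir_points FIR lags per fingertip
#' @param intercept include a baseline column in both designs
#' @return list with elements \code{detection}, \code{hrf_estimation},
#'   \code{difference_detection}
#' @export
design_efficiencies <- function(seq, hrf = double_gamma_hrf(dt = seq$tr),
                                n_fir_points = 20, intercept = TRUE) {
  if (any(tabulate(seq$conditions[seq$conditions > 0], 5) == 0)) {
    stop("sequence must contain at least one event per fingertip")
  }
  Xc <- build_design(seq, "canonical", hrf, intercept = intercept)
  p <- ncol(Xc)
  Xf <- build_design(seq, "fir", hrf, n_fir_points = n_fir_points,
                     intercept = intercept)
  pf <- ncol(Xf)
  fir_eff <- tryCatch(
    contrast_efficiency(Xf, fir_selection_contrasts(pf, n_fir_points)),
    error = function(e) {
      warning("FIR design rank deficient; using pseudoinverse", call. = FALSE)
      G <- pseudoinverse(crossprod(Xf))
      d <- diag(G)
      traces <- vapply(1:5, function(f) {
        sum(d[(f - 1) * n_fir_points + 1:n_fir_points])
      }, numeric(1))
      1 / mean(traces)
    }
  )
  list(
    detection = contrast_efficiency(Xc, detection_contrasts(p)),
    hrf_estimation = fir_eff,
    difference_detection = contrast_efficiency(Xc, pairwise_contrasts(p))
  )
}

pseudoinverse <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * s$d[1]
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Fast detection-only efficiency for sequence screening: precomputes the
# HRF Toeplitz operator once so each draw costs one small crossproduct.
make_detection_scorer <- function(n_TRs, tr = 2,
                                  hrf = double_gamma_hrf(dt = tr),
                                  intercept = TRUE) {
  h <- hrf$samples
  H <- matrix(0, n_TRs, n_TRs)
  for (k in seq_along(h)) {
    idx <- seq_len(n_TRs - k + 1)
    H[cbind(idx + k - 1L, idx)] <- h[k]
  }
  H <- tr * H
  function(conditions) {
    X <- vapply(1:5, function(f) {
      cols <- which(conditions == f)
      if (length(cols) == 0) return(rep(0, n_TRs))
      rowSums(H[, cols, drop = FALSE])
    }, numeric(n_TRs))
    if (intercept) X <- cbind(X, 1)
    XtXi <- chol2inv(chol(crossprod(X)))
    1 / mean(diag(XtXi)[1:5])
  }
}

#' Select the most detection-efficient fast ER sequences
#'
#' Draws \code{n_draws} block-randomized fast ER sequences and returns the
#' \code{top_k} with the highest overall detection efficiency, in descending
#' order of efficiency.
#'
#' @param n_draws number of random sequences to score
#' @param top_k number of sequences to keep (\code{top_k <= n_draws})
#' @param seed integer seed making the draw deterministic
#' @param tr TR duration, seconds
#' @param intercept include a baseline column in the scoring design
#' @return list with \code{sequences} (list of \code{event_sequence}),
#'   \code{efficiencies} (their detection efficiencies, descending) and
#'   \code{all_efficiencies} (the full sample, in draw order)
#' @export
optimize_fast_er <- function(n_draws, top_k = 20, seed = NULL, tr = 2,
                             intercept = TRUE) {
  stopifnot(top_k <= n_draws)
  scorer <- make_detection_scorer(126, tr = tr, intercept = intercept)
  with_seed(seed, {
    conds <- replicate(n_draws, unlist(lapply(1:6, function(b) block_of_21())))
    effs <- apply(conds, 2, scorer)
    ord <- order(effs, decreasing = TRUE)[seq_len(top_k)]
    list(
      sequences = lapply(ord, function(i) {
        event_sequence(0:125, conds[, i], 126, tr, kind = "fast_er")
      }),
      efficiencies = effs[ord],
      all_efficiencies = effs
    )
  })
}
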