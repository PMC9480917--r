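#' Ordinary least-squares GLM for multi-voxel timeseries
#'
#' Fits \code{y = X b + e} independently per voxel with homoscedastic OLS.
#' Standard errors come from \code{sigma2 * diag((X'X)^-1)} with
#' \code{dof = n - rank(X)}.
#'
#' @param ts \code{run_timeseries} (voxels x TRs)
#' @param X design matrix from \code{\link{build_design}} (or any numeric
#'   matrix with \code{n_TRs} rows)
#' @return object of class \code{glm_result}: list with \code{betas},
#'   \code{beta_se} (voxels x regressors), \code{sigma2}, \code{dof},
#'   \code{labels}, \code{XtXinv}, and the design \code{X}
#' @export
fit_glm <- function(ts, X) {
  Y <- ts$values
  if (ncol(Y) != nrow(X)) stop("timeseries and design TR counts differ")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix rank deficient; offending columns: ",
         paste(bad, collapse = ", "))
  }
  betas <- t(qr.coef(qrX, t(Y)))
  fitted <- betas %*% t(X)
  rss <- rowSums((Y - fitted)^2)
  dof <- ncol(Y) - qrX$rank
  sigma2 <- rss / dof
  XtXinv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot), drop = FALSE]
  beta_se <- sqrt(outer(sigma2, diag(XtXinv)))
  colnames(betas) <- colnames(beta_se) <- colnames(X)
  structure(
    list(betas = betas, beta_se = beta_se, sigma2 = sigma2, dof = dof,
         labels = colnames(X), XtXinv = XtXinv, X = X),
    class = "glm_result"
  )
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf("<glm_result: %d voxels x %d regressors, dof = %d>\n",
              nrow(x$betas), ncol(x$betas), x$dof))
  invisible(x)
}

#' Voxelwise FIR deconvolution of fingertip responses
#'
#' First step of the two-step GLM: fits the FIR (deconvolution) design -
#' the five fingertip event sequences convolved with \code{n_points} delta
#' functions shifted by one TR - returning each voxel's estimated response
#' to each fingertip over \code{n_points} TRs.
#'
#' @param ts \code{run_timeseries}
#' @param seq matching \code{event_sequence}
#' @param n_points FIR lags (20 lags x 2 s = 40 s coverage)
#' @param intercept include per-run intercepts
#' @return list with \code{hrfs}, an array voxels x 5 x n_points, and
#'   \code{fit}, the underlying \code{glm_result}
#' @export
estimate_voxel_hrfs <- function(ts, seq, n_points = 20, intercept = TRUE) {
  X <- build_design(seq, "fir", n_fir_points = n_points, intercept = intercept)
  fit <- fit_glm(ts, X)
  nv <- nrow(fit$betas)
  hrfs <- array(NA_real_, c(nv, 5, n_points))
  for (f in 1:5) {
    hrfs[, f, ] <- fit$betas[, (f - 1) * n_points + 1:n_points, drop = FALSE]
  }
  list(hrfs = hrfs, fit = fit)
}

#' Participant-average HRF from fingertip-specific regions
#'
#' Averages FIR HRF estimates across all voxels of each fingertip-specific
#' region, keeps each region's response to its dominant fingertip, averages
#' those across regions, and normalizes the result to unit integral.
#'
#' @param voxel_hrfs array voxels x 5 x n_points from
#'   \code{\link{estimate_voxel_hrfs}}
#' @param regions list of integer voxel-index vectors, one per region
#' @param dominant integer vector: the dominant fingertip of each region
#'   (e.g. its phase bin)
#' @param tr TR duration, seconds
#' @return an \code{hrf_model} (empirical, unit integral)
#' @export
participant_average_hrf <- function(voxel_hrfs, regions, dominant, tr = 2) {
  stopifnot(length(regions) == length(dominant))
  keep <- lengths(regions) > 0
  if (!any(keep)) stop("all regions are empty")
  if (!all(keep)) {
    warning(sum(!keep), " empty region(s) excluded from the HRF average")
  }
  per_region <- mapply(function(vox, f) {
    resp <- voxel_hrfs[vox, f, , drop = FALSE]
    colMeans(matrix(resp, nrow = length(vox)))
  }, regions[keep], dominant[keep], SIMPLIFY = FALSE)
  avg <- Reduce(`+`, per_region) / length(per_region)
  empirical_hrf(avg, dt = tr, normalization = "unit_integral")
}

#' Single-amplitude fingertip response estimation
#'
#' Second step of the two-step GLM: convolves the five fingertip event
#' sequences with the participant's average HRF and fits one amplitude per
#' fingertip per voxel.
#'
#' @param ts \code{run_timeseries}
#' @param seq matching \code{event_sequence}
#' @param hrf participant (or canonical) \code{hrf_model}
#' @param intercept include per-run intercepts
#' @return \code{glm_result} whose first five betas are the fingertip
#'   amplitudes
#' @export
fingertip_amplitudes <- function(ts, seq, hrf, intercept = TRUE) {
  X <- build_design(seq, "canonical", hrf, intercept = intercept)
  fit_glm(ts, X)
}

#' Contrast statistics for fingertip GLM results
#'
#' \describe{
#'   \item{preference}{five one-sided t contrasts, fingertip i versus the
#'     mean of the other four;}
#'   \item{activation}{five one-sided t contrasts, fingertip i versus
#'     baseline;}
#'   \item{main_effect_F}{F test for any difference among the five fingertip
#'     responses (4 numerator dof);}
#'   \item{any_positive_F}{F test for a nonzero response to at least one
#'     fingertip (5 numerator dof).}
#' }
#' One-sided p-values are reported for t contrasts (upper tail).
#'
#' @param res \code{glm_result} whose first five regressors are fingertips
#' @param kind contrast family
#' @return for t kinds, list with matrices \code{stat} and \code{p}
#'   (voxels x 5); for F kinds, data.frame with \code{stat} and \code{p}
#' @export
compute_contrasts <- function(res,
                              kind = c("preference", "activation",
                                       "main_effect_F", "any_positive_F")) {
  kind <- match.arg(kind)
  p <- ncol(res$betas)
  pad <- function(C) cbind(C, matrix(0, nrow(C), p - 5))
  if (kind %in% c("preference", "activation")) {
    Cs <- if (kind == "preference") {
      lapply(1:5, function(i) {
        C <- matrix(-1 / 4, 1, 5); C[1, i] <- 1; pad(C)
      })
    } else {
      lapply(1:5, function(i) {
        C <- matrix(0, 1, 5); C[1, i] <- 1; pad(C)
      })
    }
    stat <- sapply(Cs, function(C) {
      est <- res$betas %*% t(C)
      se <- sqrt(res$sigma2 * drop(C %*% res$XtXinv %*% t(C)))
      drop(est) / se
    })
    list(stat = stat, p = stats::pt(stat, res$dof, lower.tail = FALSE))
  } else {
    C <- if (kind == "main_effect_F") {
      pad(cbind(diag(4), -1) )
    } else {
      pad(diag(5))
    }
    q <- nrow(C)
    M <- solve(C %*% res$XtXinv %*% t(C))
    est <- res$betas %*% t(C)
    ss <- rowSums((est %*% M) * est)
    fstat <- (ss / q) / res$sigma2
    data.frame(stat = fstat,
               p = stats::pf(fstat, q, res$dof, lower.tail = FALSE))
  }
}

#' Benjamini-Hochberg step-up FDR correction
#'
#' @param p_values vector of p-values
#' @param q FDR level
#' @return list with logical \code{rejected} and numeric \code{adjusted}
#'   (BH-adjusted p-values)
#' @export
fdr_step_up <- function(p_values, q = 0.05) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  adj <- rep(NA_real_, length(p_values))
  adj[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  list(rejected = !is.na(adj) & adj <= q, adjusted = adj)
}

#' Hemodynamic delay proxy from the derivative ratio
#'
#' Fits the canonical-plus-temporal-derivative GLM and returns the ratio of
#' the derivative estimate to the canonical estimate at each voxel's
#' preferred (largest canonical beta) fingertip. Larger ratios correspond to
#' shorter hemodynamic delays; the ratio is near zero for data generated by
#' the canonical HRF itself. Voxels with non-positive canonical beta are
#' masked (NA).
#'
#' @param ts \code{run_timeseries}
#' @param seq matching \code{event_sequence}
#' @param hrf canonical \code{hrf_model}
#' @param intercept include per-run intercepts
#' @return numeric vector, one delay-proxy ratio per voxel
#' @export
delay_ratio <- function(ts, seq, hrf = double_gamma_hrf(dt = seq$tr),
                        intercept = TRUE) {
  X <- build_design(seq, "canonical_plus_derivative", hrf,
                    intercept = intercept)
  fit <- fit_glm(ts, X)
  canonical <- fit$betas[, 1:5, drop = FALSE]
  deriv <- fit$betas[, 6:10, drop = FALSE]
  pref <- max.col(canonical, ties.method = "first")
  idx <- cbind(seq_len(nrow(canonical)), pref)
  ratio <- deriv[idx] / canonical[idx]
  ratio[canonical[idx] <= 0] <- NA_real_
  ratio
}
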