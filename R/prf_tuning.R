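#' Full width at half maximum of a Gaussian
#'
#' @param sigma Gaussian spread
#' @return \code{sigma * 2 * sqrt(2 * log(2))} (factor 2.3548)
#' @export
fwhm_from_sigma <- function(sigma) sigma * 2 * sqrt(2 * log(2))

# Bounded Gaussian least squares on a fingertip tuning curve. Deterministic
# coarse-to-fine multi-start: every (center, sigma) grid start is screened
# with its closed-form best amplitude, and the most promising starts are
# refined by bounded Levenberg-Marquardt (minpack.lm); the best-RSS solution
# wins.
fit_gaussian_curve <- function(x, y, center_bounds, sigma_bounds,
                               fix_center = NULL, offset = c("none", "nonpositive"),
                               center_grid = seq(1, 5, by = 0.5),
                               sigma_grid = c(0.3, 1, 3, 10, 30),
                               n_refine = 3) {
  offset <- match.arg(offset)
  use_offset <- offset == "nonpositive"
  sigma_grid <- unique(pmin(pmax(sigma_grid, sigma_bounds[1]),
                            min(sigma_bounds[2], 1e6)))
  if (!is.null(fix_center)) center_grid <- fix_center
  center_grid <- unique(pmin(pmax(center_grid, center_bounds[1]),
                             center_bounds[2]))

  model <- function(par) {
    g <- par[["amp"]] * exp(-(x - par[["center"]])^2 / (2 * par[["sigma"]]^2))
    if (use_offset) g <- g + par[["offset"]]
    g
  }
  rss_of <- function(par) sum((y - model(par))^2)

  # screen all starts with closed-form amplitude (and offset, if used)
  starts <- expand.grid(center = center_grid, sigma = sigma_grid)
  screened <- lapply(seq_len(nrow(starts)), function(i) {
    c0 <- starts$center[i]; s0 <- starts$sigma[i]
    g0 <- exp(-(x - c0)^2 / (2 * s0^2))
    if (use_offset) {
      # least squares for (amp, offset) with offset clamped to <= 0
      X0 <- cbind(g0, 1)
      ab <- tryCatch(solve(crossprod(X0), crossprod(X0, y)),
                     error = function(e) c(1, 0))
      a0 <- max(ab[1], 1e-6); o0 <- min(ab[2], 0)
      par0 <- c(amp = a0, center = c0, sigma = s0, offset = o0)
    } else {
      a0 <- max(sum(g0 * y) / sum(g0^2), 1e-6)
      par0 <- c(amp = a0, center = c0, sigma = s0)
    }
    list(par = par0, rss = rss_of(par0))
  })
  ord <- order(vapply(screened, `[[`, numeric(1), "rss"))
  refine <- screened[ord[seq_len(min(n_refine, length(screened)))]]

  lower <- c(amp = 0, center = center_bounds[1], sigma = sigma_bounds[1])
  upper <- c(amp = Inf, center = center_bounds[2], sigma = sigma_bounds[2])
  if (!is.null(fix_center)) lower["center"] <- upper["center"] <- fix_center
  if (use_offset) {
    lower <- c(lower, offset = -Inf)
    upper <- c(upper, offset = 0)
  }

  best <- refine[[1]]
  for (st in refine) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = st$par,
        fn = function(p) {
          names(p) <- names(st$par)
          y - model(p)
        },
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      p <- stats::coef(fit); names(p) <- names(st$par)
      r <- rss_of(p)
      if (r < best$rss) best <- list(par = p, rss = r)
    }
  }
  best
}

#' Fit a Gaussian pRF to one voxel's tuning curve
#'
#' Bounded nonlinear least squares of
#' \code{amplitude * exp(-(f - center)^2 / (2 sigma^2))} over fingertips
#' f = 1..5, with the center restricted to [0.5, 5.5] fingertip units and
#' the spread capped at 30 fingertip units. A deterministic multi-start grid
#' guards against local minima. Tuning curves that are entirely zero are
#' flagged non-responsive and not fitted.
#'
#' @param curve numeric vector of 5 fingertip response estimates
#' @param center_bounds,sigma_max parameter bounds in fingertip units
#' @return data.frame row with \code{center}, \code{sigma}, \code{amplitude},
#'   \code{fwhm}, \code{rss}, \code{responsive}
#' @export
fit_voxel_prf <- function(curve, center_bounds = c(0.5, 5.5), sigma_max = 30) {
  if (length(curve) != 5 || any(!is.finite(curve))) {
    stop("curve must be 5 finite values")
  }
  if (all(curve == 0)) {
    return(data.frame(center = NA_real_, sigma = NA_real_,
                      amplitude = NA_real_, fwhm = NA_real_,
                      rss = NA_real_, responsive = FALSE))
  }
  best <- fit_gaussian_curve(1:5, curve, center_bounds,
                             sigma_bounds = c(1e-3, sigma_max))
  data.frame(
    center = unname(best$par["center"]),
    sigma = unname(best$par["sigma"]),
    amplitude = unname(best$par["amp"]),
    fwhm = fwhm_from_sigma(unname(best$par["sigma"])),
    rss = best$rss, responsive = TRUE
  )
}

#' Fit pRFs for a matrix of tuning curves
#'
#' @param betas voxels x 5 matrix of fingertip response estimates
#' @param ... passed to \code{\link{fit_voxel_prf}}
#' @return data.frame with one row per voxel
#' @export
fit_prf_map <- function(betas, ...) {
  out <- do.call(rbind, lapply(seq_len(nrow(betas)), function(v) {
    fit_voxel_prf(betas[v, ], ...)
  }))
  rownames(out) <- NULL
  out
}

#' Recentered ROI tuning curve
#'
#' Places each ROI voxel's five fingertip responses at offsets
#' \code{f - preferred} relative to that voxel's preferred fingertip and
#' averages across voxels per offset, yielding a nine-point curve over
#' offsets -4..+4 (edge offsets average fewer voxels). To avoid circularity
#' bias the preference map must come from a dataset independent of
#' \code{betas} (e.g. the phase-encoded localizer); recentering on the same
#' data's argmax produces spuriously narrowed tuning.
#'
#' @param betas voxels x 5 matrix of fingertip responses
#' @param preferred integer preferred fingertip (1-5) per voxel
#' @param roi integer indices of the ROI's voxels
#' @return data.frame of class \code{tuning_curve} with \code{position}
#'   (-4..4), \code{value} (mean response) and \code{n_voxels}
#' @export
recenter_and_average <- function(betas, preferred, roi) {
  if (length(roi) == 0) stop("empty ROI")
  pos <- -4:4
  sums <- numeric(9)
  counts <- integer(9)
  for (v in roi) {
    offs <- (1:5) - preferred[v]
    idx <- match(offs, pos)
    sums[idx] <- sums[idx] + betas[v, ]
    counts[idx] <- counts[idx] + 1L
  }
  out <- data.frame(
    position = pos,
    value = ifelse(counts > 0, sums / pmax(counts, 1L), NA_real_),
    n_voxels = counts
  )
  class(out) <- c("tuning_curve", class(out))
  out
}

#' Gaussian FWHM of a recentered ROI tuning curve
#'
#' Fits a Gaussian centered on the preferred fingertip (offset zero) with
#' free amplitude and spread. Two constraint variants from different uses:
#' \code{"offset_nonpositive"} adds an offset parameter restricted to
#' non-positive values (accounting for below-baseline responses in design
#' comparisons); \code{"sigma_floor"} instead bounds the spread below at 0.4
#' fingertip units (avoiding unrealistically narrow ROI tuning estimates),
#' with no upper bound.
#'
#' @param curve a \code{tuning_curve} (or data.frame with \code{position},
#'   \code{value})
#' @param variant constraint variant
#' @return list with \code{fwhm}, \code{sigma}, \code{amplitude},
#'   \code{offset} (NA unless fitted), \code{rss}
#' @export
fit_tuning_fwhm <- function(curve, variant = c("sigma_floor", "offset_nonpositive")) {
  variant <- match.arg(variant)
  ok <- !is.na(curve$value)
  x <- curve$position[ok]
  y <- curve$value[ok]
  if (any(!is.finite(y))) stop("non-finite curve values")
  if (variant == "sigma_floor") {
    best <- fit_gaussian_curve(
      x, y, center_bounds = c(0, 0), sigma_bounds = c(0.4, Inf),
      fix_center = 0, sigma_grid = c(0.4, 1, 3, 10, 30)
    )
    offset <- NA_real_
  } else {
    best <- fit_gaussian_curve(
      x, y, center_bounds = c(0, 0), sigma_bounds = c(1e-3, 30),
      fix_center = 0, offset = "nonpositive"
    )
    offset <- unname(best$par["offset"])
  }
  list(
    fwhm = fwhm_from_sigma(unname(best$par["sigma"])),
    sigma = unname(best$par["sigma"]),
    amplitude = unname(best$par["amp"]),
    offset = offset,
    rss = best$rss
  )
}

#' Cortical distances between consecutive fingertip representations
#'
#' For each fingertip ROI in an ordered somatotopic band, draws a center
#' line through the ROI perpendicular to the somatotopic axis (the ROI
#' voxels in the column closest to the ROI centroid, for a column axis) and
#' returns, for each consecutive fingertip pair, the average geodesic
#' separation of the two lines: the mean, over the vertices of each line,
#' of the 4-connected grid shortest-path distance to the nearest vertex of
#' the other line, symmetrized over the two directions, in voxel spacing
#' units. Parallel aligned lines d columns apart are therefore exactly
#' \code{d * spacing} apart.
#'
#' @param rois list of 5 integer voxel-index vectors (some may be empty)
#' @param grid_shape c(rows, cols)
#' @param spacing voxel spacing (e.g. mm per voxel)
#' @param axis somatotopic axis, \code{"col"} or \code{"row"}
#' @return numeric vector of 4 distances (pairs 1-2 .. 4-5); NA where a
#'   region is missing
#' @export
cortical_distances <- function(rois, grid_shape, spacing = 1, axis = "col") {
  nr <- grid_shape[1]; nc <- grid_shape[2]
  rowcol <- function(v) cbind((v - 1L) %/% nc + 1L, (v - 1L) %% nc + 1L)
  lines <- lapply(rois, function(vox) {
    if (is.null(vox) || length(vox) == 0) return(NULL)
    rc <- rowcol(vox)
    along <- if (axis == "col") rc[, 2] else rc[, 1]
    target <- along[which.min(abs(along - mean(along)))]
    vox[along == target]
  })
  g <- igraph::make_lattice(c(nc, nr))
  out <- rep(NA_real_, 4)
  for (i in 1:4) {
    a <- lines[[i]]; b <- lines[[i + 1]]
    if (is.null(a) || is.null(b)) next
    d <- igraph::distances(g, v = a, to = b)
    out[i] <- mean(c(apply(d, 1, min), apply(d, 2, min))) * spacing
  }
  out
}
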