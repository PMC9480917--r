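test_that("voxel pRF fits handle peaked, flat, zero and sampled curves", {
  f <- fit_voxel_prf(c(0, 0, 1, 0, 0))
  expect_lt(abs(f$center - 3), 0.1)
  flat <- fit_voxel_prf(c(1, 1, 1, 1, 1))
  expect_equal(flat$sigma, 30) # flat positive curve drives sigma to the cap
  z <- fit_voxel_prf(rep(0, 5))
  expect_false(z$responsive)
  expect_true(is.na(z$center))
  g <- fit_voxel_prf(0.8 * gaussian_tuning(1:5, 2.5, 1.0))
  expect_equal(g$center, 2.5, tolerance = 1e-4)
  expect_equal(g$sigma, 1.0, tolerance = 1e-4)
  expect_equal(g$amplitude, 0.8, tolerance = 1e-4)
  expect_error(fit_voxel_prf(c(1, 2, NA, 4, 5)), "finite")
})

test_that("fwhm/sigma ratio is the Gaussian constant everywhere", {
  expect_equal(fwhm_from_sigma(1), 2 * sqrt(2 * log(2)))
  expect_equal(fwhm_from_sigma(1), 2.3548, tolerance = 1e-4)
  f <- fit_voxel_prf(gaussian_tuning(1:5, 3.2, 1.7))
  expect_equal(f$fwhm / f$sigma, 2 * sqrt(2 * log(2)), tolerance = 1e-12)
})

test_that("pRF parameters are recovered from noisy curves", {
  set.seed(9)
  fits <- t(vapply(1:500, function(i) {
    y <- 0.8 * gaussian_tuning(1:5, 2.5, 1.0) + rnorm(5, 0, 0.05)
    unlist(fit_voxel_prf(y)[c("center", "sigma")])
  }, numeric(2)))
  expect_lt(abs(mean(fits[, "center"]) - 2.5), 0.1)
  expect_lt(abs(mean(fits[, "sigma"]) / 1.0 - 1), 0.15)
})

test_that("recentering produces the expected nine-point curves", {
  # identical delta-tuned voxels: delta at offset 0
  betas <- rbind(c(1, 0, 0, 0, 0), c(0, 0, 1, 0, 0), c(0, 0, 0, 0, 1))
  pref <- c(1, 3, 5)
  curve <- recenter_and_average(betas, pref, 1:3)
  expect_equal(nrow(curve), 9)
  expect_equal(curve$position, -4:4)
  expect_equal(curve$value[curve$position == 0], 1)
  expect_true(all(curve$value[curve$position != 0] == 0, na.rm = TRUE))
  # edge offsets average fewer voxels
  expect_equal(curve$n_voxels[curve$position == 0], 3L)
  expect_lt(curve$n_voxels[curve$position == -4], 3L)
  expect_error(recenter_and_average(betas, pref, integer(0)), "empty")
})

test_that("independent recentering is unbiased; circular recentering is not", {
  set.seed(10)
  nv <- 3000
  betas <- matrix(rnorm(nv * 5), nv, 5) # untuned voxels
  indep_pref <- sample(1:5, nv, replace = TRUE) # independent of betas
  circ_pref <- max.col(betas) # same-data argmax
  ci <- recenter_and_average(betas, indep_pref, 1:nv)
  cc <- recenter_and_average(betas, circ_pref, 1:nv)
  sei <- stats::sd(betas) / sqrt(nv)
  peak_effect <- function(curve) {
    curve$value[curve$position == 0] -
      mean(curve$value[abs(curve$position) >= 1], na.rm = TRUE)
  }
  expect_lt(abs(peak_effect(ci)), 3 * sei)
  expect_gt(peak_effect(cc), 3 * sei)
})

test_that("ROI tuning FWHM fits respect their constraint variants", {
  x <- -4:4
  curve <- data.frame(position = x,
                      value = 0.9 * exp(-x^2 / 2), n_voxels = 9)
  f <- fit_tuning_fwhm(curve, "sigma_floor")
  expect_equal(f$fwhm, 2.3548, tolerance = 1e-3)
  # delta curve hits the sigma floor
  delta <- data.frame(position = x, value = c(rep(0, 4), 1, rep(0, 4)),
                      n_voxels = 9)
  fd <- fit_tuning_fwhm(delta, "sigma_floor")
  expect_equal(fd$sigma, 0.4, tolerance = 1e-6)
  # positive plateau clamps the offset at zero
  plat <- data.frame(position = x, value = exp(-x^2 / 8) + 0.5, n_voxels = 9)
  fp <- fit_tuning_fwhm(plat, "offset_nonpositive")
  expect_equal(fp$offset, 0, tolerance = 1e-6)
  # negative tails are absorbed by a negative offset
  neg <- data.frame(position = x, value = exp(-x^2 / 2) - 0.3, n_voxels = 9)
  fn <- fit_tuning_fwhm(neg, "offset_nonpositive")
  expect_lt(fn$offset, 0)
  expect_equal(fn$sigma, 1, tolerance = 0.05)
  expect_error(
    fit_tuning_fwhm(data.frame(position = x, value = c(Inf, rep(0, 8)))),
    "finite"
  )
})

test_that("cortical distances match construction and a brute-force oracle", {
  gs <- c(10, 20)
  # parallel stripes 3 columns apart
  rois <- lapply(1:5, function(f) {
    col <- 3 * f
    which(rep(1:20, 10) == col & rep(1:10, each = 20) %in% 3:6)
  })
  expect_equal(cortical_distances(rois, gs), rep(3, 4))
  expect_equal(cortical_distances(rois, gs, spacing = 2), rep(6, 4))
  # missing region leaves its pairs undefined
  rois_miss <- rois
  rois_miss[[2]] <- integer(0)
  d <- cortical_distances(rois_miss, gs)
  expect_true(is.na(d[1]) && is.na(d[2]))
  expect_false(anyNA(d[3:4]))

  # irregular regions: compare against a hand-rolled BFS oracle
  set.seed(11)
  gs2 <- c(7, 12)
  rois2 <- lapply(1:5, function(f) {
    cols <- pmin(pmax(2 * f + sample(-1:1, 4, replace = TRUE), 1), 12)
    rows <- sample(1:7, 4, replace = TRUE)
    unique((rows - 1) * 12 + cols)
  })
  bfs_dist <- function(from, nr, nc) {
    d <- rep(Inf, nr * nc)
    d[from] <- 0
    queue <- from
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      r <- (v - 1) %/% nc + 1; c <- (v - 1) %% nc + 1
      for (nb in list(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))) {
        if (nb[1] >= 1 && nb[1] <= nr && nb[2] >= 1 && nb[2] <= nc) {
          w <- (nb[1] - 1) * nc + nb[2]
          if (d[w] > d[v] + 1) {
            d[w] <- d[v] + 1
            queue <- c(queue, w)
          }
        }
      }
    }
    d
  }
  center_line <- function(vox, nc) {
    along <- (vox - 1) %% nc + 1
    target <- along[which.min(abs(along - mean(along)))]
    vox[along == target]
  }
  oracle <- vapply(1:4, function(i) {
    a <- center_line(rois2[[i]], 12)
    b <- center_line(rois2[[i + 1]], 12)
    da <- vapply(a, function(v) min(bfs_dist(v, 7, 12)[b]), numeric(1))
    db <- vapply(b, function(v) min(bfs_dist(v, 7, 12)[a]), numeric(1))
    mean(c(da, db))
  }, numeric(1))
  expect_equal(cortical_distances(rois2, gs2), oracle, tolerance = 1e-6)
})

test_that("fitted sigma reproduces the built-in band gradient", {
  res <- default_pipeline_result()
  sig_by_area <- vapply(res$roi, function(r) r$mean_prf_sigma, numeric(1))
  names(sig_by_area) <- vapply(res$roi, function(r) r$area, character(1))
  expect_lt(sig_by_area[["BA3b"]], sig_by_area[["BA1"]])
  expect_lt(sig_by_area[["BA1"]], sig_by_area[["BA2"]])
  expect_lt(sig_by_area[["BA2"]], sig_by_area[["post_BA2"]])
  # rank correlation between true and fitted sigma across fitted voxels
  ok <- !is.na(res$prf$sigma) & !is.na(res$patch$voxels$prf_sigma)
  rho <- stats::cor(res$patch$voxels$prf_sigma[ok], res$prf$sigma[ok],
                    method = "spearman")
  expect_gt(rho, 0.8)
})
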