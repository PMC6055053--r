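test_that("estimate_noise recovers the noise scale robustly", {
  expect_equal(estimate_noise(rep(5, 100)), 0)
  expect_warning(z <- estimate_noise(numeric(20)), "all-zero")
  expect_equal(z, 0)

  set.seed(1)
  y <- rnorm(1e5)
  expect_gt(estimate_noise(y), 0.95)
  expect_lt(estimate_noise(y), 1.05)

  # sparse tall peaks barely move the estimate
  y2 <- y
  y2[sample(1e5, 5)] <- 500
  expect_lt(abs(estimate_noise(y2) - 1), 0.1)

  expect_error(estimate_noise(1:5), "at least 8")
})

test_that("pick_peaks finds forced peaks and nothing in silence", {
  expect_length(pick_peaks(1:50, rep(0, 50))$mz, 0L)

  ax <- seq(700, 710, by = 0.1)
  set.seed(2)
  y <- rnorm(length(ax))
  j <- 51
  y[(j - 3):(j + 3)] <- c(25, 50, 75, 100, 75, 50, 25)
  pl <- pick_peaks(ax, y, snr = 3)
  expect_true(ax[j] %in% pl$mz)
  expect_equal(pl$intensity[pl$mz == ax[j]], 100)

  # 10 known ions at high SNR: exactly 10 peaks within one channel
  set.seed(3)
  m <- profile_map(shifts = rep(0, 1), ions = test_ions,
                   heights = rep(100, 10), noise_sd = 1, seed = 3)
  pl10 <- pick_peaks(m$axis, m$intensities[1, ], snr = 10)
  expect_length(pl10$mz, 10L)
  expect_true(all(vapply(test_ions, function(mz)
    min(abs(pl10$mz - mz)) <= 0.05 + 1e-9, logical(1))))
})

test_that("phase correction recovers injected m/z shifts", {
  # already aligned: offsets are numerically zero
  m0 <- profile_map(rep(0, 20), test_ions, seed = 4)
  pc0 <- phase_correct(m0, max_shift = 0.5, anchors = test_ions)
  expect_lt(max(abs(pc0$model$offset)), 0.01)

  # uniform +0.2 Da shift, anchors at the true positions
  m1 <- profile_map(rep(0.2, 50), test_ions, seed = 5)
  pc1 <- phase_correct(m1, max_shift = 0.5, anchors = test_ions)
  expect_lt(max(abs(pc1$model$offset - 0.2)), 0.02)

  # pixel-specific shifts: post-correction anchor residual RMS < 0.05 Da
  set.seed(6)
  sh <- runif(60, -0.3, 0.3)
  m2 <- profile_map(sh, test_ions, seed = 6)
  pc2 <- phase_correct(m2, max_shift = 0.5, anchors = test_ions)
  expect_lt(sqrt(mean((pc2$model$offset - sh)^2)), 0.02)
  resid <- vapply(seq_len(60), function(i) {
    pl <- pick_peaks(m2$axis, pc2$data$intensities[i, ], snr = 10)
    sqrt(mean(vapply(test_ions, function(a) min(abs(pl$mz - a)),
                     numeric(1))^2))
  }, numeric(1))
  expect_lt(sqrt(mean(resid^2)), 0.05)

  # anchors derived from the mean spectrum work on aligned-ish data
  pc3 <- phase_correct(m2, max_shift = 0.5, anchor_quantile = 0.995)
  expect_gte(length(attr(pc3$model, "anchors")), 2L)

  # a flat map has no stable intense peaks
  flat <- spectral_map(matrix(rnorm(2 * 600), 2), seq(600, 659.9, by = 0.1),
                       cbind(c(1, 2), 0), "maldi")
  expect_error(phase_correct(flat, anchor_quantile = 0.999999),
               "no stable intense peaks")

  # peak-list input needs explicit anchors, then shifts m/z values
  pls <- list(peak_list(test_ions + 0.1, rep(10, 10), 1L),
              peak_list(test_ions - 0.2, rep(10, 10), 2L))
  expect_error(phase_correct(pls), "anchors")
  pcl <- phase_correct(pls, max_shift = 0.5, anchors = test_ions)
  expect_equal(pcl$model$offset, c(0.1, -0.2), tolerance = 1e-9)
  expect_equal(pcl$data[[1]]$mz, test_ions, tolerance = 1e-9)
})

test_that("bin_peaks clusters at mass-relative tolerance", {
  # 0.05 Da apart at 500 Da with 200 ppm (+-0.1 Da): one bin
  one <- bin_peaks(list(peak_list(c(500.00, 500.05), c(1, 1), 1L)), 200)
  expect_length(one$bins$centroids, 1L)
  # 10 Da apart: two bins
  two <- bin_peaks(list(peak_list(c(500, 510), c(1, 1), 1L)), 200)
  expect_length(two$bins$centroids, 2L)
  expect_error(bin_peaks(list(peak_list(1, 1, 1L)), 0), "positive")
  expect_error(bin_peaks(list(peak_list(numeric(0), numeric(0), 1L)), 200),
               "no peaks")

  # 30 ions, 30 ppm jitter, spacing > 1000 ppm, 100 pixels:
  # exactly 30 bins with centroids within 20 ppm of truth
  set.seed(4)
  truemz <- sort(600 + cumsum(runif(30, 2, 12)))
  stopifnot(min(diff(truemz) / truemz[-30]) * 1e6 > 1000)
  pls <- lapply(1:100, function(i)
    peak_list(truemz * (1 + rnorm(30, 0, 30e-6)), runif(30, 50, 150), i))
  bb <- bin_peaks(pls, 200)
  expect_length(bb$bins$centroids, 30L)
  expect_lt(max(abs(bb$bins$centroids - truemz) / truemz) * 1e6, 20)
  expect_equal(dim(bb$map$intensities), c(100L, 30L))
  # every pixel contributed every ion exactly once
  expect_true(all(bb$map$intensities > 0))

  # permutation invariance in pixel order: same bins, rows follow the
  # supplied list order
  perm <- rev(seq_along(pls))
  bb2 <- bin_peaks(pls[perm], 200)
  expect_identical(bb2$bins$centroids, bb$bins$centroids)
  expect_identical(bb2$map$intensities, bb$map$intensities[perm, ])
})

test_that("tic_normalize matches its definition and the l1 identity", {
  m <- spectral_map(matrix(c(2, 3, 5), 1), 1:3, cbind(0, 0), "maldi")
  expect_equal(tic_normalize(m)$intensities[1, ], c(0.2, 0.3, 0.5))

  mp <- random_map(nx = 4, ny = 3, p = 6, seed = 9, modality = "maldi")
  expect_equal(tic_normalize(mp)$intensities,
               normalize(mp, "l1")$intensities)
  expect_equal(rowSums(tic_normalize(mp)$intensities), rep(1, 12),
               tolerance = 1e-12)

  z <- spectral_map(rbind(c(0, 0), c(1, 1)), 1:2, cbind(c(0, 75), 0), "maldi")
  expect_error(tic_normalize(z), "pixel")
  dropped <- tic_normalize(z, on_zero = "drop")
  expect_equal(n_pixels(dropped), 1L)
  expect_equal(dropped$meta$dropped_pixels, 1L)
})

test_that("normalize_ms covers the alternative normalizations", {
  mp <- random_map(nx = 3, ny = 2, p = 8, seed = 12, modality = "maldi")
  y <- mp$intensities
  expect_equal(normalize_ms(mp, "rms")$intensities,
               y / sqrt(rowMeans(y^2)), ignore_attr = TRUE)
  expect_equal(normalize_ms(mp, "sqrt")$intensities, sqrt(y),
               ignore_attr = TRUE)
  expect_equal(normalize_ms(mp, "log")$intensities, log1p(y),
               ignore_attr = TRUE)
  med <- apply(y, 1, function(r) median(r[r > 0]))
  expect_equal(normalize_ms(mp, "median")$intensities, y / med,
               ignore_attr = TRUE)
  expect_equal(normalize_ms(mp, "tic")$intensities,
               tic_normalize(mp)$intensities)
})

test_that("phase correction before binning can only merge true ions", {
  set.seed(13)
  ions <- test_ions
  sh <- runif(40, -0.25, 0.25)
  m <- profile_map(sh, ions, seed = 13)
  snr <- 8
  plist_of <- function(map) lapply(seq_len(n_pixels(map)), function(i)
    pick_peaks(map$axis, map$intensities[i, ], snr = snr, pixel_id = i))
  n_raw <- length(bin_peaks(plist_of(m), 200)$bins$centroids)
  pc <- phase_correct(m, max_shift = 0.5, anchors = ions)
  n_cor <- length(bin_peaks(plist_of(pc$data), 200)$bins$centroids)
  expect_lte(n_cor, n_raw)
  expect_equal(n_cor, length(ions))
})
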