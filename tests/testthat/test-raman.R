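test_that("interpolate_axis matches linear-interpolation oracles", {
  m <- random_map(nx = 3, ny = 2, p = 10, seed = 2)
  # identity
  same <- interpolate_axis(m, m$axis)
  expect_equal(same$intensities, m$intensities, ignore_attr = TRUE)

  # midpoint of a 2-point segment
  seg <- spectral_map(matrix(c(0, 4), 1), c(0, 2), cbind(0, 0))
  expect_equal(interpolate_axis(seg, 1)$intensities[1, 1], 2)

  # restriction back to original knots reproduces piecewise-linear data
  set.seed(4)
  knots <- sort(runif(12, 0, 100))
  vals <- matrix(runif(24), 2)
  pw <- spectral_map(vals, knots, cbind(c(0, 25), 0))
  dense <- sort(c(knots, runif(40, min(knots), max(knots))))
  back <- interpolate_axis(interpolate_axis(pw, dense), knots)
  expect_equal(back$intensities, pw$intensities, tolerance = 1e-12,
               ignore_attr = TRUE)

  expect_error(interpolate_axis(m, c(min(m$axis) - 1, max(m$axis))),
               "extrapolation")
})

test_that("interpolation moves a single-peak argmax by less than one pitch", {
  ax <- seq(1000, 1200, by = 2)
  y <- exp(-(ax - 1100)^2 / (2 * 15^2))
  m <- spectral_map(rbind(y, y * 2), ax, cbind(c(0, 25), 0))
  tgt <- seq(1001, 1199, by = 2)
  out <- interpolate_axis(m, tgt)
  expect_lt(abs(tgt[which.max(out$intensities[1, ])] -
                  ax[which.max(y)]), 2 + 1e-9)
})

test_that("spike detection: smooth fields are clean, shared bands spared", {
  nx <- 8; ny <- 8; p <- 12
  coords <- cbind(rep((0:(nx - 1)) * 25, ny), rep((0:(ny - 1)) * 25, each = nx))
  # smooth noiseless map (linear in position => zero spatial curvature)
  q <- 0.03 * coords[, 1] + 0.01 * coords[, 2] + 2
  m <- spectral_map(q %o% seq(1, 2, length.out = p), seq_len(p), coords)
  msk <- detect_spikes(m, z_threshold = 1)
  expect_equal(sum(msk$flags), 0L)

  # a sharp band present in every pixel has no spatial curvature
  band <- c(0, 0, 0, 0, 0, 30, 0, 0, 0, 0, 0, 0)
  set.seed(1)
  Y <- matrix(rnorm(nx * ny * p, sd = 0.5), nx * ny, p) +
    rep(1, nx * ny) %o% band
  mb <- spectral_map(Y, seq_len(p), coords)
  mskb <- detect_spikes(mb, 8)
  expect_equal(sum(mskb$flags[, 6]), 0L)

  expect_error(detect_spikes(spectral_map(matrix(1:5, 1), 1:5, cbind(0, 0))),
               "1D fallback")
})

test_that("injected spikes are found with high recall and few false alarms", {
  sm <- spiky_map(seed = 7)
  msk <- detect_spikes(sm$map, z_threshold = 8)
  recall <- mean(msk$flags[sm$cells])
  fp <- (sum(msk$flags) - sum(msk$flags[sm$cells])) /
    (length(msk$flags) - nrow(sm$cells))
  expect_gte(recall, 0.95)
  expect_lte(fp, 0.001)

  # detect -> remove -> detect never increases the flag count
  cleaned <- remove_spikes(sm$map, msk)
  msk2 <- detect_spikes(cleaned, 8)
  expect_lte(sum(msk2$flags), sum(msk$flags))
})

test_that("remove_spikes interpolates flagged cells and nothing else", {
  m <- random_map(nx = 3, ny = 3, p = 7, seed = 3)
  empty <- structure(list(flags = matrix(FALSE, 9, 7),
                          score = matrix(0, 9, 7)), class = "SpikeMask")
  expect_identical(remove_spikes(m, empty)$intensities, m$intensities)

  flags <- matrix(FALSE, 9, 7)
  flags[2, 4] <- TRUE        # interior cell
  flags[5, 1] <- TRUE        # first channel
  flags[7, 3:4] <- TRUE      # a run of two adjacent channels
  msk <- structure(list(flags = flags, score = matrix(0, 9, 7)),
                   class = "SpikeMask")
  out <- remove_spikes(m, msk)
  ax <- m$axis
  # interior: linear interpolation between channel 3 and 5
  w <- (ax[4] - ax[3]) / (ax[5] - ax[3])
  expect_equal(out$intensities[2, 4],
               (1 - w) * m$intensities[2, 3] + w * m$intensities[2, 5])
  # boundary: constant extension from the nearest unflagged channel
  expect_equal(out$intensities[5, 1], m$intensities[5, 2])
  # untouched cells are bit-identical
  expect_identical(out$intensities[-c(2, 5, 7), ],
                   m$intensities[-c(2, 5, 7), ])

  allf <- structure(list(flags = matrix(TRUE, 9, 7),
                         score = matrix(0, 9, 7)), class = "SpikeMask")
  expect_error(remove_spikes(m, allf), "unrecoverable")
  expect_error(remove_spikes(m, structure(list(flags = matrix(FALSE, 2, 2)),
                                          class = "SpikeMask")),
               "does not match")
})

test_that("normalize implements the three norms and their distinctions", {
  m <- spectral_map(rbind(c(3, 4), c(-1, 3)), c(1, 2), cbind(c(0, 25), 0))
  expect_equal(normalize(m, "l2")$intensities[1, ], c(0.6, 0.8))
  expect_equal(normalize(m, "l1")$intensities[2, ], c(-0.25, 0.75))
  expect_equal(normalize(m, "total_intensity")$intensities[2, ],
               c(-0.5, 1.5))

  # on non-negative spectra l1 and total_intensity coincide
  mp <- random_map(nx = 3, ny = 2, p = 5, seed = 6)
  expect_equal(normalize(mp, "l1")$intensities,
               normalize(mp, "total_intensity")$intensities)

  # unit-norm property
  set.seed(10)
  mr <- spectral_map(matrix(rnorm(60), 10), 1:6,
                     cbind(seq(0, 225, by = 25), 0))
  expect_equal(rowSums(normalize(mr, "l2")$intensities^2), rep(1, 10),
               tolerance = 1e-12)
  expect_equal(rowSums(abs(normalize(mr, "l1")$intensities)), rep(1, 10),
               tolerance = 1e-12)

  z <- spectral_map(rbind(c(0, 0), c(1, 1)), c(1, 2), cbind(c(0, 25), 0))
  expect_error(normalize(z, "l2"), "pixel\\(s\\) 1")
  neg <- spectral_map(rbind(c(-2, 1), c(1, 1)), c(1, 2), cbind(c(0, 25), 0))
  expect_error(normalize(neg, "total_intensity"), "pixel\\(s\\) 1")
})
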