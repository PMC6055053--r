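test_that("fit_affine handles exact and noisy landmark systems", {
  src <- rbind(c(0, 0), c(1000, 0), c(0, 800))
  id <- fit_affine(landmark_set(src, src))
  expect_equal(id$A, diag(2), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(id$t, c(0, 0), tolerance = 1e-12)
  expect_equal(max(id$fit_residuals), 0, tolerance = 1e-9)

  tr <- fit_affine(landmark_set(src, src + rep(1, 3) %o% c(5, -3)))
  expect_equal(tr$A, diag(2), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(tr$t, c(5, -3), tolerance = 1e-9)
})

test_that("noisy affine fit beats a dense grid-search oracle", {
  set.seed(5)
  th <- 17 * pi / 180; s <- 1.3; tv <- c(120, -60)
  A <- s * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  src <- rbind(c(0, 0), c(1000, 0), c(1000, 800), c(0, 800),
               c(500, 0), c(0, 400))
  tgt <- src %*% t(A) + rep(1, 6) %o% tv + matrix(rnorm(12, 0, 0.5), 6)
  fit <- fit_affine(landmark_set(src, tgt))

  # parameter recovery within 2%
  s_hat <- sqrt(abs(det(fit$A)))
  th_hat <- atan2(fit$A[2, 1], fit$A[1, 1])
  expect_lt(abs(s_hat - s) / s, 0.02)
  expect_lt(abs(th_hat - th) / th, 0.02)

  # RSS <= best similarity transform on a coarse grid (translation solved
  # in closed form per candidate)
  rss <- sum(fit$fit_residuals^2)
  best <- Inf
  for (ang in seq(16, 18, by = 0.05) * pi / 180)
    for (sc in seq(1.25, 1.35, by = 0.005)) {
      Ac <- sc * matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
      pred <- src %*% t(Ac)
      tc <- colMeans(tgt - pred)
      best <- min(best, sum((sweep(pred, 2, -tc) - tgt)^2))
    }
  expect_lte(rss, best + 1e-9)
})

test_that("apply_affine and its inverse are consistent", {
  tr <- structure(list(A = matrix(c(1.2, 0.3, -0.2, 0.9), 2),
                       t = c(5, -3)), class = "Affine2D")
  expect_equal(apply_affine(tr, cbind(0, 0)),
               cbind(5, -3), ignore_attr = TRUE)
  id <- structure(list(A = diag(2), t = c(0, 0)), class = "Affine2D")
  x <- matrix(rnorm(20), 10)
  expect_equal(apply_affine(id, x), x, ignore_attr = TRUE)
  expect_lt(max(abs(apply_affine(invert_affine(tr),
                                 apply_affine(tr, x)) - x)), 1e-9)
})

test_that("resample_to_grid averages by nearest target point", {
  m <- random_map(nx = 4, ny = 4, p = 5, seed = 7)
  # identity: source grid == target grid
  rs <- resample_to_grid(m, m$coords)
  expect_equal(rs$map$intensities, m$intensities, ignore_attr = TRUE)
  expect_true(all(rs$counts == 1L))

  # two pixels nearest one target: arithmetic mean, count 2
  src <- spectral_map(rbind(c(1, 1), c(3, 3)), c(1, 2),
                      cbind(c(10, 20), 0))
  rs2 <- resample_to_grid(src, cbind(15, 0))
  expect_equal(rs2$map$intensities[1, ], c(2, 2))
  expect_equal(rs2$counts, 2L)

  # per-channel bounds: min <= mean <= max over assigned spectra
  big <- random_map(nx = 6, ny = 6, p = 4, seed = 8)
  tgt <- cbind(c(30, 100), c(30, 100))
  rs3 <- resample_to_grid(big, tgt)
  expect_true(all(rs3$map$intensities <=
                    apply(big$intensities, 2, max) + 1e-12))
  expect_true(all(rs3$map$intensities >=
                    apply(big$intensities, 2, min) - 1e-12))
  expect_equal(sum(rs3$counts), n_pixels(big))

  expect_error(resample_to_grid(big, cbind(1e6, 1e6), max_distance = 10),
               "do not overlap")
})

test_that("assignment agrees with a brute-force all-pairs oracle", {
  set.seed(9)
  src_xy <- cbind(runif(500, 0, 1000), runif(500, 0, 1000))
  tgt_xy <- cbind(runif(60, 0, 1000), runif(60, 0, 1000))
  Y <- matrix(runif(500 * 3), 500)
  m <- spectral_map(Y, 1:3, src_xy)
  rs <- resample_to_grid(m, tgt_xy)

  D <- outer(src_xy[, 1], tgt_xy[, 1], "-")^2 +
    outer(src_xy[, 2], tgt_xy[, 2], "-")^2
  oracle_assign <- apply(D, 1, which.min)
  oracle_counts <- tabulate(oracle_assign, 60)
  expect_equal(rs$counts, oracle_counts)
  for (j in which(oracle_counts > 0)) {
    expect_equal(rs$map$intensities[j, ],
                 colMeans(Y[oracle_assign == j, , drop = FALSE]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  miss <- which(oracle_counts == 0)
  expect_equal(rs$map$meta$missing_pixels, miss)
  expect_true(all(is.na(rs$map$intensities[miss, ])))
})

test_that("25 um pitch into 75 um pitch gives ~9 spectra per interior cell", {
  # source pixel centres offset so each 75 um cell holds a 3x3 block
  src_xy <- cbind(rep((0:23) * 25, 24), rep((0:23) * 25, each = 24)) - 25
  tgt_xy <- cbind(rep((0:7) * 75, 8), rep((0:7) * 75, each = 8))
  m <- spectral_map(matrix(1, 576, 2), 1:2, src_xy)
  rs <- resample_to_grid(m, tgt_xy)
  interior <- which(tgt_xy[, 1] > 0 & tgt_xy[, 1] < 525 &
                      tgt_xy[, 2] > 0 & tgt_xy[, 2] < 525)
  expect_true(all(rs$counts[interior] >= 7))
  expect_true(all(rs$counts[interior] <= 9))
})

test_that("equidistant ties break deterministically by (y, x) order", {
  src <- spectral_map(matrix(1:2, 1), 1:2, cbind(50, 0))
  tgt <- rbind(c(0, 0), c(100, 0))   # both at distance 50
  rs <- resample_to_grid(src, tgt)
  expect_equal(rs$counts, c(1L, 0L))
  # same with targets supplied in the other order
  rs2 <- resample_to_grid(src, tgt[2:1, ])
  expect_equal(rs2$counts, c(0L, 1L))
})

test_that("drop_pixels removes rows consistently", {
  m <- random_map(nx = 3, ny = 3, p = 4, seed = 10)
  d <- drop_pixels(m, c(2, 5))
  expect_equal(n_pixels(d), 7L)
  expect_equal(d$intensities, m$intensities[-c(2, 5), ],
               ignore_attr = TRUE)
  expect_equal(d$coords, m$coords[-c(2, 5), ], ignore_attr = TRUE)
})
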