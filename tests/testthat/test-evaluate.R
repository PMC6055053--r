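test_that("pca matches analytic and oracle results", {
  # only the first column varies
  X <- cbind(c(1, 2, 3, 4), 5, 7)
  m1 <- pca(X, k = 1)
  expect_equal(m1$explained, 1, tolerance = 1e-12)

  # 2D Gaussian with variances (4, 1): explained ~ (0.8, 0.2)
  set.seed(1)
  Z <- cbind(rnorm(1e5, sd = 2), rnorm(1e5, sd = 1))
  m2 <- pca(Z, k = 2)
  expect_equal(m2$explained, c(0.8, 0.2), tolerance = 0.01)

  # full-SVD/eigen oracle equivalence up to column sign on random inputs
  set.seed(2)
  for (rep in 1:3) {
    X <- matrix(rnorm(50 * 30), 50)
    k <- 8
    m <- pca(X, k = k)
    Xc <- scale(X, scale = FALSE)
    eig <- eigen(crossprod(Xc), symmetric = TRUE)
    expect_lt(max(abs(m$explained - eig$values[1:k] / sum(eig$values))),
              1e-8)
    for (j in 1:k) {
      v <- eig$vectors[, j]
      expect_lt(min(max(abs(m$loadings[, j] - v)),
                    max(abs(m$loadings[, j] + v))), 1e-8)
      s <- Xc %*% v
      expect_lt(min(max(abs(m$scores[, j] - s)),
                    max(abs(m$scores[, j] + s))), 1e-8)
    }
    # orthonormal loadings, non-increasing explained
    expect_equal(crossprod(m$loadings), diag(k), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_true(all(diff(m$explained) <= 1e-12))
  }

  expect_error(pca(matrix(rnorm(12), 4), k = 4), "k must be")
  expect_error(pca(matrix(1, 4, 3), k = 2), "zero variance")
  # sign convention: largest-magnitude loading element positive
  m3 <- pca(matrix(rnorm(200), 20), k = 3)
  for (j in 1:3)
    expect_gt(m3$loadings[which.max(abs(m3$loadings[, j])), j], 0)
})

test_that("cumulative_curve is a running sum capped at 1", {
  mod <- structure(list(explained = c(0.5, 0.3, 0.2),
                        cumulative = cumsum(c(0.5, 0.3, 0.2))),
                   class = "PCAModel")
  expect_equal(cumulative_curve(mod, 3), c(0.5, 0.8, 1.0))
  expect_equal(cumulative_curve(mod, 1), 0.5)
  expect_error(cumulative_curve(mod, 4), "between 1 and 3")

  set.seed(3)
  X <- matrix(rnorm(20 * 6), 20)
  full <- pca(X, k = 6)
  cc <- cumulative_curve(full)
  expect_true(all(diff(cc) >= -1e-12))
  expect_equal(cc[6], 1, tolerance = 1e-10)
})

test_that("explained proportions are invariant to global scaling", {
  set.seed(4)
  X <- matrix(rnorm(40 * 10), 40)
  expect_equal(pca(X, 5)$explained, pca(7.3 * X, 5)$explained,
               tolerance = 1e-12)
})

test_that("weight_sweep brackets the unweighted and single-block limits", {
  set.seed(5)
  n <- 30
  coords <- cbind(seq_len(n) * 75, 0)
  A <- spectral_map(matrix(rnorm(n * 8), n), seq_len(8) * 100, coords,
                    "raman")
  B <- spectral_map(matrix(abs(rnorm(n * 5)), n), 700 + seq_len(5), coords,
                    "maldi")
  k <- 5
  sw <- weight_sweep(A, B, coefficients = c(1, 5, 20, 1e6), k = k)
  expect_equal(dim(sw$curves), c(4L, k))
  expect_true(all(apply(sw$curves, 1, function(r) all(diff(r) >= -1e-12))))

  # the c = 1 row is exactly the unweighted fused PCA curve
  expect_equal(sw$curves[1, ],
               cumulative_curve(pca(fuse_blocks(A, B, w = 1), k = k)))

  # c -> infinity approaches PCA of B alone in first-PC proportion
  pb <- pca(B, k = 1)
  expect_lt(abs(sw$curves[4, 1] - pb$explained[1]), 1e-3)

  # weighting genuinely matters when both blocks vary
  expect_false(isTRUE(all.equal(sw$curves[1, ], sw$curves[3, ],
                                tolerance = 1e-6)))
  expect_length(sw$argmin_per_k, k)
})

test_that("split_loadings partitions by provenance and concatenates back", {
  p <- list(A = spectral_map(matrix(rnorm(40), 8), seq_len(5) * 100,
                             cbind(seq_len(8) * 75, 0), "raman"),
            B = spectral_map(matrix(abs(rnorm(24)), 8), 700 + seq_len(3),
                             cbind(seq_len(8) * 75, 0), "maldi"))
  f <- fuse_blocks(p$A, p$B, w = 2)
  m <- pca(f, k = 3)
  parts <- split_loadings(m)
  expect_equal(nrow(parts$raman), 5L)
  expect_equal(nrow(parts$maldi), 3L)
  expect_equal(rbind(parts$raman, parts$maldi), m$loadings,
               ignore_attr = TRUE)
  expect_error(split_loadings(m, data.frame(block = "x", channel = 1)),
               "provenance covers")
  expect_error(split_loadings(pca(matrix(rnorm(40), 8), 2)),
               "no provenance")
})

test_that("rgb_composite rasterizes scores with robust scaling", {
  nx <- 6; ny <- 5
  coords <- cbind(rep((0:(nx - 1)) * 75, ny), rep((0:(ny - 1)) * 75, each = nx))
  # constant scores -> uniform mid-gray
  comp <- rgb_composite(matrix(1, nx * ny, 3), coords, 1:3)
  expect_equal(dim(comp), c(ny, nx, 3L))
  expect_true(all(comp == 0.5))

  # one-hot spatial blocks per PC -> saturated primary colours
  s <- matrix(0, nx * ny, 3)
  s[coords[, 1] < 150, 1] <- 1
  s[coords[, 1] >= 150 & coords[, 1] < 300, 2] <- 1
  s[coords[, 1] >= 300, 3] <- 1
  comp2 <- rgb_composite(s, coords, 1:3)
  red_cell <- c(1, 1); blue_cell <- c(1, nx)
  expect_equal(comp2[red_cell[1], red_cell[2], ], c(1, 0, 0))
  expect_equal(comp2[blue_cell[1], blue_cell[2], ], c(0, 0, 1))

  # sub-pitch scatter collapses onto shared raster cells -> not a grid
  expect_error(rgb_composite(matrix(1, 3, 3),
                             cbind(c(0, 1e-9, 5), c(0, 0, 0)), 1:3),
               "rectangular grid")
  expect_error(rgb_composite(matrix(1, nx * ny, 2), coords, 1:3),
               "3 valid component")

  # missing pixels render neutral grey
  keep <- -2L
  comp3 <- rgb_composite(s[keep, ], coords[keep, ], 1:3)
  expect_equal(comp3[1, 2, ], c(0.5, 0.5, 0.5))
  expect_gte(composite_roughness(comp3), 0)
})

test_that("cross_correlation matches cor() semantics with NA flags", {
  n <- 20
  coords <- cbind(seq_len(n) * 75, 0)
  set.seed(6)
  MA <- matrix(rnorm(n * 4), n)
  MB <- cbind(MA[, 2], -MA[, 3], rnorm(n), rep(1, n))
  A <- spectral_map(MA, seq_len(4) * 100, coords, "raman")
  B <- spectral_map(MB + 10, 700 + seq_len(4), coords, "maldi")
  B$intensities <- MB   # keep the constant column constant
  r <- cross_correlation(A, B)
  expect_equal(r[2, 1], 1, tolerance = 1e-12)
  expect_equal(r[3, 2], -1, tolerance = 1e-12)
  expect_true(all(is.na(r[, 4])))

  expect_error(cross_correlation(spectral_map(MA[1:2, ], 1:4,
                                              coords[1:2, ]), B),
               "pixel")

  # null: independent Gaussian channels, n = 1000 -> 99% of |r| < 0.1
  set.seed(7)
  co <- cbind(seq_len(1000) * 10, 0)
  An <- spectral_map(matrix(rnorm(1000 * 30), 1000), seq_len(30), co)
  Bn <- spectral_map(matrix(rnorm(1000 * 40), 1000), 700 + seq_len(40), co,
                     "maldi")
  rn <- cross_correlation(An, Bn)
  expect_gte(mean(abs(rn) < 0.1), 0.99)
})
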