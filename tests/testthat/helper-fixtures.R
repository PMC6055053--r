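# shared fixture builders; everything is generated in code at test time

# random valid map on an nx x ny grid
random_map <- function(nx = 4, ny = 3, p = 6, pitch = 25, seed = 1,
                       modality = "raman") {
  set.seed(seed)
  coords <- cbind(rep((seq_len(nx) - 1) * pitch, ny),
                  rep((seq_len(ny) - 1) * pitch, each = nx))
  spectral_map(matrix(runif(nx * ny * p, 0, 100), nx * ny, p),
               sort(runif(p, 600, 1800)), coords, modality)
}

# profile MALDI map with known ion positions and per-pixel m/z shifts
profile_map <- function(shifts, ions, heights = NULL, seed = 1,
                        resolution = 3000, noise_sd = 0.5,
                        axis = seq(600, 900, by = 0.05)) {
  set.seed(seed)
  n <- length(shifts)
  Y <- matrix(0, n, length(axis))
  for (i in seq_len(n)) {
    y <- numeric(length(axis))
    for (j in seq_along(ions)) {
      mz <- ions[j]
      h <- if (is.null(heights)) runif(1, 50, 150) else heights[j]
      sdw <- mz / (resolution * 2.355)
      win <- which(abs(axis - mz - shifts[i]) < 10 * sdw)
      y[win] <- y[win] + h * exp(-(axis[win] - mz - shifts[i])^2 / (2 * sdw^2))
    }
    Y[i, ] <- y + rnorm(length(axis), 0, noise_sd)
  }
  spectral_map(Y, axis, cbind(seq_len(n), 0), "maldi")
}

test_ions <- c(620.4, 655.3, 703.6, 734.6, 772.5, 810.6, 826.6, 850.5,
               868.4, 884.3)

# Raman-like raster with smooth bands, smooth fluorescence and noise;
# returns the map plus injected spike bookkeeping
spiky_map <- function(seed = 7, nx = 40, ny = 40, p = 120, n_spikes = 20) {
  set.seed(seed)
  coords <- cbind(rep((0:(nx - 1)) * 25, ny), rep((0:(ny - 1)) * 25, each = nx))
  ax <- seq(600, 1800, length.out = p)
  n <- nx * ny
  f1 <- exp(-((coords[, 1] - 400)^2 + (coords[, 2] - 500)^2) / (2 * 300^2))
  f2 <- exp(-((coords[, 1] - 700)^2 + (coords[, 2] - 200)^2) / (2 * 250^2))
  S <- t(vapply(seq_len(n), function(i)
    20 * f1[i] * exp(-(ax - 800)^2 / 450) +
      25 * f2[i] * exp(-(ax - 1200)^2 / 800) +
      15 * exp(-(ax - 1600)^2 / 1250), numeric(p)))
  blfield <- function(lo, hi) {
    v <- numeric(n)
    for (b in 1:4) {
      ctr <- runif(2, 0, 975); s2 <- runif(1, 300, 700)^2
      v <- v + runif(1, -1, 1) *
        exp(-((coords[, 1] - ctr[1])^2 + (coords[, 2] - ctr[2])^2) / (2 * s2))
    }
    v <- (v - min(v)) / max(diff(range(v)), 1e-9)
    lo + (hi - lo) * v
  }
  u <- (ax - 600) / 1200
  B <- cbind(blfield(40, 120), blfield(-40, 40), blfield(-30, 30)) %*%
    rbind(1, u, u^2)
  Y <- S + B + matrix(rnorm(n * p), n)
  cells <- cbind(sample(n, n_spikes), sample(5:(p - 5), n_spikes))
  amps <- numeric(n_spikes)
  for (s in seq_len(n_spikes)) {
    w <- max(1, cells[s, 2] - 15):min(p, cells[s, 2] + 15)
    # spike amplitude = 10 x local MAD of the raw data around the cell
    amps[s] <- 10 * 1.4826 * mad(Y[cells[s, 1], w], constant = 1)
    Y[cells[s, 1], cells[s, 2]] <- Y[cells[s, 1], cells[s, 2]] + amps[s]
  }
  list(map = spectral_map(Y, ax, coords, "raman"), cells = cells,
       amps = amps)
}

# small, fast phantom for pipeline-level tests
small_synth <- list(maldi_nx = 10L, maldi_ny = 10L,
                    raman_nx = 32L, raman_ny = 32L,
                    maldi_axis = seq(600, 900, by = 0.1),
                    n_spikes = 10L)

expect_map_equal <- function(a, b, tol = 1e-9) {
  expect_equal(a$axis, b$axis, tolerance = tol)
  expect_equal(a$coords, b$coords, tolerance = tol, ignore_attr = TRUE)
  expect_equal(a$intensities, b$intensities, tolerance = tol,
               ignore_attr = TRUE)
  expect_identical(a$modality, b$modality)
}
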