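# Phantom generator: paired Raman/MALDI maps with known ground truth.
#
# The phantom emulates the geometry of a correlated imaging experiment: a
# Raman raster at 25 um pitch in its own coordinate frame, rotated and
# translated relative to a MALDI raster at 75 um pitch, with shared
# smooth spatial structure, modality-specific signals, a low-intensity
# MALDI-only lipid component with isotope envelopes, per-pixel
# fluorescence baselines, cosmic spikes, chemical-noise background, m/z
# jitter and multiplicative TIC variation.

#' Phantom configuration
#'
#' Returns the default configuration of [generate_phantom()]; any field
#' can be overridden by name. Defaults describe the stated world of the
#' package's validation experiments and are discussed in the methods
#' vignette; the headline property is that the lipid component's raw
#' signal energy is 1% (`lipid_energy_ratio = 0.01`) of the Raman block's,
#' so that unweighted fusion cannot expose it but l1-ratio weighting can.
#'
#' @param ... named overrides of the defaults.
#' @return named list of class `PhantomConfig`.
#' @export
phantom_config <- function(...) {
  cfg <- list(
    maldi_nx = 20L, maldi_ny = 20L, maldi_pitch = 75,
    raman_nx = 64L, raman_ny = 64L, raman_pitch = 25,
    raman_axis = seq(600, 1800, by = 2),
    maldi_axis = seq(600, 900, by = 0.05),
    rotation_deg = 2, translation = c(40, -25),
    # component 1: protein/grey-matter-like, 2: nucleic/white-matter-like,
    # 3: the MALDI-only lipid component (no Raman endmember)
    raman_bands = list(
      list(center = c(1004, 1340, 1660), width = c(8, 18, 14),
           height = c(1, 0.5, 0.8)),
      list(center = c(785, 1094, 1575), width = c(10, 12, 12),
           height = c(0.7, 0.6, 0.9)),
      list(center = numeric(0), width = numeric(0), height = numeric(0))),
    maldi_ions = list(c(703.58, 760.59), c(798.54, 826.57),
                      c(734.57, 772.53, 810.60)),
    ion_base = c(1000, 1000, NA),       # lipid base set by the energy ratio
    # spatially uniform matrix-cluster ions (CHCA-like): they dominate the
    # TIC, which keeps TIC normalization from imprinting compositional
    # closure on the minor ions, and they provide the stable intense
    # anchor peaks that phase correction relies on
    matrix_ions = c(609.28, 634.26, 666.42, 688.53),
    matrix_base = 2500,
    isotope_ratios = c(1, 0.6, 0.2),
    isotope_spacing = 1.0034,
    lipid_energy_ratio = 0.01,
    raman_amplitude = 500,
    raman_noise_sd = 4,
    n_spikes = 30L,
    spike_range = c(2000, 10000),
    baseline_const = c(60, 140),
    baseline_coef = 40,
    resolution = 6000,
    mz_jitter = 0.15,
    chem_bg = 12, chem_bg_tau = 300,
    tic_cv = 0.2,
    maldi_noise_scale = 1,
    n_blobs = 6L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown phantom config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "PhantomConfig")
}

grid_coords <- function(nx, ny, pitch) {
  cbind(x = rep((seq_len(nx) - 1) * pitch, times = ny),
        y = rep((seq_len(ny) - 1) * pitch, each = nx))
}

pseudo_voigt <- function(axis, center, width, eta = 0.3) {
  g <- exp(-(axis - center)^2 / (2 * (width / 2.355)^2))
  l <- 1 / (1 + ((axis - center) / (width / 2))^2)
  (1 - eta) * g + eta * l
}

# raw smooth field: random Gaussian blobs plus one geometric region
make_raw_field <- function(domain, n_blobs, geom) {
  centers <- cbind(stats::runif(n_blobs, 0, domain[1]),
                   stats::runif(n_blobs, 0, domain[2]))
  sds <- stats::runif(n_blobs, 150, 400)
  amps <- stats::runif(n_blobs, 0.5, 1.5) * sample(c(-1, 1), n_blobs,
                                                   replace = TRUE)
  function(x, y) {
    v <- numeric(length(x))
    for (b in seq_len(n_blobs))
      v <- v + amps[b] * exp(-((x - centers[b, 1])^2 +
                               (y - centers[b, 2])^2) / (2 * sds[b]^2))
    v + geom(x, y)
  }
}

# Turn K raw fields into abundance maps in [0, 1] that are (empirically)
# decorrelated on the MALDI grid: random blob fields can correlate
# strongly by chance, which would confound "which component does this PC
# recover"; Cholesky whitening of the raw values followed by a logistic
# squash keeps the fields smooth while making the true components
# spatially independent, so recovery correlations are attributable.
make_field_eval <- function(raw_fns, calib_xy) {
  raw <- vapply(raw_fns, function(f) f(calib_xy[, 1], calib_xy[, 2]),
                numeric(nrow(calib_xy)))
  mu <- colMeans(raw)
  W <- solve(chol(stats::cov(raw)))
  function(x, y) {
    r <- vapply(raw_fns, function(f) f(x, y), numeric(length(x)))
    stats::plogis((sweep(r, 2L, mu) %*% W) / 1.2)
  }
}

#' Generate a paired Raman/MALDI phantom with ground truth
#'
#' Builds K = 3 smooth abundance fields in the MALDI frame (two shared
#' components and one MALDI-only lipid component), then renders:
#'
#' * a Raman map on its own 25 um grid, rotated/translated relative to
#'   the MALDI frame by a known affine transform: abundance-weighted
#'   pseudo-Voigt bands + per-pixel cubic fluorescence baseline +
#'   Gaussian noise + sparse single-cell cosmic spikes (raw intensities
#'   are non-negative by construction);
#' * a MALDI profile map on the 75 um grid: Gaussian ion peaks whose
#'   width grows with m/z (constant resolving power), 3-peak isotope
#'   envelopes, per-pixel uniform m/z jitter, an exponentially decaying
#'   chemical-noise background, multiplicative TIC variation and
#'   Poisson-like noise (variance proportional to signal).
#'
#' The lipid component's noiseless signal energy is scaled to
#' `lipid_energy_ratio` times the Raman block's, which is what makes the
#' weighted-vs-unweighted fusion contrast testable. The same seed gives
#' bit-identical output.
#'
#' @param config a [phantom_config()].
#' @param seed integer RNG seed.
#' @return list with `raman` (`SpectralMap`, Raman frame), `maldi`
#'   (`SpectralMap`, raw profile, MALDI frame) and `truth`
#'   (`PhantomTruth`: abundance maps on both grids, endmembers, the ion
#'   table with noiseless peak-height maps, exact landmarks and
#'   transform, and the seed).
#' @export
generate_phantom <- function(config = phantom_config(), seed = 42L) {
  stopifnot(inherits(config, "PhantomConfig"))
  K <- 3L
  if (length(config$raman_bands) != K || length(config$maldi_ions) != K)
    stop("config must describe exactly ", K, " components")
  if (config$maldi_nx < 8L || config$maldi_ny < 8L)
    stop("MALDI grid must be at least 8 x 8")
  set.seed(as.integer(seed))
  cfg <- config

  maldi_xy <- grid_coords(cfg$maldi_nx, cfg$maldi_ny, cfg$maldi_pitch)
  raman_xy <- grid_coords(cfg$raman_nx, cfg$raman_ny, cfg$raman_pitch)
  th <- cfg$rotation_deg * pi / 180
  A <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  transform <- structure(list(A = A, t = as.numeric(cfg$translation)),
                         class = "Affine2D")
  # centre the transformed Raman footprint on the MALDI footprint
  centre_shift <- colMeans(maldi_xy) -
    colMeans(apply_affine(transform, raman_xy))
  transform$t <- unname(transform$t + centre_shift)
  raman_in_maldi <- apply_affine(transform, raman_xy)

  domain <- c((cfg$maldi_nx - 1) * cfg$maldi_pitch,
              (cfg$maldi_ny - 1) * cfg$maldi_pitch)
  geoms <- list(
    function(x, y) 1.4 * stats::plogis(
      (250 - sqrt((x - 0.3 * domain[1])^2 + (y - 0.35 * domain[2])^2)) / 40),
    function(x, y) 1.4 * stats::plogis((y - 0.65 * domain[2]) / 60) *
      stats::plogis((0.9 * domain[2] - y) / 60),
    function(x, y) 1.4 * stats::plogis(
      (220 - sqrt((x - 0.72 * domain[1])^2 + (y - 0.3 * domain[2])^2)) / 40))
  raw_fns <- lapply(geoms, function(g) make_raw_field(domain, cfg$n_blobs, g))
  field_eval <- make_field_eval(raw_fns, maldi_xy)
  abund_maldi <- field_eval(maldi_xy[, 1], maldi_xy[, 2])
  abund_raman <- field_eval(raman_in_maldi[, 1], raman_in_maldi[, 2])

  ## ---- Raman map -------------------------------------------------------
  rax <- cfg$raman_axis
  E <- t(vapply(cfg$raman_bands, function(b) {
    e <- numeric(length(rax))
    for (i in seq_along(b$center))
      e <- e + b$height[i] * pseudo_voigt(rax, b$center[i], b$width[i])
    e
  }, numeric(length(rax))))
  raman_signal <- cfg$raman_amplitude * (abund_raman %*% E)
  n_r <- nrow(raman_xy); p_r <- length(rax)
  u <- (rax - min(rax)) / diff(range(rax))
  # fluorescence coefficients vary smoothly across the map (fluorophore
  # content is a tissue property), so the spectral baseline differs from
  # pixel to pixel without creating spatial discontinuities
  smooth_coef <- function(lo, hi) {
    v <- numeric(n_r)
    for (b in 1:4) {
      ctr <- stats::runif(2, 0, c((cfg$raman_nx - 1) * cfg$raman_pitch,
                                  (cfg$raman_ny - 1) * cfg$raman_pitch))
      s2 <- stats::runif(1, 300, 800)^2
      v <- v + stats::runif(1, -1, 1) *
        exp(-((raman_xy[, 1] - ctr[1])^2 +
              (raman_xy[, 2] - ctr[2])^2) / (2 * s2))
    }
    v <- (v - min(v)) / max(diff(range(v)), 1e-9)
    lo + (hi - lo) * v
  }
  bl_coef <- cbind(smooth_coef(cfg$baseline_const[1], cfg$baseline_const[2]),
                   vapply(1:3, function(j)
                     smooth_coef(-cfg$baseline_coef, cfg$baseline_coef),
                     numeric(n_r)))
  baseline <- bl_coef %*% rbind(1, u, u^2, u^3)
  baseline <- baseline - apply(baseline, 1L, min) + 30
  raman_raw <- raman_signal + baseline +
    matrix(stats::rnorm(n_r * p_r, sd = cfg$raman_noise_sd), n_r)
  spike_cells <- cbind(sample.int(n_r, cfg$n_spikes, replace = TRUE),
                       sample.int(p_r, cfg$n_spikes, replace = TRUE))
  spike_cells <- spike_cells[!duplicated(spike_cells), , drop = FALSE]
  raman_raw[spike_cells] <- raman_raw[spike_cells] +
    stats::runif(nrow(spike_cells), cfg$spike_range[1], cfg$spike_range[2])

  ## ---- MALDI map -------------------------------------------------------
  max_ <- cfg$maldi_axis
  n_m <- nrow(maldi_xy); p_m <- length(max_)
  peaks <- do.call(rbind, lapply(seq_len(K), function(k) {
    ions <- cfg$maldi_ions[[k]]
    if (!length(ions)) return(NULL)
    do.call(rbind, lapply(seq_along(ions), function(i)
      data.frame(component = k, ion = paste0("c", k, "i", i),
                 mz = ions[i] + (seq_along(cfg$isotope_ratios) - 1) *
                   cfg$isotope_spacing,
                 coef = cfg$isotope_ratios *
                   c(1, 0.85, 0.7)[min(i, 3L)])))
  }))
  if (length(cfg$matrix_ions)) {
    # component 0: spatially uniform matrix-cluster ions
    peaks <- rbind(do.call(rbind, lapply(seq_along(cfg$matrix_ions),
      function(i) data.frame(component = 0L, ion = paste0("m", i),
                             mz = cfg$matrix_ions[i] +
                               (seq_along(cfg$isotope_ratios) - 1) *
                               cfg$isotope_spacing,
                             coef = cfg$isotope_ratios *
                               stats::runif(1, 0.7, 1)))), peaks)
  }

  # lipid base intensity from the stated energy ratio: the noiseless
  # lipid signal energy is lipid_energy_ratio x the Raman signal energy
  e_raman <- sum(raman_signal^2)
  lip <- peaks$component == K
  unit_prof <- numeric(p_m)
  for (r in which(lip)) {
    sdw <- peaks$mz[r] / (cfg$resolution * 2.355)
    win <- which(abs(max_ - peaks$mz[r]) < 12 * sdw)
    unit_prof[win] <- unit_prof[win] +
      peaks$coef[r] * exp(-(max_[win] - peaks$mz[r])^2 / (2 * sdw^2))
  }
  e_lipid_unit <- sum(unit_prof^2) * sum(abund_maldi[, K]^2)
  base <- cfg$ion_base
  base[K] <- sqrt(cfg$lipid_energy_ratio * e_raman / e_lipid_unit)

  jitter <- stats::runif(n_m, -cfg$mz_jitter, cfg$mz_jitter)
  tic_f <- exp(stats::rnorm(n_m, 0, cfg$tic_cv))
  heights <- matrix(0, n_m, nrow(peaks))   # noiseless peak-height maps
  profile <- matrix(0, n_m, p_m)
  for (r in seq_len(nrow(peaks))) {
    k <- peaks$component[r]
    h <- if (k == 0L) rep(cfg$matrix_base * peaks$coef[r], n_m)
         else abund_maldi[, k] * base[k] * peaks$coef[r]
    heights[, r] <- h
    sdw <- peaks$mz[r] / (cfg$resolution * 2.355)
    win <- which(abs(max_ - peaks$mz[r]) < cfg$mz_jitter + 8 * sdw)
    d <- outer(-jitter, max_[win], "+") - peaks$mz[r]
    profile[, win] <- profile[, win] + h * exp(-d^2 / (2 * sdw^2))
  }
  chem <- outer(tic_f * cfg$chem_bg, exp(-(max_ - min(max_)) / cfg$chem_bg_tau))
  profile <- profile * tic_f + chem
  maldi_raw <- profile +
    sqrt(profile + 1) * cfg$maldi_noise_scale *
      matrix(stats::rnorm(n_m * p_m), n_m)
  maldi_raw <- pmax(maldi_raw, 0)

  ## ---- landmarks and truth --------------------------------------------
  ex <- (cfg$raman_nx - 1) * cfg$raman_pitch
  ey <- (cfg$raman_ny - 1) * cfg$raman_pitch
  src <- rbind(c(0, 0), c(ex, 0), c(ex, ey), c(0, ey),
               c(ex / 2, 0), c(0, ey / 2))
  landmarks <- landmark_set(src, apply_affine(transform, src))

  truth <- structure(
    list(component_maps = list(maldi = abund_maldi, raman = abund_raman),
         raman_endmembers = E,
         ion_table = peaks,
         peak_heights = heights,
         ion_base = base,
         landmarks = landmarks,
         transform = transform,
         lipid_component = K,
         seed = as.integer(seed),
         config = cfg),
    class = "PhantomTruth")

  list(
    raman = spectral_map(raman_raw, rax, raman_xy, modality = "raman",
                         meta = list(phantom_seed = as.integer(seed))),
    maldi = spectral_map(maldi_raw, max_, maldi_xy, modality = "maldi",
                         meta = list(phantom_seed = as.integer(seed))),
    truth = truth)
}

#' @export
print.PhantomTruth <- function(x, ...) {
  cat(sprintf(
    "<PhantomTruth: %d components (lipid = %d), seed %d>\n",
    ncol(x$component_maps$maldi), x$lipid_component, x$seed))
  invisible(x)
}

#' Best recovery of each true component by PC score maps
#'
#' For every true abundance map, the maximum absolute Pearson correlation
#' between it and any of the first `k` PC score maps. Rows of `scores`
#' and `truth_maps` must describe the same pixels in the same order
#' (subset both identically if pixels were dropped during the pipeline).
#' Invariant under negation of any score map.
#'
#' @param scores a `PCAModel` or an `n x >=k` score matrix.
#' @param truth_maps `n x K` matrix of true abundance maps.
#' @param k number of leading components to search (default 3).
#' @return numeric vector of length K: best `|r|` per component.
#' @export
score_recovery <- function(scores, truth_maps, k = 3L) {
  S <- if (inherits(scores, "PCAModel")) scores$scores else as.matrix(scores)
  truth_maps <- as.matrix(truth_maps)
  if (nrow(S) != nrow(truth_maps))
    stop("grid mismatch: ", nrow(S), " score rows vs ",
         nrow(truth_maps), " truth rows")
  k <- min(as.integer(k), ncol(S))
  r <- abs(stats::cor(truth_maps, S[, seq_len(k), drop = FALSE]))
  apply(r, 1L, max)
}
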