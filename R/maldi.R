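# MALDI-specific preprocessing: noise estimation, peak picking, phase
# correction along the m/z axis, mass-relative binning and TIC
# normalization.

#' Robust noise scale of a spectrum
#'
#' Estimates the standard deviation of the additive noise as
#' `1.4826 * MAD(diff(y)) / sqrt(2)`: first-differencing removes smooth
#' signal, MAD ignores the sparse peaks, and the sqrt(2) undoes the
#' variance doubling of the difference.
#'
#' @param y numeric vector, length >= 8.
#' @return non-negative noise scale; 0 with a warning for an all-zero
#'   spectrum.
#' @export
estimate_noise <- function(y) {
  y <- as.numeric(y)
  if (length(y) < 8L) stop("need at least 8 points to estimate noise")
  if (all(y == 0)) {
    warning("all-zero spectrum: noise estimate is 0")
    return(0)
  }
  d <- diff(y)
  1.4826 * stats::median(abs(d - stats::median(d))) / sqrt(2)
}

# per-channel noise scale from block-wise diff-MAD, linearly interpolated
# between block centres; captures the heteroscedastic (shot-noise and
# chemical-background driven) noise floor of MALDI profile spectra
local_noise <- function(y, window = 401L) {
  n <- length(y)
  window <- min(as.integer(window), n)
  starts <- seq(1L, n, by = window)
  centres <- pmin(starts + (window - 1L) / 2, n)
  est <- vapply(starts, function(s) {
    seg <- y[s:min(s + window - 1L, n)]
    if (length(seg) < 8L || all(seg == 0)) return(NA_real_)
    d <- diff(seg)
    1.4826 * stats::median(abs(d - stats::median(d))) / sqrt(2)
  }, numeric(1))
  if (all(is.na(est))) return(rep(0, n))
  est[is.na(est)] <- min(est, na.rm = TRUE)
  if (length(est) == 1L) return(rep(est, n))
  stats::approx(centres, est, xout = seq_len(n), rule = 2)$y
}

# block-wise local level (median), interpolated between block centres;
# SNIP estimates a lower envelope, so the subtracted spectrum keeps a
# small positive offset that peak SNR tests must not count as signal
local_level <- function(y, window = 401L) {
  n <- length(y)
  window <- min(as.integer(window), n)
  starts <- seq(1L, n, by = window)
  centres <- pmin(starts + (window - 1L) / 2, n)
  est <- vapply(starts, function(s)
    stats::median(y[s:min(s + window - 1L, n)]), numeric(1))
  if (length(est) == 1L) return(rep(est, n))
  stats::approx(centres, est, xout = seq_len(n), rule = 2)$y
}

# indices of strict local maxima of y (plateaus take the left edge)
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  i[y[i] > y[i - 1L] & y[i] >= y[i + 1L]]
}

# sub-channel apex position by a parabola through the 3 points around j
refine_apex <- function(axis, y, j) {
  n <- length(y)
  if (j <= 1L || j >= n) return(axis[j])
  den <- y[j - 1L] - 2 * y[j] + y[j + 1L]
  if (den >= 0) return(axis[j])
  delta <- 0.5 * (y[j - 1L] - y[j + 1L]) / den
  delta <- max(-0.5, min(0.5, delta))
  axis[j] + delta * (axis[j + 1L] - axis[j - 1L]) / 2
}

#' Pick peaks from a background-subtracted spectrum
#'
#' Local maxima whose intensity exceeds `snr` times the robust noise scale
#' of [estimate_noise()] become peaks; the reported m/z is the axis value
#' at the maximum. An empty peak list is a valid result. With
#' `noise = "local"` the same diff-MAD estimator is evaluated in blocks
#' of `noise_window` channels, which tracks the heteroscedastic noise
#' floor of real MALDI spectra (shot noise grows with the chemical
#' background towards low m/z), and a peak must additionally rise
#' `snr * noise` above the block-median local level: SNIP backgrounds are
#' lower envelopes, so the subtracted spectrum keeps a small positive
#' offset that must not count as signal. The global estimator remains the
#' default.
#'
#' @param axis strictly increasing m/z axis.
#' @param intensity background-subtracted intensities, same length.
#' @param snr positive signal-to-noise cutoff (default 3).
#' @param pixel_id pixel index recorded in the output.
#' @param noise `"global"` or `"local"` noise estimation.
#' @param noise_window block size (channels) for `noise = "local"`.
#' @return a [peak_list()].
#' @export
pick_peaks <- function(axis, intensity, snr = 3, pixel_id = 1L,
                       noise = c("global", "local"), noise_window = 401L) {
  noise <- match.arg(noise)
  axis <- as.numeric(axis); intensity <- as.numeric(intensity)
  stopifnot(length(axis) == length(intensity), snr > 0)
  if (all(intensity == 0)) {
    thr <- rep(0, length(intensity))
    lvl <- 0
  } else if (noise == "global") {
    thr <- rep(estimate_noise(intensity), length(intensity))
    lvl <- 0
  } else {
    thr <- local_noise(intensity, noise_window)
    lvl <- local_level(intensity, noise_window)
  }
  idx <- local_maxima(intensity)
  idx <- idx[intensity[idx] - (if (length(lvl) > 1L) lvl[idx] else lvl) >
               snr * thr[idx] & intensity[idx] > 0]
  peak_list(axis[idx], intensity[idx], pixel_id = pixel_id)
}

#' Phase correction of the m/z axis
#'
#' Per-pixel m/z axes of MALDI measurements float slightly between
#' acquisitions. The correction picks *anchors* - stable intense peaks of
#' the pixel-mean spectrum above a configurable intensity quantile -
#' matches each anchor to the strongest observed peak of each pixel
#' within `max_shift`, and fits a per-pixel shift by least squares (a constant
#' offset by default, optionally offset + slope * m/z). Profile spectra
#' are then resampled at `axis + shift`; peak lists have the shift
#' subtracted from their m/z values. Apex positions are refined to
#' sub-channel precision by parabolic interpolation.
#'
#' A pixel matching no anchor keeps a zero shift and is flagged in the
#' returned model.
#'
#' @param x a `SpectralMap` of profile spectra, or a list of
#'   [peak_list()] objects (which then requires explicit `anchors`).
#' @param max_shift maximum credible |shift| in Da (default 0.5).
#' @param anchor_quantile intensity quantile of the mean spectrum above
#'   which local maxima become anchors (default 0.99).
#' @param model `"offset"` or `"linear"`.
#' @param anchors optional numeric vector of anchor m/z values; mandatory
#'   for peak-list input.
#' @param min_snr candidate peaks of a pixel must exceed this multiple of
#'   the pixel's local noise floor to be matched to an anchor (profile
#'   input only); keeps noise maxima from hijacking the match.
#' @return list with `data` (corrected object of the same kind) and
#'   `model` (a `PhaseModel`: data frame with per-pixel `offset`, `slope`,
#'   `n_matched`, `flagged`, plus the anchors as an attribute).
#' @export
phase_correct <- function(x, max_shift = 0.5, anchor_quantile = 0.99,
                          model = c("offset", "linear"), anchors = NULL,
                          min_snr = 3) {
  UseMethod("phase_correct")
}

fit_pixel_shift <- function(obs, anc, model) {
  d <- obs - anc
  if (model == "offset" || length(obs) < 2L)
    return(c(offset = mean(d), slope = 0))
  co <- stats::coef(stats::lm.fit(cbind(1, anc), d))
  c(offset = co[[1]], slope = co[[2]])
}

#' @export
phase_correct.SpectralMap <- function(x, max_shift = 0.5,
                                      anchor_quantile = 0.99,
                                      model = c("offset", "linear"),
                                      anchors = NULL, min_snr = 3) {
  model <- match.arg(model)
  validate_spectral_map(x)
  mean_spec <- colMeans(x$intensities)
  if (is.null(anchors)) {
    cand <- local_maxima(mean_spec)
    thr <- stats::quantile(mean_spec, anchor_quantile, names = FALSE)
    cand <- cand[mean_spec[cand] > thr]
    anchors <- vapply(cand, function(j) refine_apex(x$axis, mean_spec, j),
                      numeric(1))
  }
  if (length(anchors) < 2L)
    stop("no stable intense peaks: fewer than 2 anchors above the ",
         anchor_quantile, " quantile of the mean spectrum")

  n <- n_pixels(x)
  out <- x$intensities
  tab <- data.frame(pixel = seq_len(n), offset = 0, slope = 0,
                    n_matched = 0L, flagged = FALSE)
  for (i in seq_len(n)) {
    y <- x$intensities[i, ]
    idx <- local_maxima(y)
    if (length(idx) && min_snr > 0 && !all(y == 0)) {
      nz <- local_noise(y)
      lv <- local_level(y)
      idx <- idx[y[idx] - lv[idx] > min_snr * nz[idx]]
    }
    if (length(idx)) {
      pos <- vapply(idx, function(j) refine_apex(x$axis, y, j), numeric(1))
      matched_obs <- matched_anc <- numeric(0)
      for (a in anchors) {
        # strongest candidate within max_shift: nearest-position matching
        # is fragile against small noise maxima sitting closer than the
        # true (shifted) peak
        cand <- which(abs(pos - a) <= max_shift)
        if (length(cand)) {
          j <- cand[which.max(y[idx[cand]])]
          matched_obs <- c(matched_obs, pos[j])
          matched_anc <- c(matched_anc, a)
        }
      }
      tab$n_matched[i] <- length(matched_obs)
      if (length(matched_obs) >= 1L) {
        fit <- fit_pixel_shift(matched_obs, matched_anc, model)
        tab$offset[i] <- fit[["offset"]]
        tab$slope[i] <- fit[["slope"]]
      }
    }
    if (tab$n_matched[i] < 1L) tab$flagged[i] <- TRUE
    if (tab$offset[i] != 0 || tab$slope[i] != 0) {
      xout <- x$axis + tab$offset[i] + tab$slope[i] * x$axis
      out[i, ] <- stats::approx(x$axis, y, xout = xout, rule = 2)$y
    }
  }
  x$intensities <- out
  x <- note_step(x, "phase_correct",
                 list(model = model, max_shift = max_shift,
                      n_anchors = length(anchors)))
  attr(tab, "anchors") <- anchors
  class(tab) <- c("PhaseModel", "data.frame")
  list(data = x, model = tab)
}

#' @export
phase_correct.list <- function(x, max_shift = 0.5, anchor_quantile = 0.99,
                               model = c("offset", "linear"),
                               anchors = NULL, min_snr = 3) {
  model <- match.arg(model)
  if (is.null(anchors))
    stop("phase correction of peak lists needs explicit 'anchors' ",
         "(e.g. taken from a profile map or known calibrants)")
  if (length(anchors) < 2L) stop("no stable intense peaks: need >= 2 anchors")
  tab <- data.frame(pixel = seq_along(x), offset = 0, slope = 0,
                    n_matched = 0L, flagged = FALSE)
  out <- x
  for (i in seq_along(x)) {
    pl <- x[[i]]
    matched_obs <- matched_anc <- numeric(0)
    if (length(pl$mz)) {
      for (a in anchors) {
        cand <- which(abs(pl$mz - a) <= max_shift)
        if (length(cand)) {
          j <- cand[which.max(pl$intensity[cand])]
          matched_obs <- c(matched_obs, pl$mz[j])
          matched_anc <- c(matched_anc, a)
        }
      }
    }
    tab$n_matched[i] <- length(matched_obs)
    if (length(matched_obs) >= 1L) {
      fit <- fit_pixel_shift(matched_obs, matched_anc, model)
      tab$offset[i] <- fit[["offset"]]
      tab$slope[i] <- fit[["slope"]]
      out[[i]] <- peak_list(
        pl$mz - (tab$offset[i] + tab$slope[i] * pl$mz),
        pl$intensity, pl$pixel_id)
    } else {
      tab$flagged[i] <- TRUE
    }
  }
  attr(tab, "anchors") <- anchors
  class(tab) <- c("PhaseModel", "data.frame")
  list(data = out, model = tab)
}

#' Bin centroided peaks across pixels at a mass-relative tolerance
#'
#' Peak positions still vary slightly between spectra after phase
#' correction, and peak width grows with mass, so bins are defined by a
#' tolerance *relative* to the mass value (ppm). All peaks are pooled and
#' sorted; a greedy left-to-right pass opens a new bin whenever the next
#' m/z exceeds the running intensity-weighted bin centroid by more than
#' `tolerance_ppm * 1e-6 * centroid`. The result is a `SpectralMap` whose
#' axis is the bin centroids and whose cell (pixel, bin) is the sum of
#' that pixel's member intensities, together with the full bin membership
#' table. Deterministic and invariant to pixel order.
#'
#' @param peak_lists list of [peak_list()] objects, one per pixel (empty
#'   lists allowed, but at least one peak overall).
#' @param tolerance_ppm positive tolerance in parts per million
#'   (default 200).
#' @param coords optional `n x 2` um coordinates for the output map;
#'   defaults to `(pixel_index, 0)` placeholders.
#' @param modality modality tag of the output map.
#' @return list with `map` (the binned `SpectralMap`) and `bins` (a
#'   `BinTable`: `centroids`, `members` data frame, `tolerance_ppm`).
#' @export
bin_peaks <- function(peak_lists, tolerance_ppm = 200, coords = NULL,
                      modality = "maldi") {
  if (tolerance_ppm <= 0) stop("tolerance_ppm must be positive")
  n <- length(peak_lists)
  mz <- unlist(lapply(peak_lists, `[[`, "mz"), use.names = FALSE)
  ity <- unlist(lapply(peak_lists, `[[`, "intensity"), use.names = FALSE)
  px <- rep(seq_len(n),
            vapply(peak_lists, function(p) length(p$mz), integer(1)))
  if (!length(mz)) stop("no peaks: all peak lists are empty")

  ord <- order(mz)
  mz <- mz[ord]; ity <- ity[ord]; px <- px[ord]
  N <- length(mz)
  bin <- integer(N)
  cur <- 0L
  sw <- sm <- 0
  tol <- tolerance_ppm * 1e-6
  for (i in seq_len(N)) {
    cent <- if (cur > 0L && sw > 0) sm / sw else NA_real_
    if (cur == 0L || mz[i] - cent > tol * cent) {
      cur <- cur + 1L
      sw <- 0; sm <- 0
    }
    bin[i] <- cur
    w <- if (ity[i] > 0) ity[i] else .Machine$double.eps
    sw <- sw + w
    sm <- sm + w * mz[i]
  }
  nb <- cur
  w <- ifelse(ity > 0, ity, .Machine$double.eps)
  centroids <- as.numeric(tapply(w * mz, bin, sum) / tapply(w, bin, sum))

  key <- (px - 1L) * nb + bin
  agg <- rowsum(ity, key)
  kidx <- as.integer(rownames(agg))
  M <- matrix(0, n, nb)
  M[cbind((kidx - 1L) %/% nb + 1L, (kidx - 1L) %% nb + 1L)] <- agg[, 1L]
  if (is.null(coords)) coords <- cbind(seq_len(n), 0)
  map <- spectral_map(M, centroids, coords, modality = modality,
                      meta = list(binned = TRUE,
                                  tolerance_ppm = tolerance_ppm))
  bins <- structure(
    list(centroids = centroids,
         members = data.frame(bin = bin, pixel_id = px, mz = mz,
                              intensity = ity),
         tolerance_ppm = tolerance_ppm),
    class = "BinTable")
  list(map = map, bins = bins)
}

#' Total-ion-count normalization
#'
#' Divides each spectrum by its total ion count (the sum of its
#' intensities). For non-negative spectra this is identical to l1
#' normalization.
#'
#' @param map a `SpectralMap`.
#' @param on_zero `"error"` (default) or `"drop"`: what to do with pixels
#'   whose TIC is not positive. Dropped pixels are removed from the map
#'   and recorded in `meta$dropped_pixels`.
#' @return the normalized `SpectralMap`.
#' @export
tic_normalize <- function(map, on_zero = c("error", "drop")) {
  on_zero <- match.arg(on_zero)
  validate_spectral_map(map)
  tic <- rowSums(map$intensities)
  bad <- which(tic <= 0)
  if (length(bad)) {
    if (on_zero == "error")
      stop("zero or negative TIC at pixel(s) ",
           paste(utils::head(bad, 5L), collapse = ", "))
    map$intensities <- map$intensities[-bad, , drop = FALSE]
    map$coords <- map$coords[-bad, , drop = FALSE]
    map$meta$dropped_pixels <- bad
    tic <- tic[-bad]
  }
  map$intensities <- map$intensities / tic
  note_step(map, "tic_normalize", list(dropped = length(bad)))
}

#' Mass-spectral normalizations
#'
#' The normalizations in common use for MALDI imaging, sharing the
#' [tic_normalize()] contract. `tic` divides by the intensity sum, `rms`
#' by the root-mean-square (vector norm up to a constant), `median` by the
#' median of the positive intensities, `noise` by the robust noise scale
#' of [estimate_noise()]; `sqrt` and `log` are variance-stabilizing
#' transforms (`sqrt(y)`, `log1p(y)`) rather than divisions. TIC is the
#' default used downstream.
#'
#' @param map a `SpectralMap`.
#' @param method one of `"tic"`, `"rms"`, `"median"`, `"sqrt"`, `"log"`,
#'   `"noise"`.
#' @return the normalized `SpectralMap`.
#' @export
normalize_ms <- function(map, method = c("tic", "rms", "median", "sqrt",
                                         "log", "noise")) {
  method <- match.arg(method)
  validate_spectral_map(map)
  if (method == "tic") return(tic_normalize(map))
  y <- map$intensities
  if (method %in% c("sqrt", "log")) {
    if (any(y < 0)) stop(method, " transform needs non-negative intensities")
    map$intensities <- if (method == "sqrt") sqrt(y) else log1p(y)
    return(note_step(map, "normalize_ms", list(method = method)))
  }
  div <- switch(method,
    rms = sqrt(rowMeans(y^2)),
    median = apply(y, 1L, function(r) {
      pos <- r[r > 0]
      if (!length(pos)) NA_real_ else stats::median(pos)
    }),
    noise = apply(y, 1L, function(r)
      if (all(r == 0)) 0 else estimate_noise(r)))
  bad <- which(!is.finite(div) | div <= 0)
  if (length(bad))
    stop("cannot ", method, "-normalize pixel(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  map$intensities <- y / div
  note_step(map, "normalize_ms", list(method = method))
}
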