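# Raman-specific preprocessing: axis interpolation, cosmic-spike
# detection/removal, and per-spectrum normalization.

# Try to arrange pixel coordinates on a rectangular grid. Returns NULL if
# the pixels do not occupy distinct cells of the implied grid.
coords_to_grid <- function(coords, digits = 6L) {
  kx <- round(coords[, 1], digits)
  ky <- round(coords[, 2], digits)
  ux <- sort(unique(kx)); uy <- sort(unique(ky))
  ci <- match(kx, ux); ri <- match(ky, uy)
  cell <- (ri - 1L) * length(ux) + ci
  if (anyDuplicated(cell)) return(NULL)
  list(ux = ux, uy = uy, col = ci, row = ri,
       nx = length(ux), ny = length(uy), cell = cell)
}

#' Interpolate a map onto a new channel axis
#'
#' Linear per-pixel interpolation onto `target_axis`, used to bring Raman
#' maps measured under different wavenumber calibrations onto one common
#' axis. Extrapolation is refused.
#'
#' @param map a `SpectralMap`.
#' @param target_axis strictly increasing numeric vector within the range
#'   of `map$axis`.
#' @return a `SpectralMap` on the new axis.
#' @export
interpolate_axis <- function(map, target_axis) {
  validate_spectral_map(map)
  target_axis <- as.numeric(target_axis)
  if (any(diff(target_axis) <= 0))
    stop("target_axis must be strictly increasing")
  if (min(target_axis) < min(map$axis) || max(target_axis) > max(map$axis))
    stop("extrapolation requested: target axis [", min(target_axis), ", ",
         max(target_axis), "] exceeds source range [", min(map$axis), ", ",
         max(map$axis), "]")
  out <- t(apply(map$intensities, 1L, function(y)
    stats::approx(map$axis, y, xout = target_axis)$y))
  if (length(target_axis) == 1L) out <- matrix(out, ncol = 1L)
  map$intensities <- out
  map$axis <- target_axis
  note_step(map, "interpolate_axis",
            list(n_channels = length(target_axis)))
}

#' Detect cosmic spikes via a spatial Laplacian
#'
#' Cosmic-ray spikes hit a single detector pixel during a single
#' acquisition, so they are sharp along the *spatial* dimension of the
#' data matrix, whereas genuine Raman bands are shared by neighbouring
#' pixels. The detection statistic is the sum of symmetric spatial second
#' differences of each channel image over the pixel grid - the discrete
#' 5-point Laplacian at interior pixels; edge pixels use the direction
#' whose two neighbours both exist, and the four corners are unscreened
#' (one-sided stencils would respond to gradients of smooth fields). For
#' non-gridded maps the second difference along raster-scan order
#' (row-major in (y, x)) is used. Scores are variance-normalized per
#' stencil size and robustly standardized by the median/MAD over the
#' whole map; cells with `|z| > z_threshold` are flagged. A band present
#' in all pixels at the same channel has zero spatial curvature and is
#' never flagged.
#'
#' @param map a `SpectralMap` with at least 3 pixels and 3 channels.
#' @param z_threshold positive flagging threshold in robust-MAD units
#'   (default 8).
#' @return an object of class `SpikeMask`: list with `flags` (logical
#'   matrix) and `score` (standardized statistic), both `n_pixels x
#'   n_channels`.
#' @export
detect_spikes <- function(map, z_threshold = 8) {
  validate_spectral_map(map)
  n <- n_pixels(map); p <- n_channels(map)
  if (n < 3L)
    stop("spike detection needs >= 3 pixels; for a single spectrum use a ",
         "1D fallback (second difference along channels only)")
  if (p < 3L) stop("spike detection needs >= 3 channels")
  if (z_threshold <= 0) stop("z_threshold must be positive")
  D <- map$intensities

  grid <- coords_to_grid(map$coords)
  if (!is.null(grid)) {
    pix_at <- matrix(NA_integer_, grid$ny, grid$nx)
    pix_at[cbind(grid$row, grid$col)] <- seq_len(n)
    nbr <- function(dr, dc) {
      r <- grid$row + dr; c <- grid$col + dc
      ok <- r >= 1L & r <= grid$ny & c >= 1L & c <= grid$nx
      idx <- rep(NA_integer_, n)
      idx[ok] <- pix_at[cbind(r[ok], c[ok])]
      idx
    }
    pairs <- list(list(nbr(-1L, 0L), nbr(1L, 0L)),
                  list(nbr(0L, -1L), nbr(0L, 1L)))
  } else {
    ord <- order(map$coords[, 2], map$coords[, 1])
    pos <- match(seq_len(n), ord)
    prv <- ord[ifelse(pos - 1L >= 1L, pos - 1L, NA_integer_)]
    nxt <- ord[ifelse(pos + 1L <= n, pos + 1L, NA_integer_)]
    pairs <- list(list(prv, nxt))
  }

  # symmetric second differences only (both neighbours of a direction
  # must exist): one-sided stencils respond to gradients of smooth
  # fields, which would flag map edges
  acc <- matrix(0, n, p)
  npair <- numeric(n)
  for (pr in pairs) {
    ok <- !is.na(pr[[1]]) & !is.na(pr[[2]])
    if (any(ok)) {
      acc[ok, ] <- acc[ok, ] + D[pr[[1]][ok], , drop = FALSE] +
        D[pr[[2]][ok], , drop = FALSE] - 2 * D[ok, , drop = FALSE]
      npair[ok] <- npair[ok] + 1
    }
  }
  denom <- sqrt(pmax(2 * npair + 4 * npair^2, 1))
  score <- acc / denom
  # numerical zero floor: exact cancellation on smooth fields leaves
  # rounding dust that must not be standardized into outliers
  score[abs(score) < 1e-10 * max(abs(D))] <- 0

  med <- stats::median(score)
  scale <- 1.4826 * stats::median(abs(score - med))
  z <- if (scale > 0) {
    (score - med) / scale
  } else {
    ifelse(score == med, 0, sign(score - med) * Inf)
  }
  structure(list(flags = abs(z) > z_threshold, score = z,
                 z_threshold = z_threshold),
            class = "SpikeMask")
}

#' Replace flagged spike cells by interpolation along the channel axis
#'
#' Each flagged cell is replaced by linear interpolation between the
#' nearest unflagged channels of the same spectrum; runs of adjacent
#' flagged channels are filled as one gap, and flagged cells at the
#' spectrum edges take the nearest unflagged value (constant extension).
#' Unflagged cells are untouched.
#'
#' @param map a `SpectralMap`.
#' @param mask a `SpikeMask` from [detect_spikes()] with matching shape.
#' @return the corrected `SpectralMap`.
#' @export
remove_spikes <- function(map, mask) {
  validate_spectral_map(map)
  stopifnot(inherits(mask, "SpikeMask"))
  if (!identical(dim(mask$flags), dim(map$intensities)))
    stop("mask shape ", paste(dim(mask$flags), collapse = "x"),
         " does not match map ", paste(dim(map$intensities), collapse = "x"))
  rows <- which(rowSums(mask$flags) > 0L)
  ax <- map$axis
  for (i in rows) {
    f <- mask$flags[i, ]
    if (all(f)) stop("spectrum unrecoverable: every channel of pixel ", i,
                     " is flagged")
    good <- which(!f)
    map$intensities[i, f] <- stats::approx(
      ax[good], map$intensities[i, good], xout = ax[f], rule = 2)$y
  }
  note_step(map, "remove_spikes", list(n_cells = sum(mask$flags)))
}

#' Normalize every spectrum of a map
#'
#' `l2` (vector normalization) divides each spectrum by its Euclidean
#' norm, `l1` by the sum of absolute values, and `total_intensity` by the
#' signed sum. The latter two differ only when negative values are present
#' (as they are after baseline correction of Raman spectra); on
#' non-negative spectra `l1` and `total_intensity` coincide with TIC
#' normalization.
#'
#' @param map a `SpectralMap`.
#' @param method `"l2"`, `"l1"` or `"total_intensity"`.
#' @return the normalized `SpectralMap`.
#' @export
normalize <- function(map, method = c("l2", "l1", "total_intensity")) {
  method <- match.arg(method)
  validate_spectral_map(map)
  y <- map$intensities
  norms <- switch(method,
    l2 = sqrt(rowSums(y^2)),
    l1 = rowSums(abs(y)),
    total_intensity = rowSums(y))
  bad <- if (method == "total_intensity") norms <= 0 else norms == 0
  if (any(bad))
    stop("cannot ", method, "-normalize pixel(s) ",
         paste(utils::head(which(bad), 5L), collapse = ", "),
         ": per-spectrum norm is ",
         if (method == "total_intensity") "non-positive" else "zero")
  map$intensities <- y / norms
  note_step(map, "normalize", list(method = method))
}
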