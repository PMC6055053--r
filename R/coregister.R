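# Landmark-based affine co-registration of the Raman map into the MALDI
# coordinate frame, and nearest-grid-point resampling with averaging.

#' Fit a planar affine transform from paired landmarks
#'
#' Least-squares fit of the 6-parameter transform `x -> A x + t`
#' minimizing the summed squared Euclidean error over the landmark pairs.
#' With exactly 3 non-collinear points the fit is exact.
#'
#' @param landmarks a [landmark_set()].
#' @return an object of class `Affine2D`: list with `A` (2x2), `t`
#'   (length 2, um) and `fit_residuals` (per-landmark Euclidean error,
#'   um).
#' @export
fit_affine <- function(landmarks) {
  stopifnot(inherits(landmarks, "LandmarkSet"))
  X <- cbind(landmarks$source_xy, 1)
  beta <- qr.solve(X, landmarks$target_xy)   # 3 x 2
  A <- t(beta[1:2, , drop = FALSE])
  tv <- as.numeric(beta[3, ])
  if (abs(det(A)) < 1e-12)
    stop("degenerate transform: linear part is singular")
  pred <- apply_affine(structure(list(A = A, t = tv), class = "Affine2D"),
                       landmarks$source_xy)
  res <- sqrt(rowSums((pred - landmarks$target_xy)^2))
  structure(list(A = A, t = tv, fit_residuals = res), class = "Affine2D")
}

#' @export
print.Affine2D <- function(x, ...) {
  cat("<Affine2D>\n  A =", sprintf("[%.6g %.6g; %.6g %.6g]",
      x$A[1, 1], x$A[1, 2], x$A[2, 1], x$A[2, 2]),
      "\n  t =", sprintf("(%.6g, %.6g) um", x$t[1], x$t[2]), "\n")
  if (!is.null(x$fit_residuals))
    cat(sprintf("  landmark RMS residual = %.4g um\n",
                sqrt(mean(x$fit_residuals^2))))
  invisible(x)
}

#' Apply an affine transform to coordinates
#'
#' @param t an `Affine2D`.
#' @param coords `n x 2` matrix of (x, y) positions.
#' @return `n x 2` matrix of transformed positions.
#' @export
apply_affine <- function(t, coords) {
  stopifnot(inherits(t, "Affine2D"))
  coords <- as.matrix(coords)
  sweep(coords %*% t(t$A), 2L, t$t, "+")
}

#' Invert an affine transform
#' @param t an `Affine2D`.
#' @return the inverse `Affine2D`.
#' @export
invert_affine <- function(t) {
  stopifnot(inherits(t, "Affine2D"))
  Ai <- solve(t$A)
  structure(list(A = Ai, t = as.numeric(-Ai %*% t$t)), class = "Affine2D")
}

#' Resample a map onto a target grid by nearest-point averaging
#'
#' Each source pixel is transformed into the target frame and assigned to
#' its nearest (Euclidean) target point; the output spectrum at a target
#' point is the arithmetic mean of all spectra assigned to it. Exactly
#' equidistant ties go to the target point that comes first in a
#' lexicographic (y, x) sort, which makes the assignment deterministic.
#' Target points receiving no spectrum are flagged in
#' `meta$missing_pixels` (their rows are `NA`) and must be excluded before
#' fusion.
#'
#' @param source a `SpectralMap` (typically the Raman map).
#' @param target_coords `m x 2` matrix of distinct target positions (um,
#'   typically the MALDI grid).
#' @param transform an `Affine2D` mapping source coordinates into the
#'   target frame; identity if `NULL`.
#' @param max_distance optional cutoff (um): transformed source pixels
#'   farther than this from every target point are dropped instead of
#'   assigned.
#' @return list with `map` (a `SpectralMap` on the target grid) and
#'   `counts` (integer assignments per target point).
#' @export
resample_to_grid <- function(source, target_coords, transform = NULL,
                             max_distance = Inf) {
  validate_spectral_map(source)
  target_coords <- as.matrix(target_coords)
  if (anyDuplicated(paste(target_coords[, 1], target_coords[, 2])))
    stop("target coordinates must be distinct")
  pts <- if (is.null(transform)) source$coords
         else apply_affine(transform, source$coords)
  m <- nrow(target_coords)

  # deterministic tie-break: search targets in (y, x) order
  ord <- order(target_coords[, 2], target_coords[, 1])
  tx <- target_coords[ord, 1]; ty <- target_coords[ord, 2]

  n <- nrow(pts)
  assign_idx <- integer(n)
  mind <- numeric(n)
  chunk <- max(1L, floor(2e7 / m))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    d2 <- outer(pts[s:e, 1], tx, "-")^2 + outer(pts[s:e, 2], ty, "-")^2
    j <- max.col(-d2, ties.method = "first")
    assign_idx[s:e] <- ord[j]
    mind[s:e] <- sqrt(d2[cbind(seq_len(e - s + 1L), j)])
  }
  keep <- mind <= max_distance
  if (!any(keep)) stop("grids do not overlap: no source pixel within range")
  assign_idx <- assign_idx[keep]

  counts <- tabulate(assign_idx, nbins = m)
  sums <- rowsum(source$intensities[keep, , drop = FALSE], assign_idx)
  out <- matrix(NA_real_, m, n_channels(source))
  got <- sort(unique(assign_idx))
  out[got, ] <- sums / counts[got]
  missing <- which(counts == 0L)

  map <- spectral_map(out, source$axis, target_coords,
                      modality = source$modality,
                      meta = c(source$meta,
                               list(missing_pixels = missing,
                                    resampled = TRUE)))
  list(map = map, counts = counts)
}

#' Drop pixels from a map
#'
#' Utility to remove pixels (e.g. grid points flagged as missing after
#' resampling) consistently from intensities and coordinates.
#'
#' @param map a `SpectralMap`.
#' @param idx integer pixel indices to drop.
#' @return the reduced `SpectralMap` (with `meta$missing_pixels` cleared).
#' @export
drop_pixels <- function(map, idx) {
  validate_spectral_map(map)
  idx <- unique(as.integer(idx))
  if (!length(idx)) return(map)
  map$intensities <- map$intensities[-idx, , drop = FALSE]
  map$coords <- map$coords[-idx, , drop = FALSE]
  map$meta$missing_pixels <- NULL
  note_step(map, "drop_pixels", list(n = length(idx)))
}
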