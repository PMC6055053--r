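#' Construct a spectral map
#'
#' A `SpectralMap` is the central container of the package: a pixels-by-
#' channels intensity matrix together with a strictly increasing channel
#' axis (wavenumber in cm^-1 for Raman, m/z in Da for MALDI), the spatial
#' coordinates of every pixel (micrometres, pixel centres), a modality tag
#' and a free-form metadata list used as a processing history.
#'
#' Coordinates are real-valued positions, not grid indices: the two
#' modalities are acquired on grids of different pitch (e.g. 25 um Raman
#' vs 75 um MALDI) and all geometry is done in micrometres.
#'
#' @param intensities numeric matrix, `n_pixels x n_channels`.
#' @param axis numeric vector of channel positions, strictly increasing,
#'   length `n_channels`. If unsorted it is sorted and the columns of
#'   `intensities` are permuted consistently.
#' @param coords numeric matrix `n_pixels x 2` of (x, y) positions in um.
#' @param modality `"raman"` or `"maldi"`.
#' @param meta named list of provenance entries.
#' @return an object of class `SpectralMap`.
#' @export
spectral_map <- function(intensities, axis,
                         coords,
                         modality = c("raman", "maldi"),
                         meta = list()) {
  modality <- match.arg(modality)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  axis <- as.numeric(axis)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (is.unsorted(axis, strictly = TRUE)) {
    ord <- order(axis)
    axis <- axis[ord]
    intensities <- intensities[, ord, drop = FALSE]
  }
  m <- structure(
    list(intensities = intensities, axis = axis, coords = coords,
         modality = modality, meta = meta),
    class = "SpectralMap")
  validate_spectral_map(m)
  m
}

#' Validate a SpectralMap
#'
#' Checks all container invariants: dimension agreement between the
#' intensity matrix, the axis and the coordinate table; a strictly
#' increasing axis; and distinct pixel coordinates. Pixels listed in
#' `meta$missing_pixels` (e.g. grid points that received no spectrum
#' during resampling) are allowed to hold `NA` intensities.
#'
#' @param m a `SpectralMap`.
#' @return `m`, invisibly; errors on any violation.
#' @export
validate_spectral_map <- function(m) {
  stopifnot(inherits(m, "SpectralMap"))
  n <- nrow(m$intensities)
  p <- ncol(m$intensities)
  if (length(m$axis) != p)
    stop("axis length (", length(m$axis), ") != n_channels (", p, ")")
  if (p > 1L && any(diff(m$axis) <= 0))
    stop("channel axis must be strictly increasing")
  if (!is.matrix(m$coords) || nrow(m$coords) != n || ncol(m$coords) != 2L)
    stop("coords must be an n_pixels x 2 matrix (got ",
         nrow(m$coords), " x ", ncol(m$coords), " for ", n, " pixels)")
  key <- paste(signif(m$coords[, 1], 12), signif(m$coords[, 2], 12))
  if (anyDuplicated(key))
    stop("duplicate pixel coordinates at rows ",
         paste(utils::head(which(duplicated(key)), 5L), collapse = ", "))
  missing <- m$meta$missing_pixels %||% integer(0)
  ok_rows <- setdiff(seq_len(n), missing)
  if (length(ok_rows) && !all(is.finite(m$intensities[ok_rows, , drop = FALSE])))
    stop("non-finite intensities in non-missing pixels")
  invisible(m)
}

#' @export
print.SpectralMap <- function(x, ...) {
  cat(sprintf("<SpectralMap: %s, %d pixels x %d channels, axis [%.6g, %.6g]>\n",
              x$modality, nrow(x$intensities), ncol(x$intensities),
              min(x$axis), max(x$axis)))
  if (length(x$meta)) cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.SpectralMap <- function(x) dim(x$intensities)

#' Number of pixels / channels of a SpectralMap
#' @param m a `SpectralMap`.
#' @return integer count.
#' @export
n_pixels <- function(m) nrow(m$intensities)

#' @rdname n_pixels
#' @export
n_channels <- function(m) ncol(m$intensities)

#' Construct a centroided peak list for one pixel
#'
#' @param mz numeric vector of peak positions (Da), strictly increasing
#'   (unsorted input is sorted together with `intensity`).
#' @param intensity numeric vector of non-negative peak intensities.
#' @param pixel_id integer index of the pixel this list belongs to.
#' @return an object of class `PeakList`.
#' @export
peak_list <- function(mz, intensity, pixel_id = 1L) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have the same length")
  if (length(mz)) {
    if (is.unsorted(mz, strictly = TRUE)) {
      ord <- order(mz)
      mz <- mz[ord]; intensity <- intensity[ord]
      if (any(diff(mz) <= 0)) stop("duplicate m/z values in peak list")
    }
    if (any(intensity < 0)) stop("peak intensities must be non-negative")
  }
  structure(list(mz = mz, intensity = intensity,
                 pixel_id = as.integer(pixel_id)),
            class = "PeakList")
}

#' @export
print.PeakList <- function(x, ...) {
  cat(sprintf("<PeakList: pixel %d, %d peaks>\n", x$pixel_id, length(x$mz)))
  invisible(x)
}

#' Construct a set of paired registration landmarks
#'
#' Landmarks are k >= 3 manually identified positions visible in both
#' modalities; the source points must not be collinear, otherwise the
#' affine fit is rank-deficient.
#'
#' @param source_xy numeric `k x 2` matrix, positions in the source
#'   (Raman) frame, um.
#' @param target_xy numeric `k x 2` matrix, matched positions in the
#'   target (MALDI) frame, um.
#' @return an object of class `LandmarkSet`.
#' @export
landmark_set <- function(source_xy, target_xy) {
  source_xy <- as.matrix(source_xy); storage.mode(source_xy) <- "double"
  target_xy <- as.matrix(target_xy); storage.mode(target_xy) <- "double"
  if (nrow(source_xy) != nrow(target_xy))
    stop("source and target landmark counts differ")
  if (nrow(source_xy) < 3L)
    stop("insufficient landmarks: need at least 3, got ", nrow(source_xy))
  if (ncol(source_xy) != 2L || ncol(target_xy) != 2L)
    stop("landmarks must have 2 columns (x, y)")
  cs <- sweep(source_xy, 2, colMeans(source_xy))
  sv <- svd(cs, nu = 0, nv = 0)$d
  if (sv[2] <= 1e-9 * max(sv[1], 1))
    stop("degenerate landmarks: source points are collinear")
  structure(list(source_xy = source_xy, target_xy = target_xy),
            class = "LandmarkSet")
}

#' @export
print.LandmarkSet <- function(x, ...) {
  cat(sprintf("<LandmarkSet: %d paired points>\n", nrow(x$source_xy)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# append a processing-history entry to a map's metadata
note_step <- function(map, step, params = list()) {
  h <- map$meta$history %||% list()
  h[[length(h) + 1L]] <- c(list(step = step), params)
  map$meta$history <- h
  map
}
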