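#' Read a spectral map from disk
#'
#' Two dialects are supported. `wide_csv` is the package's plain-text
#' exchange format: row 1 holds the literal headers `x,y` followed by the
#' channel-axis values; every following row is one pixel, `x, y` in um
#' followed by the intensities. `imzml` reads continuous-mode imzML (an
#' XML index plus a binary `.ibd` companion); processed-mode files with
#' per-pixel axes should be read with [read_imzml_peaks()] and binned.
#'
#' @param path file path.
#' @param format `"wide_csv"` or `"imzml"`.
#' @param modality modality tag for the returned map; defaults to
#'   `"raman"` for `wide_csv` and `"maldi"` for `imzml`.
#' @return a [spectral_map()].
#' @export
read_spectral_map <- function(path, format = c("wide_csv", "imzml"),
                              modality = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "imzml")
    return(read_imzml(path, modality = modality %||% "maldi"))
  dt <- data.table::fread(path, header = FALSE, sep = ",",
                          colClasses = "character", data.table = FALSE)
  if (nrow(dt) < 2L || ncol(dt) < 3L)
    stop("wide_csv file is empty or too small: ", path)
  head_row <- as.character(dt[1, ])
  if (!identical(tolower(head_row[1:2]), c("x", "y")))
    stop("wide_csv header must start with 'x,y': ", path)
  axis <- suppressWarnings(as.numeric(head_row[-(1:2)]))
  if (anyNA(axis))
    stop("non-numeric axis value in header column ",
         which(is.na(axis))[1] + 2L)
  body <- as.matrix(dt[-1, , drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at data row %d, column %d of %s",
                 bad[1], bad[2], path))
  }
  spectral_map(num[, -(1:2), drop = FALSE], axis, num[, 1:2, drop = FALSE],
               modality = modality %||% "raman",
               meta = list(source = path))
}

#' Write a spectral map to disk
#'
#' Inverse of [read_spectral_map()]; `wide_csv` round-trips intensities to
#' better than 1e-9 (15 significant digits) and `imzml` exactly (IEEE
#' doubles).
#'
#' @param map a `SpectralMap`.
#' @param path output path (for imzML, the `.ibd` companion is written
#'   next to it).
#' @param format `"wide_csv"` or `"imzml"`.
#' @return `path`, invisibly.
#' @export
write_spectral_map <- function(map, path, format = c("wide_csv", "imzml")) {
  format <- match.arg(format)
  validate_spectral_map(map)
  if (format == "imzml") return(write_imzml(map, path))
  header <- c("x", "y", format(map$axis, digits = 15, trim = TRUE,
                               scientific = FALSE))
  dt <- data.table::data.table(cbind(map$coords, map$intensities))
  writeLines(paste(header, collapse = ","), path)
  data.table::fwrite(dt, path, col.names = FALSE, append = TRUE, sep = ",")
  invisible(path)
}

#' Read registration landmarks from a 4-column CSV
#'
#' Expects at least 3 rows of `x_src, y_src, x_tgt, y_tgt` (um). A header
#' line is allowed and detected. Errors on fewer than 3 rows
#' ("insufficient landmarks") or collinear source points ("degenerate
#' landmarks").
#'
#' @param path file path.
#' @return a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = "auto", data.table = FALSE)
  if (ncol(dt) != 4L)
    stop("landmark file must have 4 numeric columns, got ", ncol(dt))
  m <- suppressWarnings(matrix(as.numeric(as.matrix(dt)), ncol = 4))
  if (anyNA(m)) stop("non-numeric value in landmark file ", path)
  landmark_set(m[, 1:2, drop = FALSE], m[, 3:4, drop = FALSE])
}

#' Write registration landmarks
#' @param lm a `LandmarkSet`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "LandmarkSet"))
  df <- data.frame(x_src = lm$source_xy[, 1], y_src = lm$source_xy[, 2],
                   x_tgt = lm$target_xy[, 1], y_tgt = lm$target_xy[, 2])
  data.table::fwrite(df, path)
  invisible(path)
}
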