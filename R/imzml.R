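# Minimal imzML support.
#
# imzML stores an mzML-style XML index next to a binary ".ibd" file that
# starts with a 16-byte UUID followed by the raw arrays. In continuous
# mode the m/z axis is stored once and every spectrum stores only its
# intensity array; in processed mode each spectrum stores its own m/z and
# intensity arrays. Only 64-bit little-endian floats are written and read.
# No vendor reader is available in this environment, so the reader/writer
# pair below covers exactly the subset needed for imaging round-trips and
# is validated by round-trip tests.

IMZML_UUID <- as.raw(c(0x73, 0x70, 0x65, 0x63, 0x66, 0x75, 0x73, 0x65,
                       0x00, 0x01, 0x02, 0x03, 0x04, 0x05, 0x06, 0x07))

imzml_paths <- function(path) {
  base <- sub("\\.imzml$", "", path, ignore.case = TRUE)
  list(xml = path, ibd = paste0(base, ".ibd"))
}

cvp <- function(cv, acc, name, value = NULL) {
  v <- if (is.null(value)) "" else sprintf(' value="%s"', value)
  sprintf('<cvParam cvRef="%s" accession="%s" name="%s"%s/>', cv, acc, name, v)
}

# coordinates are stored twice: as 1-based integer grid indices in the
# standard IMS position params, and as exact um positions in userParams so
# that the package's real-valued coordinate convention round-trips.
imzml_spectrum_xml <- function(i, ix, iy, x_um, y_um, arrays) {
  paste0(
    sprintf('<spectrum index="%d" id="spectrum=%d" defaultArrayLength="0">', i - 1L, i),
    '<scanList count="1"><scan>',
    cvp("IMS", "IMS:1000050", "position x", ix),
    cvp("IMS", "IMS:1000051", "position y", iy),
    sprintf('<userParam name="position_x_um" value="%s"/>',
            format(x_um, digits = 15, trim = TRUE, scientific = FALSE)),
    sprintf('<userParam name="position_y_um" value="%s"/>',
            format(y_um, digits = 15, trim = TRUE, scientific = FALSE)),
    '</scan></scanList>',
    sprintf('<binaryDataArrayList count="%d">', length(arrays)),
    paste(vapply(arrays, function(a) paste0(
      '<binaryDataArray encodedLength="0">',
      sprintf('<referenceableParamGroupRef ref="%s"/>', a$ref),
      cvp("IMS", "IMS:1000102", "external offset", a$offset),
      cvp("IMS", "IMS:1000103", "external array length", a$length),
      cvp("IMS", "IMS:1000104", "external encoded length", a$length * 8),
      '<binary/></binaryDataArray>'), character(1)), collapse = ""),
    '</binaryDataArrayList></spectrum>')
}

imzml_header_xml <- function(mode, n_spectra, nx, ny) {
  mode_acc <- if (mode == "continuous") {
    cvp("IMS", "IMS:1000030", "continuous")
  } else {
    cvp("IMS", "IMS:1000031", "processed")
  }
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<fileDescription><fileContent>',
    mode_acc,
    cvp("IMS", "IMS:1000080", "universally unique identifier",
        paste0("{", paste(IMZML_UUID, collapse = ""), "}")),
    cvp("MS", "MS:1000294", "mass spectrum"),
    '</fileContent></fileDescription>',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    cvp("MS", "MS:1000514", "m/z array"),
    cvp("MS", "MS:1000523", "64-bit float"),
    cvp("IMS", "IMS:1000101", "external data", "true"),
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    cvp("MS", "MS:1000515", "intensity array"),
    cvp("MS", "MS:1000523", "64-bit float"),
    cvp("IMS", "IMS:1000101", "external data", "true"),
    '</referenceableParamGroup>',
    '</referenceableParamGroupList>',
    '<scanSettingsList count="1"><scanSettings id="scan1">',
    cvp("IMS", "IMS:1000042", "max count of pixel x", nx),
    cvp("IMS", "IMS:1000043", "max count of pixel y", ny),
    '</scanSettings></scanSettingsList>',
    sprintf('<run id="run1"><spectrumList count="%d">', n_spectra))
}

#' Write a SpectralMap as continuous-mode imzML
#'
#' @param map a `SpectralMap` with a shared channel axis.
#' @param path output `.imzML` path; the `.ibd` binary companion is
#'   written alongside.
#' @return `path`, invisibly.
#' @export
write_imzml <- function(map, path) {
  validate_spectral_map(map)
  pp <- imzml_paths(path)
  n <- n_pixels(map); p <- n_channels(map)
  ix <- as.integer(rank(map$coords[, 1], ties.method = "min"))
  iy <- as.integer(rank(map$coords[, 2], ties.method = "min"))
  ix <- match(ix, sort(unique(ix)))
  iy <- match(iy, sort(unique(iy)))

  ibd <- file(pp$ibd, "wb")
  writeBin(IMZML_UUID, ibd)
  writeBin(as.numeric(map$axis), ibd, size = 8, endian = "little")
  mz_offset <- 16
  spec_xml <- character(n)
  offset <- 16 + 8 * p
  for (i in seq_len(n)) {
    writeBin(as.numeric(map$intensities[i, ]), ibd, size = 8,
             endian = "little")
    spec_xml[i] <- imzml_spectrum_xml(
      i, ix[i], iy[i], map$coords[i, 1], map$coords[i, 2],
      list(list(ref = "mzArray", offset = mz_offset, length = p),
           list(ref = "intensityArray", offset = offset, length = p)))
    offset <- offset + 8 * p
  }
  close(ibd)

  xml <- paste0(imzml_header_xml("continuous", n, max(ix), max(iy)),
                paste(spec_xml, collapse = ""),
                '</spectrumList></run></mzML>')
  writeLines(xml, pp$xml)
  invisible(path)
}

#' Write centroided peak lists as processed-mode imzML
#'
#' @param peak_lists list of [peak_list()] objects, one per pixel.
#' @param coords `n x 2` matrix of pixel positions (um).
#' @param path output `.imzML` path.
#' @return `path`, invisibly.
#' @export
write_imzml_peaks <- function(peak_lists, coords, path) {
  coords <- as.matrix(coords)
  n <- length(peak_lists)
  stopifnot(nrow(coords) == n)
  pp <- imzml_paths(path)
  ix <- match(rank(coords[, 1], ties.method = "min"),
              sort(unique(rank(coords[, 1], ties.method = "min"))))
  iy <- match(rank(coords[, 2], ties.method = "min"),
              sort(unique(rank(coords[, 2], ties.method = "min"))))
  ibd <- file(pp$ibd, "wb")
  writeBin(IMZML_UUID, ibd)
  offset <- 16
  spec_xml <- character(n)
  for (i in seq_len(n)) {
    pl <- peak_lists[[i]]
    k <- length(pl$mz)
    writeBin(as.numeric(pl$mz), ibd, size = 8, endian = "little")
    writeBin(as.numeric(pl$intensity), ibd, size = 8, endian = "little")
    spec_xml[i] <- imzml_spectrum_xml(
      i, ix[i], iy[i], coords[i, 1], coords[i, 2],
      list(list(ref = "mzArray", offset = offset, length = k),
           list(ref = "intensityArray", offset = offset + 8 * k, length = k)))
    offset <- offset + 16 * k
  }
  close(ibd)
  xml <- paste0(imzml_header_xml("processed", n, max(ix), max(iy)),
                paste(spec_xml, collapse = ""),
                '</spectrumList></run></mzML>')
  writeLines(xml, pp$xml)
  invisible(path)
}

imzml_parse <- function(path) {
  pp <- imzml_paths(path)
  if (!file.exists(pp$ibd)) stop("missing .ibd companion for ", path)
  doc <- xml2::read_xml(pp$xml)
  xml2::xml_ns_strip(doc)
  mode_node <- xml2::xml_find_first(
    doc, "//fileContent/cvParam[@accession='IMS:1000030' or @accession='IMS:1000031']")
  mode <- if (!is.na(xml2::xml_attr(mode_node, "accession")) &&
              xml2::xml_attr(mode_node, "accession") == "IMS:1000030")
    "continuous" else "processed"
  spectra <- xml2::xml_find_all(doc, "//spectrum")
  if (!length(spectra)) stop("no spectra in ", path)
  ibd <- file(pp$ibd, "rb")
  on.exit(close(ibd))
  invisible(readBin(ibd, "raw", 16))

  read_array <- function(node) {
    off <- as.numeric(xml2::xml_attr(
      xml2::xml_find_first(node, ".//cvParam[@accession='IMS:1000102']"), "value"))
    len <- as.integer(xml2::xml_attr(
      xml2::xml_find_first(node, ".//cvParam[@accession='IMS:1000103']"), "value"))
    seek(ibd, off)
    readBin(ibd, "double", len, size = 8, endian = "little")
  }
  out <- lapply(seq_along(spectra), function(i) {
    sp <- spectra[[i]]
    ref <- function(name) xml2::xml_find_first(
      sp, sprintf(".//binaryDataArray[referenceableParamGroupRef/@ref='%s']", name))
    ux <- xml2::xml_find_first(sp, ".//userParam[@name='position_x_um']")
    uy <- xml2::xml_find_first(sp, ".//userParam[@name='position_y_um']")
    x <- if (inherits(ux, "xml_missing")) {
      as.numeric(xml2::xml_attr(xml2::xml_find_first(
        sp, ".//cvParam[@accession='IMS:1000050']"), "value"))
    } else as.numeric(xml2::xml_attr(ux, "value"))
    y <- if (inherits(uy, "xml_missing")) {
      as.numeric(xml2::xml_attr(xml2::xml_find_first(
        sp, ".//cvParam[@accession='IMS:1000051']"), "value"))
    } else as.numeric(xml2::xml_attr(uy, "value"))
    list(mz = read_array(ref("mzArray")),
         intensity = read_array(ref("intensityArray")),
         x = x, y = y)
  })
  list(mode = mode, spectra = out)
}

#' Read continuous-mode imzML into a SpectralMap
#'
#' @param path `.imzML` path (the `.ibd` companion must sit alongside).
#' @param modality modality tag, default `"maldi"`.
#' @return a [spectral_map()].
#' @export
read_imzml <- function(path, modality = "maldi") {
  parsed <- imzml_parse(path)
  axes <- lapply(parsed$spectra, `[[`, "mz")
  shared <- all(vapply(axes, function(a) identical(a, axes[[1]]), logical(1)))
  if (parsed$mode == "processed" && !shared)
    stop("processed-mode imzML with per-pixel axes: use read_imzml_peaks() ",
         "and bin_peaks() instead")
  ints <- do.call(rbind, lapply(parsed$spectra, `[[`, "intensity"))
  coords <- cbind(vapply(parsed$spectra, `[[`, numeric(1), "x"),
                  vapply(parsed$spectra, `[[`, numeric(1), "y"))
  spectral_map(ints, axes[[1]], coords, modality = modality,
               meta = list(source = path, imzml_mode = parsed$mode))
}

#' Read imzML (either mode) as per-pixel peak lists
#'
#' @param path `.imzML` path.
#' @return list with `peaks` (list of [peak_list()]) and `coords`
#'   (`n x 2` um matrix).
#' @export
read_imzml_peaks <- function(path) {
  parsed <- imzml_parse(path)
  peaks <- lapply(seq_along(parsed$spectra), function(i) {
    sp <- parsed$spectra[[i]]
    peak_list(sp$mz, sp$intensity, pixel_id = i)
  })
  coords <- cbind(vapply(parsed$spectra, `[[`, numeric(1), "x"),
                  vapply(parsed$spectra, `[[`, numeric(1), "y"))
  list(peaks = peaks, coords = coords)
}
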