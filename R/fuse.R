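# The data-fusion centre: block weighting by the ratio of matrix l1-norms
# and column-wise concatenation into a single fused matrix.

matrix_l1 <- function(x) {
  if (inherits(x, "SpectralMap")) x <- x$intensities
  if (inherits(x, "FusedMatrix")) x <- x$matrix
  sum(abs(x))
}

#' Block weighting coefficient from the ratio of matrix l1-norms
#'
#' Preprocessed Raman and MALDI blocks differ in dimensionality and
#' dynamic range, so the second block is rescaled before fusion by
#' `w = ||A||_1 / ||B||_1`, where the matrix l1-norm is the sum of the
#' absolute values of all entries. By construction `||w B||_1 = ||A||_1`
#' exactly, so both blocks enter the joint PCA with equal total absolute
#' intensity.
#'
#' @param A,B numeric matrices or `SpectralMap`s (the Raman and MALDI
#'   blocks).
#' @return positive scalar `w`.
#' @export
l1_weight <- function(A, B) {
  na <- matrix_l1(A); nb <- matrix_l1(B)
  if (nb == 0) stop("cannot weight: second block has zero l1-norm")
  if (na == 0) stop("cannot weight: first block has zero l1-norm")
  na / nb
}

#' Fuse two aligned blocks into a single matrix
#'
#' Column-concatenates the Raman block and the weighted MALDI block,
#' `[A | w B]`, for pixel-wise joint analysis. Both blocks must share the
#' pixel set and ordering (i.e. be post-co-registration) and contain no
#' missing-flagged pixels. Per-column provenance (block tag plus the
#' original channel value in cm^-1 or Da) makes the fusion exactly
#' reversible.
#'
#' @param A `SpectralMap`, the Raman block.
#' @param B `SpectralMap`, the MALDI block.
#' @param w positive weighting coefficient applied to `B`; defaults to
#'   [l1_weight()] (the l1-ratio choice), use 1 for the unweighted case.
#' @return an object of class `FusedMatrix`: list with `matrix`,
#'   `provenance` (data frame of `block`, `channel`), `w`, `coords`.
#' @export
fuse_blocks <- function(A, B, w = NULL) {
  validate_spectral_map(A)
  validate_spectral_map(B)
  for (m in list(A, B))
    if (length(m$meta$missing_pixels %||% integer(0)))
      stop("block contains missing-flagged pixels; drop_pixels() first")
  if (is.null(w)) w <- l1_weight(A, B)
  if (!is.numeric(w) || length(w) != 1L || !is.finite(w) || w <= 0)
    stop("weight must be a single positive number")
  if (n_pixels(A) != n_pixels(B) ||
      any(abs(A$coords - B$coords) > 1e-6)) {
    bad <- if (n_pixels(A) == n_pixels(B))
      which(rowSums(abs(A$coords - B$coords)) > 1e-6) else integer(0)
    stop("pixel sets differ between blocks",
         if (length(bad)) paste0(": first mismatch at (",
           paste(A$coords[bad[1], ], collapse = ", "), ") vs (",
           paste(B$coords[bad[1], ], collapse = ", "), ")") else
           paste0(": ", n_pixels(A), " vs ", n_pixels(B), " pixels"))
  }
  prov <- data.frame(
    block = c(rep(A$modality, n_channels(A)), rep(B$modality, n_channels(B))),
    channel = c(A$axis, B$axis),
    stringsAsFactors = FALSE)
  structure(list(matrix = cbind(A$intensities, w * B$intensities),
                 provenance = prov, w = w, coords = A$coords),
            class = "FusedMatrix")
}

#' @export
print.FusedMatrix <- function(x, ...) {
  tab <- table(x$provenance$block)
  cat(sprintf("<FusedMatrix: %d pixels x %d channels (%s), w = %.6g>\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(sprintf("%s %d", names(tab), tab), collapse = " + "),
              x$w))
  invisible(x)
}

#' Slice a fused matrix back into its blocks
#'
#' @param fused a `FusedMatrix`.
#' @return named list of matrices, one per provenance block (the second
#'   block still carries its weighting), each with the original channel
#'   axis as attribute `"channel"`.
#' @export
split_blocks <- function(fused) {
  stopifnot(inherits(fused, "FusedMatrix"))
  blocks <- unique(fused$provenance$block)
  out <- lapply(blocks, function(b) {
    j <- fused$provenance$block == b
    m <- fused$matrix[, j, drop = FALSE]
    attr(m, "channel") <- fused$provenance$channel[j]
    m
  })
  names(out) <- blocks
  out
}
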