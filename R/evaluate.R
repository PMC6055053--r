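# Joint analysis of the fused matrix: PCA, the cumulative-explained-
# variance criterion, the weighting sweep, loading decomposition, RGB
# score composites and cross-modality correlation.

as_data_matrix <- function(x) {
  if (inherits(x, "FusedMatrix")) return(x$matrix)
  if (inherits(x, "SpectralMap")) return(x$intensities)
  as.matrix(x)
}

#' Principal component analysis of a (fused) data matrix
#'
#' Column-mean-centred PCA by singular value decomposition. No per-column
#' standardization is applied: unit-variance scaling would equalize the
#' blocks and nullify the weighting question the fused analysis is meant
#' to answer. Explained-variance proportions are computed against the
#' total variance of the *full* centred matrix, so they remain correct for
#' a truncated model. Loading signs are fixed so that each column's
#' largest-magnitude element is positive, making score images
#' reproducible.
#'
#' @param x numeric matrix (`n x p`), `SpectralMap` or `FusedMatrix`.
#' @param k number of components, `<= min(n - 1, p)`.
#' @return an object of class `PCAModel`: `mean` (p-vector), `loadings`
#'   (`p x k`, orthonormal), `scores` (`n x k`), `explained` (k
#'   proportions), `cumulative`, `total_variance`; plus `provenance` when
#'   `x` is a `FusedMatrix`.
#' @export
pca <- function(x, k = 3L) {
  prov <- if (inherits(x, "FusedMatrix")) x$provenance
  X <- as_data_matrix(x)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop("need at least 2 rows for PCA")
  k <- as.integer(k)
  if (k < 1L || k > min(n - 1L, p))
    stop("k must be between 1 and min(n-1, p) = ", min(n - 1L, p))
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  tot_ss <- sum(Xc^2)
  if (tot_ss == 0) stop("zero variance: matrix is constant")
  sv <- svd(Xc, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  loadings <- sweep(sv$v, 2L, flip, "*")
  scores <- sweep(sv$u, 2L, sv$d[seq_len(k)] * flip, "*")
  explained <- sv$d[seq_len(k)]^2 / tot_ss
  structure(list(mean = mu, loadings = loadings, scores = scores,
                 explained = explained, cumulative = cumsum(explained),
                 total_variance = tot_ss / (n - 1L),
                 singular_values = sv$d, provenance = prov),
            class = "PCAModel")
}

#' @export
print.PCAModel <- function(x, ...) {
  k <- length(x$explained)
  cat(sprintf("<PCAModel: %d components, cumulative explained %.1f%%>\n",
              k, 100 * x$cumulative[k]))
  print(round(rbind(explained = x$explained,
                    cumulative = x$cumulative), 4))
  invisible(x)
}

#' Cumulative explained-variance curve
#'
#' Running sum of the per-component explained-variance proportions over
#' the first `k` components; the curve reaches 1 at full rank. A slower
#' rise means the data variance is spread over more independent features,
#' which is the criterion used to judge the quality of a block weighting.
#'
#' @param model a `PCAModel`.
#' @param k number of components, `<=` the model's component count.
#' @return numeric vector of length `k`, non-decreasing, bounded by 1.
#' @export
cumulative_curve <- function(model, k = length(model$explained)) {
  stopifnot(inherits(model, "PCAModel"))
  k <- as.integer(k)
  if (k < 1L || k > length(model$explained))
    stop("k must be between 1 and ", length(model$explained))
  model$cumulative[seq_len(k)]
}

#' Sweep the block weighting coefficient
#'
#' For each candidate coefficient `c`, runs a PCA of `[A | c B]` and
#' records the cumulative explained-variance curve. The curve minimum per
#' PC count identifies the coefficient that spreads the variance over the
#' most components ("optimal unmixing" for that number of PCs). The
#' default grid is 1..20; `c = 1` is the unweighted case.
#'
#' @param A,B aligned `SpectralMap`s or matrices (same pixels, same
#'   order).
#' @param coefficients vector of positive weighting coefficients.
#' @param k number of PCs per curve.
#' @return an object of class `SweepResult`: `coefficients`, `curves`
#'   (`length(coefficients) x k`), `argmin_per_k`.
#' @export
weight_sweep <- function(A, B, coefficients = 1:20, k = 20L) {
  if (any(coefficients <= 0)) stop("coefficients must be positive")
  MA <- as_data_matrix(A); MB <- as_data_matrix(B)
  if (nrow(MA) != nrow(MB)) stop("blocks must share the pixel set")
  curves <- t(vapply(coefficients, function(cc) {
    cumulative_curve(pca(cbind(MA, cc * MB), k = k))
  }, numeric(k)))
  structure(list(coefficients = coefficients, curves = curves,
                 argmin_per_k = coefficients[apply(curves, 2L, which.min)]),
            class = "SweepResult")
}

#' @export
print.SweepResult <- function(x, ...) {
  cat(sprintf("<SweepResult: %d coefficients x %d PCs>\n",
              length(x$coefficients), ncol(x$curves)))
  invisible(x)
}

#' Split fused loadings by modality
#'
#' Partitions each loading column of a fused-data PCA into its
#' per-modality parts using the column provenance, so Raman loadings can
#' be read against cm^-1 and MALDI loadings against Da.
#'
#' @param model a `PCAModel`.
#' @param provenance data frame with `block` and `channel` per fused
#'   column; defaults to the provenance stored by `pca(<FusedMatrix>)`.
#' @return named list of matrices (one per block, `p_block x k`), each
#'   with attribute `"channel"`.
#' @export
split_loadings <- function(model, provenance = model$provenance) {
  stopifnot(inherits(model, "PCAModel"))
  if (is.null(provenance)) stop("no provenance available")
  if (nrow(provenance) != nrow(model$loadings))
    stop("provenance covers ", nrow(provenance), " columns but loadings have ",
         nrow(model$loadings))
  blocks <- unique(provenance$block)
  out <- lapply(blocks, function(b) {
    j <- provenance$block == b
    m <- model$loadings[j, , drop = FALSE]
    attr(m, "channel") <- provenance$channel[j]
    m
  })
  names(out) <- blocks
  out
}

robust_unit_scale <- function(v, probs = c(0.02, 0.98)) {
  q <- stats::quantile(v, probs, names = FALSE, na.rm = TRUE)
  if (q[2] <= q[1]) return(rep(0.5, length(v)))
  pmin(1, pmax(0, (v - q[1]) / (q[2] - q[1])))
}

#' False-colour composite image of three PC score maps
#'
#' Rasterizes three score columns onto the pixel grid as the red, green
#' and blue channels. Each channel is robustly scaled (clipped to its
#' 2nd-98th percentile, then min-max to [0, 1]); a constant channel maps
#' to 0.5. Grid cells without a pixel are rendered neutral grey (0.5).
#'
#' @param model a `PCAModel` (or a plain score matrix).
#' @param coords `n x 2` um coordinates of the score rows; must form a
#'   rectangular grid (missing cells allowed).
#' @param pcs integer triple of component indices (default 1, 2, 3).
#' @return an array `ny x nx x 3` of class `rgb_composite`, with the grid
#'   axes as attributes `x` and `y`.
#' @export
rgb_composite <- function(model, coords, pcs = c(1L, 2L, 3L)) {
  scores <- if (inherits(model, "PCAModel")) model$scores else as.matrix(model)
  if (length(pcs) != 3L || any(pcs < 1L) || any(pcs > ncol(scores)))
    stop("pcs must be 3 valid component indices")
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(scores))
    stop("coords rows must match score rows")
  grid <- coords_to_grid(coords)
  if (is.null(grid))
    stop("coords do not form a rectangular grid; resample to a regular ",
         "pitch first")
  img <- array(0.5, dim = c(grid$ny, grid$nx, 3L))
  for (ch in 1:3) {
    plane <- matrix(NA_real_, grid$ny, grid$nx)
    plane[cbind(grid$row, grid$col)] <- scores[, pcs[ch]]
    scaled <- matrix(0.5, grid$ny, grid$nx)
    got <- !is.na(plane)
    scaled[got] <- robust_unit_scale(plane[got])
    img[, , ch] <- scaled
  }
  structure(img, x = grid$ux, y = grid$uy, pcs = pcs,
            class = "rgb_composite")
}

#' @export
plot.rgb_composite <- function(x, ...) {
  op <- graphics::par(mar = c(2, 2, 1, 1))
  on.exit(graphics::par(op))
  xr <- range(attr(x, "x")); yr <- range(attr(x, "y"))
  graphics::plot(NA, xlim = xr, ylim = yr, asp = 1, xlab = "x (um)",
                 ylab = "y (um)", ...)
  graphics::rasterImage(grDevices::as.raster(unclass(x)[dim(x)[1]:1, , ]),
                        xr[1], yr[1], xr[2], yr[2])
  invisible(x)
}

#' Spatial roughness of a composite image
#'
#' Mean squared difference between 4-connected neighbouring cells,
#' averaged over the three colour channels - a simple spatial-noise
#' metric used to compare fused and single-modality composites. An
#' optional logical mask restricts the metric to (e.g.) homogeneous
#' regions; only cell pairs fully inside the mask are counted.
#'
#' @param comp an `rgb_composite`.
#' @param mask optional logical matrix `ny x nx`.
#' @return non-negative scalar.
#' @export
composite_roughness <- function(comp, mask = NULL) {
  stopifnot(inherits(comp, "rgb_composite"))
  a <- unclass(comp)
  ny <- dim(a)[1]; nx <- dim(a)[2]
  if (is.null(mask)) mask <- matrix(TRUE, ny, nx)
  num <- 0; den <- 0
  for (ch in 1:3) {
    p <- a[, , ch]
    mh <- mask[, -nx] & mask[, -1]
    mv <- mask[-ny, ] & mask[-1, ]
    num <- num + sum(((p[, -nx] - p[, -1])^2)[mh]) +
      sum(((p[-ny, ] - p[-1, ])^2)[mv])
    den <- den + sum(mh) + sum(mv)
  }
  if (den == 0) stop("empty mask")
  num / den
}

#' Cross-modality channel correlation
#'
#' Pearson correlation across pixels between every Raman channel and
#' every MALDI bin of two aligned maps. Constant channels yield `NA`
#' entries rather than errors.
#'
#' @param A,B aligned `SpectralMap`s (same pixels, same order).
#' @return `p_A x p_B` matrix of correlations, with the channel axes as
#'   `dimnames`.
#' @export
cross_correlation <- function(A, B) {
  MA <- as_data_matrix(A); MB <- as_data_matrix(B)
  if (nrow(MA) != nrow(MB)) stop("maps must share the pixel set")
  if (nrow(MA) < 3L) stop("need at least 3 shared pixels")
  sa <- apply(MA, 2L, stats::sd)
  sb <- apply(MB, 2L, stats::sd)
  r <- suppressWarnings(stats::cor(MA, MB))
  r[sa == 0, ] <- NA_real_
  r[, sb == 0] <- NA_real_
  if (inherits(A, "SpectralMap")) rownames(r) <- signif(A$axis, 8)
  if (inherits(B, "SpectralMap")) colnames(r) <- signif(B$axis, 8)
  r
}
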