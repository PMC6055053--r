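#' SNIP parameters
#'
#' Parameters of the sensitive nonlinear iterative peak (SNIP) clipping
#' background estimator shared by both modalities: a maximum clipping
#' half-window `max_window` (in channels), an optional log-log-square-root
#' (LLS) dynamic-range compression applied before clipping and inverted
#' afterwards, and the iteration order of the window size.
#'
#' The increasing order (p = 1..m) is the classic variant and the default;
#' LLS compression defaults off for Raman data and on for MALDI data,
#' whose shot-noise-dominated chemical background spans a much larger
#' dynamic range.
#'
#' @param max_window positive integer half-window m (channels); must be
#'   `>= 1` and `< n_channels / 2` of the spectra it is applied to.
#' @param lls logical, apply the LLS transform.
#' @param order `"increasing"` (p = 1..m) or `"decreasing"` (p = m..1).
#' @return an object of class `SnipParams`.
#' @export
snip_params <- function(max_window, lls = FALSE,
                        order = c("increasing", "decreasing")) {
  order <- match.arg(order)
  max_window <- as.integer(max_window)
  if (is.na(max_window) || max_window < 1L)
    stop("max_window must be a positive integer")
  structure(list(max_window = max_window, lls = isTRUE(lls), order = order),
            class = "SnipParams")
}

# LLS compression and its inverse; applied to a matrix shifted so its
# row-wise minimum is zero (the transform needs non-negative input).
lls_forward <- function(v) log(log(sqrt(v + 1) + 1) + 1)
lls_inverse <- function(t) (exp(exp(t) - 1) - 1)^2 - 1

# vectorized SNIP over the rows of a matrix: one clipping pass
# y_ij <- min(y_ij, (y_i(j-p) + y_i(j+p)) / 2) per window p, with
# out-of-range indices clamped to the edge.
snip_core <- function(Y, params) {
  p <- ncol(Y)
  if (params$max_window >= p / 2)
    stop("max_window (", params$max_window,
         ") must be smaller than n_channels/2 (", p / 2, ")")
  shift <- NULL
  if (params$lls) {
    shift <- apply(Y, 1L, min)
    Y <- lls_forward(Y - shift)
  }
  cols <- seq_len(p)
  windows <- seq_len(params$max_window)
  if (params$order == "decreasing") windows <- rev(windows)
  for (w in windows) {
    left <- pmax(cols - w, 1L)
    right <- pmin(cols + w, p)
    Y <- pmin(Y, (Y[, left, drop = FALSE] + Y[, right, drop = FALSE]) / 2)
  }
  if (params$lls) Y <- lls_inverse(Y) + shift
  Y
}

#' Estimate a spectral background with the SNIP algorithm
#'
#' Iteratively clips each point to the mean of its two neighbours at
#' distance p, for p = 1..`max_window` (or the reverse order). Without the
#' LLS transform the estimate is pointwise `<= y`; with LLS that bound can
#' be violated by rounding of the transform inversion.
#'
#' @param y numeric vector, one spectrum; must be longer than
#'   `2 * max_window`.
#' @param params a [snip_params()] object.
#' @return numeric vector of the same length: the estimated background.
#' @export
snip_baseline <- function(y, params) {
  stopifnot(inherits(params, "SnipParams"))
  y <- as.numeric(y)
  if (length(y) <= 2L * params$max_window)
    stop("spectrum too short (", length(y), ") for max_window ",
         params$max_window)
  drop(snip_core(matrix(y, nrow = 1L), params))
}

#' Subtract a SNIP background from every spectrum of a map
#'
#' Replaces each pixel's spectrum by `y - snip_baseline(y)`. Negative
#' values can remain near the noise floor and are deliberately preserved:
#' the distinction between l1 and total-intensity normalization rests on
#' them.
#'
#' @param map a `SpectralMap`.
#' @param params a [snip_params()] object.
#' @return the corrected `SpectralMap`; `meta$history` records the
#'   parameters.
#' @export
subtract_baseline <- function(map, params) {
  validate_spectral_map(map)
  stopifnot(inherits(params, "SnipParams"))
  if (n_channels(map) <= 2L * params$max_window)
    stop("spectra too short for max_window ", params$max_window)
  bg <- snip_core(map$intensities, params)
  map$intensities <- map$intensities - bg
  note_step(map, "snip_baseline",
            list(max_window = params$max_window, lls = params$lls,
                 order = params$order))
}
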